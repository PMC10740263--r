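test_that("the alignment is the V x J permutation with conserved anchors", {
  g <- fixtureGermlines(seed = 2, nV = 3, nJ = 2)
  aln <- buildAlignment(g$V, g$J)
  expect_length(aln@rows, 6L)                       # |V| x |J|
  expect_length(unique(nchar(aln@rows)), 1L)
  mat <- do.call(rbind, strsplit(aln@rows, ""))
  expect_true(all(mat[, match("23", aln@labels)] == "C"))
  expect_true(all(mat[, match("104", aln@labels)] == "C"))
  expect_true(all(mat[, match("41", aln@labels)] == "W"))
  expect_true(all(mat[, match("118", aln@labels)] == "W"))
  # no residue lost or duplicated: degapped rows reproduce V + J
  for (id in names(aln@rows)) {
    vj <- strsplit(id, "|", fixed = TRUE)[[1]]
    expect_identical(gsub("-", "", aln@rows[[id]]),
                     paste0(g$V[[vj[1]]], g$J[[vj[2]]]))
  }
})

test_that("a 1 x 1 germline pair gives a single gap-free row", {
  g <- fixtureGermlines(seed = 3, nV = 1, nJ = 1)
  aln <- buildAlignment(g$V, g$J)
  expect_length(aln@rows, 1L)
  expect_identical(unname(aln@rows[[1]]), paste0(g$V[[1]], g$J[[1]]))
})

test_that("empty germline sets are refused", {
  g <- fixtureGermlines()
  expect_error(buildAlignment(character(0), g$J), "empty V")
  expect_error(buildAlignment(g$V, character(0)), "empty J")
})

test_that("a segment without anchors names itself in the build error", {
  g <- fixtureGermlines()
  bad <- c(g$V, broken = gsub("C", "A", g$V[[1]]))
  expect_error(buildAlignment(bad, g$J), "broken")
})

test_that("validation passes fixture alignments and flags forced defects", {
  aln <- fixtureAlignment()
  rep <- validateAlignment(aln)
  expect_true(rep$pass)
  expect_identical(nrow(rep$findings), 0L)

  # (a) one row one column short
  rows <- aln@rows
  rows[[2]] <- substring(rows[[2]], 1, nchar(rows[[2]]) - 1L)
  bad <- validateAlignment(list(rows = rows, labels = aln@labels))
  expect_false(bad$pass)
  f <- bad$findings
  expect_true(any(f$code == "non_rectangular" &
                  f$detail == names(rows)[2]))

  # (c) CDR2 columns all gapped
  rows2 <- aln@rows
  cdr2 <- which(aln@regions == "CDR2")
  for (id in names(rows2)) {
    ch <- strsplit(rows2[[id]], "")[[1]]
    ch[cdr2] <- "-"
    rows2[[id]] <- paste(ch, collapse = "")
  }
  bad2 <- validateAlignment(list(rows = rows2, labels = aln@labels))
  expect_false(bad2$pass)
  expect_true(any(bad2$findings$code == "empty_region" &
                  bad2$findings$detail == "CDR2"))

  # (d) duplicate row ids
  rows3 <- aln@rows
  names(rows3)[2] <- names(rows3)[1]
  bad3 <- validateAlignment(list(rows = rows3, labels = aln@labels))
  expect_false(bad3$pass)
  expect_true(any(bad3$findings$code == "duplicate_row_id"))

  # (b) anchor degradation only warns
  rows4 <- aln@rows
  c23 <- match("23", aln@labels)
  for (id in names(rows4)) substring(rows4[[id]], c23, c23) <- "A"
  warned <- validateAlignment(list(rows = rows4, labels = aln@labels))
  expect_true(warned$pass)
  expect_true(any(warned$findings$code == "anchor_conservation" &
                  warned$findings$level == "warn"))
})

test_that("alignments round-trip through Stockholm and aligned FASTA", {
  aln <- fixtureAlignment()
  sto <- withr::local_tempfile(fileext = ".sto")
  writeAlignment(aln, sto, format = "stockholm")
  back <- importAlignment(sto)
  expect_identical(back@rows, aln@rows)
  expect_identical(back@labels, aln@labels)
  expect_identical(back@regions, aln@regions)

  fa <- withr::local_tempfile(fileext = ".fasta")
  writeAlignment(aln, fa, format = "fasta")
  back2 <- importAlignment(fa)      # labels re-derived from the rows
  expect_identical(back2@labels, aln@labels)
  expect_identical(back2@regions, aln@regions)
  expect_identical(back2@rows, aln@rows)
})

test_that("unreadable and empty alignment files raise parse errors", {
  expect_error(importAlignment(file.path(tempdir(), "nope.sto")),
               "cannot read")
  empty <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "#=GF IMGT 1 2 3", "//"), empty)
  expect_error(importAlignment(empty), "0 records")
  noLabels <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "a ACD", "//"), noLabels)
  expect_error(importAlignment(noLabels), "IMGT")
})

test_that("the registry builds, lists, loads and removes models", {
  reg <- withr::local_tempdir()
  expect_identical(nrow(listModels(reg)), 0L)       # fresh registry
  aln <- fixtureAlignment()
  buildModel(aln, "toy", registry = reg)
  lst <- listModels(reg)
  expect_identical(lst$name, "toy")
  expect_identical(lst$alphabet_size, 20L)
  expect_false(lst$corrupt)
  # duplicate name refused without overwrite
  expect_error(buildModel(aln, "toy", registry = reg), "already exists")
  expect_silent(buildModel(aln, "toy", registry = reg, overwrite = TRUE))
  # load restores the profile bit-exactly
  m <- loadModel("toy", reg)
  expect_identical(m@profile, trainProfile(aln, 20)$profile)
  expect_identical(m@columnLabels, aln@labels[
    trainProfile(aln, 20)$matchCols])
  # removal
  removeModel("toy", reg)
  expect_identical(nrow(listModels(reg)), 0L)
  expect_error(removeModel("toy", reg), "not found")
})

test_that("invalid model names and failed validation are refused", {
  reg <- withr::local_tempdir()
  aln <- fixtureAlignment()
  expect_error(buildModel(aln, "bad name", registry = reg), "name")
  rows <- aln@rows
  names(rows)[2] <- names(rows)[1]
  badAln <- new("ModelAlignment", rows = rows, labels = aln@labels,
                regions = aln@regions)
  expect_error(buildModel(badAln, "ok", registry = reg), "validation")
})

test_that("corrupt registry entries are listed, not fatal", {
  reg <- withr::local_tempdir()
  buildModel(fixtureAlignment(), "good", registry = reg)
  dir.create(file.path(reg, "broken"))
  writeLines("not json", file.path(reg, "broken", "meta.json"))
  lst <- listModels(reg)
  expect_identical(sort(lst$name), c("broken", "good"))
  expect_identical(lst$corrupt[lst$name == "broken"], TRUE)
  expect_identical(lst$corrupt[lst$name == "good"], FALSE)
})

test_that("model builds are deterministic to the byte", {
  reg1 <- withr::local_tempdir(); reg2 <- withr::local_tempdir()
  aln <- fixtureAlignment()
  buildModel(aln, "m", registry = reg1)
  buildModel(aln, "m", registry = reg2)
  expect_identical(readLines(file.path(reg1, "m", "profile.txt")),
                   readLines(file.path(reg2, "m", "profile.txt")))
})

test_that("a reduced-alphabet model annotates unreduced queries", {
  reg <- withr::local_tempdir()
  m8 <- buildModel(fixtureAlignment(), "toy8", alphabetSize = 8,
                   registry = reg)
  expect_identical(m8@alphabetSize, 8L)
  expect_identical(listModels(reg)$alphabet_size, 8L)
  g <- fixtureGermlines()
  res <- annotate(paste0(g$V[[1]], g$J[[1]]), m8, id = "q")
  expect_identical(annotationStatus(res), "annotated")
})
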