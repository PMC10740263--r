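test_that("FASTA round-trips ids, descriptions and sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  df <- data.frame(id = c("a", "b"), description = c("b c", ""),
                   sequence = c("ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACD",
                                "MKVL"), stringsAsFactors = FALSE)
  writeFasta(df, f)
  back <- readFasta(f)
  expect_identical(back$id, df$id)
  expect_identical(back$description, df$description)
  expect_identical(back$sequence, df$sequence)
  expect_identical(back$molecule, c("aa", "aa"))
})

test_that("the id is the first header token", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a b c", "MKV"), f)
  r <- readFasta(f)
  expect_identical(r$id, "a")
  expect_identical(r$description, "b c")
})

test_that("molecule type is detected at the 90% ACGTUN rule", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">nt", "ACGTACGT", ">aa", "ACDEFGHIK"), f)
  r <- readFasta(f)
  expect_identical(r$molecule, c("nt", "aa"))
  expect_identical(readFasta(f, molecule = "aa")$molecule, c("aa", "aa"))
})

test_that("malformed and empty FASTA files are handled per contract", {
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("MKVL", ">a", "ACD"), bad)
  expect_error(readFasta(bad), "line 1")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_identical(nrow(readFasta(empty)), 0L)
  expect_error(readFasta(file.path(tempdir(), "missing.fasta")),
               "cannot read")
})

test_that("six-frame translation follows the genetic code", {
  fr <- sixFrameTranslate("ATGGCC", id = "x")
  expect_identical(fr$sequence, c("MA", "W", "G", "GH", "A", "P"))
  expect_identical(fr$id, paste0("x/frame", c("+1", "+2", "+3",
                                              "-1", "-2", "-3")))
  expect_identical(sixFrameTranslate("TAA")$sequence[1], "*")
  expect_identical(sixFrameTranslate("AANTGG")$sequence[1], "XW")
  expect_error(sixFrameTranslate("ACGZ"))
})

test_that("reverse frames equal forward frames of the reverse complement", {
  set.seed(17)
  for (k in 1:5) {
    nt <- paste(sample(c("A", "C", "G", "T"), 30 + k, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    a <- sixFrameTranslate(nt)
    b <- sixFrameTranslate(rc)
    for (f in 1:3)
      expect_identical(a$sequence[a$frame == paste0("-", f)],
                       b$sequence[b$frame == paste0("+", f)])
    # frame lengths: floor((L - f + 1) / 3) residues at offset f - 1
    L <- nchar(nt)
    expect_identical(nchar(a$sequence[1:3]), (L - 0:2) %/% 3L)
  }
})

test_that("stop-containing records are filtered with a count message", {
  expect_identical(suppressMessages(filterStops(c(a = "MAK", b = "MA*K"))),
                   c(a = "MAK"))
  expect_message(filterStops(c(a = "MA*", b = "M*K")), "2 record")
  expect_identical(filterStops(c(a = "MAK")), c(a = "MAK"))
})

test_that("BED output follows the 0-based half-open convention", {
  g <- fixtureGermlines()
  model <- fixtureModel()
  rep <- makeRepertoire(g, 5, cdr3Range = c(0, 10), mutationRate = 0,
                        seed = 41)
  res <- annotateBatch(rep$reads, model)
  f <- withr::local_tempfile(fileext = ".bed")
  writeBed(res, f)
  lines <- readLines(f)
  expect_identical(length(lines), 35L)            # 5 reads x 7 regions
  first <- strsplit(lines[[1]], "\t")[[1]]
  expect_identical(first[1:4], c("read0001", "0", "26", "FR1"))
  expect_identical(first[6], "+")
  expect_true(all(as.integer(vapply(strsplit(lines, "\t"), `[[`, "", 5)) <=
                  1000L))
  # intervals per query are sorted and non-overlapping
  for (id in unique(vapply(strsplit(lines, "\t"), `[[`, "", 1))) {
    part <- do.call(rbind, strsplit(lines[startsWith(lines, id)], "\t"))
    s <- as.integer(part[, 2]); e <- as.integer(part[, 3])
    expect_true(all(s[-1] >= e[-length(e)]))
  }
  # rejected records emit no lines
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeBed(list(annotate("", model, id = "bad")), f2)
  expect_identical(readLines(f2), character(0))
})

test_that("BED intervals of zero-mutation reads equal the truth file", {
  g <- fixtureGermlines()
  model <- fixtureModel()
  rep <- makeRepertoire(g, 20, cdr3Range = c(0, 10), mutationRate = 0,
                        seed = 42)
  res <- annotateBatch(rep$reads, model)
  out <- withr::local_tempfile(fileext = ".bed")
  tru <- withr::local_tempfile(fileext = ".bed")
  writeBed(res, out)
  writeTruthBed(rep$truth, tru)
  take4 <- function(p) vapply(strsplit(readLines(p), "\t"),
                              function(x) paste(x[1:4], collapse = "\t"), "")
  expect_identical(take4(out), take4(tru))
})

test_that("region FASTA export round-trips the in-memory regions", {
  g <- fixtureGermlines()
  model <- fixtureModel()
  rep <- makeRepertoire(g, 5, cdr3Range = c(5, 10), mutationRate = 0,
                        seed = 43)
  res <- annotateBatch(rep$reads, model)
  f <- withr::local_tempfile(fileext = ".fasta")
  writeFastaRegions(res, f, which = "CDR3")
  back <- readFasta(f, molecule = "aa")
  expect_identical(nrow(back), 5L)               # one record per query
  for (k in seq_len(5)) {
    meta <- strsplit(back$id[k], "|", fixed = TRUE)[[1]]
    r <- res[[match(meta[1], vapply(res, function(x) x@queryId, ""))]]
    expect_identical(back$sequence[k],
                     regions(r)$sequence[regions(r)$region == "CDR3"])
  }
  fFull <- withr::local_tempfile(fileext = ".fasta")
  writeFastaRegions(res, fFull, which = "full")
  full <- readFasta(fFull, molecule = "aa")
  expect_identical(full$sequence[1],
                   paste(regions(res[[1]])$sequence, collapse = ""))
  expect_error(writeFastaRegions(res, f, which = "CDR9"), "selector")
})
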