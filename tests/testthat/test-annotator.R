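mkHit <- function(score, qpos, labels, model = "m") {
  new("DomainHit", modelName = model, bitScore = score,
      start = min(qpos), end = max(qpos) + 1L,
      path = data.frame(qpos = as.integer(qpos), state = "M",
                        label = as.character(labels), odds = 2,
                        stringsAsFactors = FALSE))
}

test_that("model selection maximises the best single-hit score", {
  a40 <- mkHit(40, 0:20, 1:21, "A")
  b25 <- mkHit(25, 0:20, 1:21, "B")
  expect_identical(selectBestModel(list(A = list(a40), B = list(b25))), "A")
  expect_identical(selectBestModel(list(A = list(), B = list(b25))), "B")
  expect_identical(selectBestModel(list(A = list(), B = list())),
                   NA_character_)
  # tie on best hit -> total summed score decides, then lexical name
  expect_identical(selectBestModel(list(
    B = list(mkHit(30, 0:9, 1:10), mkHit(10, 20:29, 20:29)),
    A = list(mkHit(30, 0:9, 1:10)))), "B")
  expect_identical(selectBestModel(list(B = list(mkHit(30, 0:9, 1:10)),
                                        A = list(mkHit(30, 0:9, 1:10)))),
                   "A")
})

test_that("a heavy-chain query picks the heavy model over the light model", {
  regH <- file.path(tempdir(), "igp-two-models")
  gH <- fixtureGermlines(seed = 1)
  gL <- makeGermlineSet(seed = 77, nV = 3, nJ = 2)
  mH <- buildModel(buildAlignment(gH$V, gH$J), "heavy", registry = regH,
                   overwrite = TRUE)
  mL <- buildModel(buildAlignment(gL$V, gL$J), "light", registry = regH,
                   overwrite = TRUE)
  res <- annotate(paste0(gH$V[[1]], "ARDYW", gH$J[[2]]), list(mH, mL),
                  id = "h1")
  expect_identical(annotationStatus(res), "annotated")
  expect_identical(res@modelName, "heavy")
})

test_that("a single full-length hit merges to its own path", {
  h <- mkHit(50, 0:25, 1:26)
  cn <- mergeHits(list(h), paste(rep("A", 26), collapse = ""))
  expect_identical(cn@entries$qpos, 0:25)
  expect_identical(cn@entries$label, as.character(1:26))
  expect_identical(unique(cn@entries$residue), "A")
  expect_length(cn@sourceHits, 1L)
})

test_that("an ultralong CDR3 is stitched across two hits with IMGT codes", {
  # FR1..FR3 hit ending at IMGT 104 + FR4 hit starting at IMGT 118,
  # 45 unassigned residues between them
  q <- paste(rep("K", 60 + 45 + 11), collapse = "")
  hV <- mkHit(200, 0:59, 45:104)
  hJ <- mkHit(25, 105:115, 118:128)
  cn <- mergeHits(list(hV, hJ), q)
  gap <- cn@entries[cn@entries$qpos %in% 60:104, ]
  expect_identical(nrow(gap), 45L)
  expect_identical(gap$label[1:7], as.character(105:111))
  expect_identical(gap$label[45], "117")
  expect_true(any(gap$label == "111.1"))
  expect_true(any(gap$label == "112.1"))
  expect_true(all(diff(imgtKey(cn@entries$label)) > 0))
  expect_identical(sum(imgtRegion(cn@entries$label) == "CDR3"), 45L)
})

test_that("overlapping conflicting hits resolve to the stronger one", {
  strong <- mkHit(30, 0:20, 10:30)
  weak <- mkHit(12, 5:25, 10:30)   # same labels, shifted query: conflict
  cn <- mergeHits(list(strong, weak), paste(rep("A", 30), collapse = ""))
  expect_identical(cn@entries$qpos[cn@entries$source == "match"], 0:20)
  expect_length(cn@sourceHits, 1L)
  expect_identical(cn@sourceHits[[1]]@bitScore, 30)
})

test_that("near-tied incompatible hits record an ambiguous merge", {
  a <- mkHit(30, 0:20, 10:30)
  b <- mkHit(29.5, 25:45, 10:30)   # label-incompatible, within 1 bit
  cn <- mergeHits(list(a, b), paste(rep("A", 50), collapse = ""))
  expect_true("ambiguous_merge" %in% cn@findings)
})

test_that("consensus validation passes full-length fixtures reads", {
  g <- fixtureGermlines()
  model <- fixtureModel()
  res <- annotate(paste0(g$V[[1]], "GRSTMDY", g$J[[1]]), model, id = "q")
  expect_identical(annotationStatus(res), "annotated")
  rep <- validateConsensus(numbering(res), model)
  expect_true(rep$pass)
  expect_identical(nrow(rep$findings), 0L)
})

test_that("a consensus missing FR4 fails coverage, a 60-residue CDR3 passes", {
  g <- fixtureGermlines()
  model <- fixtureModel()
  res <- annotate(paste0(g$V[[1]], "GRSTMDY", g$J[[1]]), model, id = "q")
  cn <- numbering(res)
  noFr4 <- new("ConsensusNumbering",
               entries = cn@entries[imgtRegion(cn@entries$label) != "FR4", ],
               modelName = cn@modelName, sourceHits = cn@sourceHits,
               findings = character(0))
  rep <- validateConsensus(noFr4, model)
  expect_false(rep$pass)
  expect_true(any(rep$findings$code == "low_coverage" &
                  rep$findings$detail == "FR4"))

  # explicitly no upper bound on CDR3 length
  rep60 <- makeRepertoire(g, 3, cdr3Range = c(60, 60), mutationRate = 0,
                          seed = 31)
  for (q in rep60$reads) {
    r <- annotate(q, model, id = "u")
    expect_identical(annotationStatus(r), "annotated")
    reg <- regions(r)
    expect_identical(reg$end[6] - reg$start[6], 60L)
  }
})

test_that("anchor mutations warn but do not reject", {
  g <- fixtureGermlines()
  model <- fixtureModel()
  rep <- makeRepertoire(g, 3, cdr3Range = c(3, 8), mutationRate = 0,
                        seed = 32, breakAnchors = TRUE)
  for (q in rep$reads) {
    r <- annotate(q, model, id = "b")
    expect_identical(annotationStatus(r), "annotated")
    v <- validateConsensus(numbering(r), model)
    expect_true(v$pass)
    expect_true(any(v$findings$code == "anchor_mismatch" &
                    v$findings$level == "warn"))
  }
})

test_that("regions partition the annotated span in order", {
  g <- fixtureGermlines()
  model <- fixtureModel()
  rep <- makeRepertoire(g, 10, cdr3Range = c(0, 20), mutationRate = 0,
                        seed = 33)
  for (id in names(rep$reads)) {
    q <- rep$reads[[id]]
    r <- annotate(q, model, id = id)
    reg <- regions(r)
    expect_identical(reg$region, c("FR1", "CDR1", "FR2", "CDR2", "FR3",
                                   "CDR3", "FR4"))
    expect_true(all(reg$start[-1] == reg$end[-7]))
    expect_identical(paste(reg$sequence, collapse = ""),
                     substring(q, reg$start[1] + 1L, reg$end[7]))
    # full 13-position CDR3 has length 13
    tl <- truthFor(rep$truth, id)
    expect_identical(reg$end[6] - reg$start[6],
                     tl$end[6] - tl$start[6])
  }
})

test_that("invalid and unmatched queries reject with coded reasons", {
  model <- fixtureModel()
  expect_identical(rejectReasons(annotate("", model)), "invalid_sequence")
  expect_identical(rejectReasons(annotate("ACDB1", model)),
                   "invalid_sequence")
  set.seed(55)
  r <- annotate(randomQuery(40), model, id = "rand")
  expect_identical(annotationStatus(r), "rejected")
  expect_identical(rejectReasons(r), "no_hit")
})

test_that("two concatenated domains reject as multiple_domains", {
  g <- fixtureGermlines()
  model <- fixtureModel()
  domain <- paste0(g$V[[1]], "GRSTMDY", g$J[[1]])
  scfv <- paste0(domain, "GGGGSGGGGS", domain)
  r <- annotate(scfv, model, id = "scfv")
  expect_identical(annotationStatus(r), "rejected")
  expect_true("multiple_domains" %in% rejectReasons(r))
})

test_that("batch annotation is order-preserving and worker-invariant", {
  g <- fixtureGermlines()
  model <- fixtureModel()
  rep <- makeRepertoire(g, 50, cdr3Range = c(0, 30), mutationRate = 0.03,
                        seed = 34)
  r1 <- annotateBatch(rep$reads, model, workers = 1)
  r4 <- annotateBatch(rep$reads, model, workers = 4)
  expect_length(r1, 50L)
  expect_identical(vapply(r1, function(r) r@queryId, ""), names(rep$reads))
  expect_identical(lapply(r1, regions), lapply(r4, regions))
  expect_identical(vapply(r1, annotationStatus, ""),
                   vapply(r4, annotationStatus, ""))
  expect_identical(annotateBatch(character(0), model), list())
})
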