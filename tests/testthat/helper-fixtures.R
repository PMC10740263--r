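# Shared fixture objects, built once per test run.
.fixCache <- new.env(parent = emptyenv())

fixtureGermlines <- function(seed = 1, nV = 4, nJ = 3) {
  key <- paste0("g", seed, "_", nV, "_", nJ)
  if (is.null(.fixCache[[key]]))
    .fixCache[[key]] <- makeGermlineSet(seed = seed, nV = nV, nJ = nJ)
  .fixCache[[key]]
}

fixtureAlignment <- function(seed = 1, nV = 4, nJ = 3) {
  key <- paste0("a", seed, "_", nV, "_", nJ)
  if (is.null(.fixCache[[key]])) {
    g <- fixtureGermlines(seed, nV, nJ)
    .fixCache[[key]] <- buildAlignment(g$V, g$J)
  }
  .fixCache[[key]]
}

# a trained model in a session registry; alphabetSize varies
fixtureModel <- function(alphabetSize = 20, seed = 1, nV = 4, nJ = 3) {
  key <- paste0("m", seed, "_", nV, "_", nJ, "_", alphabetSize)
  if (is.null(.fixCache[[key]])) {
    reg <- file.path(tempdir(), "igprofile-test-registry")
    .fixCache[[key]] <- buildModel(fixtureAlignment(seed, nV, nJ),
                                   paste0("fix", key),
                                   alphabetSize = alphabetSize,
                                   registry = reg, overwrite = TRUE)
  }
  .fixCache[[key]]
}

# truth rows for one read id
truthFor <- function(truth, id) truth[truth$id == id, , drop = FALSE]

# do the regions of an annotated result equal the ground truth exactly?
regionsMatchTruth <- function(result, truth, tol = 0L) {
  t <- truthFor(truth, result@queryId)
  r <- regions(result)
  all(abs(r$start - t$start) <= tol) && all(abs(r$end - t$end) <= tol)
}
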