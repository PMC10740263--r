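# Brute-force oracle for local profile-HMM alignment: enumerate every state
# path (entry at any match cell, exit at any match cell) recursively and
# return the maximum bit score.  Written independently of the package's
# dynamic-programming engine; only usable for tiny profiles/queries.
oracleBestScore <- function(profile, seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(ch, profile@symbols)
  L <- length(ch)
  M <- profile@nMatch
  lo <- matrix(0, L, M)
  for (i in seq_len(L)) {
    if (!is.na(idx[i]))
      lo[i, ] <- log2(profile@matchEmis[, idx[i]]) -
        log2(profile@background[idx[i]])
  }
  t2 <- lapply(profile@transitions, log2)
  best <- -Inf
  rec <- function(state, i, j, sc) {
    if (state == "M") best <<- max(best, sc)
    if (j < M) {
      if (state == "M") {
        if (i < L) rec("M", i + 1L, j + 1L, sc + t2$mm[j] + lo[i + 1L, j + 1L])
        if (i < L) rec("I", i + 1L, j, sc + t2$mi[j])
        rec("D", i, j + 1L, sc + t2$md[j])
      } else if (state == "I") {
        if (i < L) rec("I", i + 1L, j, sc + t2$ii[j])
        if (i < L) rec("M", i + 1L, j + 1L, sc + t2$im[j] + lo[i + 1L, j + 1L])
      } else {
        if (i < L) rec("M", i + 1L, j + 1L, sc + t2$dm[j] + lo[i + 1L, j + 1L])
        rec("D", i, j + 1L, sc + t2$dd[j])
      }
    }
  }
  for (i0 in seq_len(L)) for (j0 in seq_len(M))
    rec("M", i0, j0, lo[i0, j0])
  best
}

# random tiny profile for oracle comparisons (raw stochastic matrices, not
# tied to the training code path)
randomTinyProfile <- function(nMatch, alphabetSize = 20) {
  alphabet <- getAlphabet(alphabetSize)
  symbols <- unique(alphabet@mapping)
  K <- length(symbols)
  rdist <- function(n) { x <- stats::runif(n) + 0.05; x / sum(x) }
  emis <- t(vapply(seq_len(nMatch), function(i) rdist(K), numeric(K)))
  colnames(emis) <- symbols
  nj <- max(nMatch - 1L, 0L)
  tr <- list(mm = numeric(0), mi = numeric(0), md = numeric(0),
             im = numeric(0), ii = numeric(0), dm = numeric(0),
             dd = numeric(0))
  if (nj > 0L) {
    m3 <- t(vapply(seq_len(nj), function(i) rdist(3L), numeric(3)))
    i2 <- t(vapply(seq_len(nj), function(i) rdist(2L), numeric(2)))
    d2 <- t(vapply(seq_len(nj), function(i) rdist(2L), numeric(2)))
    tr <- list(mm = m3[, 1], mi = m3[, 2], md = m3[, 3],
               im = i2[, 1], ii = i2[, 2], dm = d2[, 1], dd = d2[, 2])
  }
  bg <- rep(1 / K, K)
  names(bg) <- symbols
  new("ProfileHMM", nMatch = as.integer(nMatch),
      alphabetSize = as.integer(alphabetSize), symbols = symbols,
      matchEmis = emis, background = as.numeric(bg), transitions = tr)
}

randomQuery <- function(len) paste(sample(igprofile:::.AA20, len,
                                          replace = TRUE), collapse = "")
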