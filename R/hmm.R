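#' Profile HMM training and local alignment
#'
#' The engine behind annotation: a Plan7-style profile HMM (match, insert
#' and delete states; no I<->D transitions) trained from an IMGT-labelled
#' alignment, and Viterbi local alignment with Smith-Waterman-style free
#' entry/exit at match states.  All probability math is done in log space;
#' bit score = log-odds versus the background model / log(2).
#'
#' @name hmm_engine
#' @keywords internal
NULL

#' Train a profile HMM from a model alignment
#'
#' Match states are the alignment columns with >= 50% non-gap residues.
#' Rows are reduced with the Li et al. alphabet of size `alphabetSize` before
#' counting.  Emissions are column symbol counts plus a Laplace pseudocount
#' of 1, normalised over the alphabet; transitions are counted from the
#' observed gap structure of the rows plus a pseudocount of 1 per allowed
#' move.  Background (and insert) emission probabilities are proportional to
#' the number of amino acids each group symbol represents, so reduction
#' leaves a uniform-residue background exactly uniform over groups' mass.
#' Training is deterministic.
#'
#' @param aln a [ModelAlignment-class].
#' @param alphabetSize alphabet size, 3..20 (20 = no reduction).
#' @return list with elements `profile` (a [ProfileHMM-class]), `matchCols`
#'   (indices of the alignment columns that became match states).
#' @export
trainProfile <- function(aln, alphabetSize = 20) {
  stopifnot(is(aln, "ModelAlignment"))
  alphabet <- getAlphabet(alphabetSize)
  rows <- reduceSequence(aln@rows, alphabet)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  nr <- nrow(mat)
  occ <- colSums(mat != "-") / nr
  matchCols <- which(occ >= 0.5)
  M <- length(matchCols)
  if (M == 0L) stop("degenerate model: no column reaches 50% occupancy",
                    call. = FALSE)
  symbols <- unique(alphabet@mapping[.AA20])
  K <- length(symbols)
  bg <- .alphabetGroupSizes(alphabet)[symbols] / 20

  emis <- matrix(1, nrow = M, ncol = K, dimnames = list(NULL, symbols))
  for (m in seq_len(M)) {
    col <- mat[, matchCols[m]]
    tab <- table(factor(col[col %in% symbols], levels = symbols))
    emis[m, ] <- emis[m, ] + as.numeric(tab)
  }
  emis <- emis / rowSums(emis)

  # transition counts per junction j (between match j and j+1)
  cn <- list(mm = 0, mi = 0, md = 0, im = 0, ii = 0, dm = 0, dd = 0)
  counts <- lapply(cn, function(z) rep(1, max(M - 1L, 0L)))  # pseudocount 1
  if (M > 1L) {
    for (r in seq_len(nr)) {
      cells <- mat[r, ]
      isM <- cells[matchCols] != "-"
      nIns <- integer(M - 1L)
      for (j in seq_len(M - 1L)) {
        between <- seq.int(matchCols[j] + 1L, matchCols[j + 1L] - 1L)
        between <- between[between >= matchCols[j] + 1L &
                           between <= matchCols[j + 1L] - 1L]
        if (length(between)) nIns[j] <- sum(cells[between] != "-")
      }
      for (j in seq_len(M - 1L)) {
        src <- if (isM[j]) "m" else "d"
        dst <- if (isM[j + 1L]) "m" else "d"
        if (nIns[j] > 0L) {
          if (src == "m") {  # Plan7: no D->I; skip counting that entry move
            counts$mi[j] <- counts$mi[j] + 1
            if (nIns[j] > 1L) counts$ii[j] <- counts$ii[j] + nIns[j] - 1L
            if (dst == "m") counts$im[j] <- counts$im[j] + 1
          }
        } else {
          key <- paste0(src, dst)
          counts[[key]][j] <- counts[[key]][j] + 1
        }
      }
    }
  }
  tr <- list()
  sM <- counts$mm + counts$mi + counts$md
  tr$mm <- counts$mm / sM; tr$mi <- counts$mi / sM; tr$md <- counts$md / sM
  sI <- counts$im + counts$ii
  tr$im <- counts$im / sI; tr$ii <- counts$ii / sI
  sD <- counts$dm + counts$dd
  tr$dm <- counts$dm / sD; tr$dd <- counts$dd / sD

  # V x J models carry no CDR3 match columns (V ends at IMGT 104, J starts at
  # 117/118): the junction spanning the missing CDR3 gets an
  # insertion-tolerant prior (open an insertion with probability 1/2), so
  # CDR3 residues ride insert states there instead of being squeezed into
  # framework columns whose emissions they happen to tie.
  if (M > 1L) {
    base <- .imgtBase(aln@labels[matchCols])
    cdr3J <- which(base[-M] <= 111L & base[-1L] >= 112L)
    for (j in cdr3J) {
      keep <- tr$mm[j] + tr$md[j]
      tr$mi[j] <- 0.5
      tr$mm[j] <- 0.5 * tr$mm[j] / keep
      tr$md[j] <- 0.5 * tr$md[j] / keep
      tr$ii[j] <- 0.5; tr$im[j] <- 0.5
    }
  }

  profile <- new("ProfileHMM", nMatch = M, alphabetSize = alphabet@size,
                 symbols = symbols, matchEmis = emis,
                 background = as.numeric(bg), transitions = tr)
  list(profile = profile, matchCols = matchCols)
}

# log2 match emission odds of a query (already reduced) against a profile;
# rows = query positions, cols = match states.  'X' scores 0 (background).
.queryLogOdds <- function(profile, seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(ch, profile@symbols)
  lo2 <- log2(profile@matchEmis) -
    matrix(log2(profile@background), nrow = profile@nMatch,
           ncol = length(profile@symbols), byrow = TRUE)
  out <- matrix(0, nrow = length(ch), ncol = profile@nMatch)
  known <- !is.na(idx)
  if (any(!known) && any(!ch[!known] %in% "X"))
    stop("invalid residue '", setdiff(ch[!known], "X")[[1]],
         "' for this profile's alphabet", call. = FALSE)
  out[known, ] <- t(lo2[, idx[known], drop = FALSE])
  out
}

#' Align a query locally against a profile HMM
#'
#' Viterbi local alignment (free entry into and exit from any match state).
#' After the best-scoring hit is found its query interval is masked and the
#' alignment is repeated, up to `maxHits` times, while hits keep scoring at
#' least `threshold` bits -- this yields the multiple non-overlapping hits
#' per domain that consensus merging stitches together.  Hits spanning fewer
#' than `minLength` query residues are discarded (very short local matches
#' are uninformative).
#'
#' @param profile a [ProfileHMM-class].
#' @param seq query amino-acid sequence, already reduced to the profile's
#'   alphabet ('X' is allowed and scores as background).
#' @param modelName name recorded in the returned hits.
#' @param threshold reporting threshold in bits (default 8).
#' @param minLength minimum hit span in query residues (default 5).
#' @param maxHits maximum number of masking iterations (default 4).
#' @param labels optional IMGT labels per match state (attached to the path).
#' @param mask optional logical vector (length nchar(seq)): TRUE positions
#'   are excluded from any alignment.
#' @return list of [DomainHit-class], ordered by decreasing bit score;
#'   empty list when nothing reaches the threshold.
#' @export
viterbiAlign <- function(profile, seq, modelName = "model", threshold = 8,
                         minLength = 5, maxHits = 4, labels = NULL,
                         mask = NULL) {
  stopifnot(is(profile, "ProfileHMM"))
  L <- nchar(seq)
  if (L == 0L) return(list())
  if (is.null(mask)) mask <- rep(FALSE, L)
  stopifnot(length(mask) == L)
  if (is.null(labels)) labels <- as.character(seq_len(profile@nMatch))
  lo <- .queryLogOdds(profile, seq)
  tr <- lapply(profile@transitions, log2)
  hits <- list()
  for (iter in seq_len(maxHits)) {
    if (all(mask)) break
    res <- igp_viterbi(lo, tr$mm, tr$mi, tr$md, tr$im, tr$ii, tr$dm, tr$dd,
                       mask)
    if (res$score < threshold || nrow(res$path) == 0L) break
    qpos <- res$path[, 1L]                       # 0-based
    span <- c(min(qpos), max(qpos) + 1L)
    mask[(span[1] + 1L):span[2]] <- TRUE         # mask regardless of keep
    if (span[2] - span[1] < minLength) next
    state <- ifelse(res$path[, 2L] == 0L, "M", "I")
    lab <- ifelse(state == "M", labels[res$path[, 3L] + 1L], NA_character_)
    odds <- ifelse(state == "M", lo[cbind(qpos + 1L, res$path[, 3L] + 1L)], 0)
    hit <- new("DomainHit", modelName = modelName, bitScore = res$score,
               start = as.integer(span[1]), end = as.integer(span[2]),
               path = data.frame(qpos = as.integer(qpos), state = state,
                                 label = lab, odds = odds,
                                 stringsAsFactors = FALSE))
    hits[[length(hits) + 1L]] <- hit
  }
  hits[order(vapply(hits, function(h) h@bitScore, numeric(1)),
             decreasing = TRUE)]
}

# ---- profile serialization: self-describing text, bit-exact round trip ----

.fmt17 <- function(x) sprintf("%.17g", x)

#' Write a profile HMM as self-describing text
#'
#' The format has a version line, the alphabet, background, one `EMIT` line
#' per match state and one `TRANS` line per junction, all numbers printed
#' with 17 significant digits so [readProfile()] restores them bit-exactly.
#'
#' @param profile a [ProfileHMM-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(profile, path) {
  con <- file(path, "w"); on.exit(close(con))
  M <- profile@nMatch
  writeLines(c(
    "IGPROFILE 1",
    paste("ALPH", profile@alphabetSize),
    paste("SYMS", paste(profile@symbols, collapse = " ")),
    paste("NMATCH", M),
    paste("BG", paste(.fmt17(profile@background), collapse = " "))), con)
  for (m in seq_len(M))
    writeLines(paste("EMIT", m,
                     paste(.fmt17(profile@matchEmis[m, ]), collapse = " ")),
               con)
  tr <- profile@transitions
  for (j in seq_len(max(M - 1L, 0L)))
    writeLines(paste("TRANS", j, paste(.fmt17(c(
      tr$mm[j], tr$mi[j], tr$md[j], tr$im[j], tr$ii[j], tr$dm[j], tr$dd[j])),
      collapse = " ")), con)
  writeLines("END", con)
  invisible(path)
}

#' Read a profile HMM written by [writeProfile()]
#'
#' @param path profile text file.
#' @return a [ProfileHMM-class], bit-identical to the one written.
#' @export
readProfile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^IGPROFILE 1", lines[[1]]))
    stop("not an igprofile profile file: ", path, call. = FALSE)
  field <- function(tag) {
    ln <- grep(paste0("^", tag, " "), lines, value = TRUE)[[1]]
    strsplit(sub(paste0("^", tag, " "), "", ln), " +")[[1]]
  }
  alph <- as.integer(field("ALPH"))
  syms <- field("SYMS")
  M <- as.integer(field("NMATCH"))
  bg <- as.numeric(field("BG"))
  emis <- matrix(0, M, length(syms), dimnames = list(NULL, syms))
  for (ln in grep("^EMIT ", lines, value = TRUE)) {
    f <- strsplit(ln, " +")[[1]]
    emis[as.integer(f[[2]]), ] <- as.numeric(f[-(1:2)])
  }
  tr <- list(mm = numeric(0), mi = numeric(0), md = numeric(0),
             im = numeric(0), ii = numeric(0), dm = numeric(0),
             dd = numeric(0))
  if (M > 1L) {
    tmat <- matrix(0, M - 1L, 7L)
    for (ln in grep("^TRANS ", lines, value = TRUE)) {
      f <- strsplit(ln, " +")[[1]]
      tmat[as.integer(f[[2]]), ] <- as.numeric(f[-(1:2)])
    }
    tr <- list(mm = tmat[, 1], mi = tmat[, 2], md = tmat[, 3],
               im = tmat[, 4], ii = tmat[, 5], dm = tmat[, 6],
               dd = tmat[, 7])
  }
  new("ProfileHMM", nMatch = M, alphabetSize = alph, symbols = syms,
      matchEmis = emis, background = bg, transitions = tr)
}

#' @describeIn ProfileHMM-class display summary
#' @param object a ProfileHMM
#' @export
setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM:", object@nMatch, "match states, alphabet size",
      object@alphabetSize, "(", paste(object@symbols, collapse = ""), ")\n")
})

#' @describeIn DomainHit-class display summary
#' @param object a DomainHit
#' @export
setMethod("show", "DomainHit", function(object) {
  lab <- object@path$label[object@path$state == "M"]
  cat(sprintf("DomainHit vs %s: %.1f bits, query [%d,%d), IMGT %s..%s\n",
              object@modelName, object@bitScore, object@start, object@end,
              lab[[1]], lab[[length(lab)]]))
})
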