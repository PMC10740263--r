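#' IMGT unique numbering utilities
#'
#' The IMGT unique numbering scheme assigns every residue of an antibody (or
#' TCR) variable domain a position label between 1 and 128, with conserved
#' anchors Cys 23, Trp 41, Cys 104 and Trp/Phe 118.  Long CDR3 loops receive
#' insertion codes around positions 111/112 (111.1, 111.2, ..., 112.2, 112.1).
#' Labels are represented as character strings throughout the package.
#'
#' @name imgt
#' @keywords internal
NULL

# Region boundaries (IMGT positions, inclusive).  Stated once; used everywhere.
.IMGT_REGIONS <- data.frame(
  region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
  from   = c(1L, 27L, 39L, 56L, 66L, 105L, 118L),
  to     = c(26L, 38L, 55L, 65L, 104L, 117L, 128L),
  stringsAsFactors = FALSE
)

.REGION_ORDER <- .IMGT_REGIONS$region

#' Table of IMGT region boundaries
#'
#' @return A data.frame with columns `region`, `from`, `to` giving the
#'   inclusive IMGT position range of each of the seven variable-domain
#'   regions FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4.
#' @export
#' @examples
#' imgtRegionTable()
imgtRegionTable <- function() .IMGT_REGIONS

#' Numeric sort key for IMGT position labels
#'
#' Plain integer labels compare numerically.  Insertion labels `n.k` sort
#' just after `n` in ascending `k` order, except at the CDR3 pivot: `112.k`
#' labels sort just *before* 112 in descending `k` order, so that the full
#' CDR3 order is 111 < 111.1 < 111.2 < ... < 112.2 < 112.1 < 112.
#'
#' @param labels character vector of IMGT labels (e.g. `"23"`, `"111.3"`).
#' @return numeric vector of the same length; `order(imgtKey(x))` sorts
#'   labels into IMGT order.
#' @export
#' @examples
#' imgtKey(c("111", "111.1", "112.2", "112.1", "112"))
imgtKey <- function(labels) {
  labels <- as.character(labels)
  parts <- strsplit(labels, ".", fixed = TRUE)
  vapply(parts, function(p) {
    base <- as.numeric(p[[1]])
    if (length(p) == 1L) return(base)
    k <- as.numeric(p[[2]])
    if (base == 112) base - k / 1000 else base + k / 1000
  }, numeric(1))
}

# Integer (base) part of a label; insertion labels inherit their base.
.imgtBase <- function(labels) {
  as.integer(sub("\\..*$", "", as.character(labels)))
}

#' Region of an IMGT position label
#'
#' @param labels character vector of IMGT labels.
#' @return character vector of region names (`"FR1"` ... `"FR4"`); insertion
#'   labels belong to the region of their base position.
#' @export
imgtRegion <- function(labels) {
  base <- .imgtBase(labels)
  idx <- findInterval(base, .IMGT_REGIONS$from)
  out <- rep(NA_character_, length(base))
  ok <- idx >= 1L & !is.na(base) & base <= 128L
  out[ok] <- .IMGT_REGIONS$region[idx[ok]]
  out
}

# Occupy `n` of the slots lo..hi with residues, gapping the middle:
# first ceil(n/2) slots from the left, last floor(n/2) from the right.
# This is the IMGT convention for CDR loops shorter than their span.
.middleGapSlots <- function(n, lo, hi) {
  span <- hi - lo + 1L
  stopifnot(n <= span, n >= 0L)
  if (n == 0L) return(integer(0))
  left <- ceiling(n / 2)
  right <- n - left
  c(seq.int(lo, length.out = left),
    if (right > 0L) seq.int(hi - right + 1L, hi) else integer(0))
}

#' Labels for residues falling between two assigned IMGT positions
#'
#' Given `n` query residues lying between two consensus positions `prev` and
#' `nxt`, produce strictly increasing labels for them.  When the bracket spans
#' the CDR3 pivot (base of `prev` <= 111 and base of `nxt` >= 112) the IMGT
#' CDR3 rule applies: free integer positions are filled middle-gapped for
#' short stretches, and stretches longer than the available integers receive
#' insertion codes 111.1, 111.2, ... then ..., 112.2, 112.1 before 112.
#' Elsewhere free integers are used left to right and any overflow gets
#' ascending insertion codes on the last integer position (or on `prev`).
#'
#' @param prev,nxt flanking IMGT labels (character).
#' @param n number of residues to label.
#' @return character vector of `n` labels, strictly increasing under
#'   [imgtKey()] and strictly between `prev` and `nxt`.
#' @export
#' @examples
#' imgtGapLabels("104", "118", 13)  # a full-length CDR3: 105..117
#' imgtGapLabels("104", "118", 16)  # ultralong: insertion codes at 111/112
imgtGapLabels <- function(prev, nxt, n) {
  n <- as.integer(n)
  if (n <= 0L) return(character(0))
  kPrev <- imgtKey(prev)
  kNxt <- imgtKey(nxt)
  if (kNxt <= kPrev) stop("flanking labels out of order: ", prev, " >= ", nxt)
  ints <- seq.int(floor(kPrev) + 1L, ceiling(kNxt) - 1L)
  ints <- ints[ints > kPrev & ints < kNxt]
  cdr3 <- .imgtBase(prev) <= 111L && .imgtBase(nxt) >= 112L
  if (cdr3) {
    if (n <= length(ints)) {
      return(as.character(ints[.middleGapSlots(n, 1L, length(ints))]))
    }
    # extra residues alternate between the two sides starting at 112.1,
    # so the 112 side takes the odd one out
    extra <- n - length(ints)
    nRight <- ceiling(extra / 2)
    nLeft <- extra - nRight
    lo <- ints[ints <= 111L]
    hi <- ints[ints >= 112L]
    c(as.character(lo),
      paste0("111.", seq_len(nLeft)),
      if (nRight > 0L) paste0("112.", rev(seq_len(nRight))) else character(0),
      as.character(hi))
  } else {
    if (n <= length(ints)) return(as.character(ints[seq_len(n)]))
    extra <- n - length(ints)
    anchor <- if (length(ints)) max(ints) else .imgtBase(prev)
    # continue numbering if prev is itself an insertion on the anchor
    k0 <- 0L
    if (grepl("\\.", prev) && .imgtBase(prev) == anchor)
      k0 <- as.integer(sub("^.*\\.", "", prev))
    c(as.character(ints), paste0(anchor, ".", k0 + seq_len(extra)))
  }
}

#' Labels occupied by a CDR3 of a given length
#'
#' Convenience wrapper for a CDR3 bracketed by the conserved Cys 104 and
#' Trp/Phe 118: returns the IMGT labels of an `n`-residue CDR3.
#'
#' @param n CDR3 length in residues (>= 0, no upper bound).
#' @return character vector of `n` labels.
#' @export
cdr3Labels <- function(n) imgtGapLabels("104", "118", n)
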