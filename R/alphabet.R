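# The 20 standard amino acids, alphabetical one-letter codes.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Hierarchical residue grouping after Li, Fan, Wang & Wang (2003),
# Protein Engineering 16:323-330, who cluster the 20 amino acids by
# physicochemical similarity into 2..19 groups.  Transcribed once; the merge
# order below reproduces the widely reproduced Li et al. partitions at small
# group counts, e.g.
#   k=5: [CMFWY] [LIV] [G] [ATS] [NQDEHKRP]
#   k=4: [CMFWY] [LIV] [GATS] [NQDEHKRP]
#   k=3: [CMFWYLIV] [GATS] [NQDEHKRP]
# Each entry merges the group containing the first letter with the group
# containing the second; the merged listing keeps the first-named group's
# members first, so the group representative (first member) is stable.
.LI_MERGES <- list(
  c("I", "V"),   # -> 19 groups
  c("L", "I"),   # -> 18
  c("F", "W"),   # -> 17
  c("F", "Y"),   # -> 16
  c("M", "F"),   # -> 15
  c("C", "M"),   # -> 14
  c("A", "T"),   # -> 13
  c("A", "S"),   # -> 12
  c("K", "R"),   # -> 11
  c("H", "K"),   # -> 10
  c("D", "E"),   # -> 9
  c("N", "Q"),   # -> 8
  c("D", "H"),   # -> 7
  c("N", "D"),   # -> 6
  c("N", "P"),   # -> 5
  c("G", "A"),   # -> 4
  c("C", "L")    # -> 3
)

.liGroups <- function(size) {
  groups <- as.list(.AA20)
  for (m in .LI_MERGES[seq_len(20L - size)]) {
    ia <- which(vapply(groups, function(g) m[[1]] %in% g, logical(1)))
    ib <- which(vapply(groups, function(g) m[[2]] %in% g, logical(1)))
    groups[[ia]] <- c(groups[[ia]], groups[[ib]])
    groups <- groups[-ib]
  }
  groups
}

#' Get a reduced amino-acid alphabet
#'
#' Returns the Li et al. (2003) residue grouping with `size` groups.  The 20
#' standard amino acids are mapped onto the first member letter of their
#' group; size 20 is the identity mapping (no reduction).
#'
#' @param size integer group count, between 3 and 20.
#' @return a [ReducedAlphabet-class] object.  The result is deterministic:
#'   every call with the same `size` returns identical content.
#' @export
#' @examples
#' getAlphabet(20)  # identity
#' a8 <- getAlphabet(8)
#' length(unique(a8@mapping))  # 8
getAlphabet <- function(size) {
  if (length(size) != 1L || is.na(size) || size != as.integer(size) ||
      size < 3 || size > 20)
    stop("invalid alphabet size ", deparse(substitute(size)),
         ": supported sizes are 3 to 20", call. = FALSE)
  size <- as.integer(size)
  groups <- .liGroups(size)
  mapping <- character(0)
  for (g in groups) mapping[g] <- g[[1]]
  mapping <- mapping[.AA20]
  new("ReducedAlphabet", size = size, mapping = mapping,
      name = paste0("li-", size))
}

#' Apply a reduced alphabet to an amino-acid sequence
#'
#' Replaces each standard amino-acid letter by its group representative.
#' The characters `X` (unknown), `*` (stop) and `-` (gap) pass through
#' unchanged; lowercase input is uppercased first.  Output length always
#' equals input length, and reducing an already-reduced sequence with the
#' same alphabet is a no-op.
#'
#' @param seq character scalar or vector of amino-acid sequences.
#' @param alphabet a [ReducedAlphabet-class], e.g. from [getAlphabet()].
#' @return reduced sequence(s), same shape as `seq`.
#' @export
#' @examples
#' reduceSequence("ACDEFGHIKLMNPQRSTVWY", getAlphabet(8))
reduceSequence <- function(seq, alphabet) {
  stopifnot(is(alphabet, "ReducedAlphabet"))
  lut <- c(alphabet@mapping, X = "X", `*` = "*", `-` = "-")
  vapply(toupper(as.character(seq)), function(s) {
    if (is.na(s)) stop("sequence is NA", call. = FALSE)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- lut[ch]
    if (anyNA(out)) {
      bad <- which(is.na(out))[[1]]
      stop("invalid residue '", ch[[bad]], "' at position ", bad, call. = FALSE)
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# size of each group, named by representative (background composition weights)
.alphabetGroupSizes <- function(alphabet) {
  tab <- table(alphabet@mapping)
  sizes <- as.numeric(tab)
  names(sizes) <- names(tab)
  sizes
}

#' @describeIn ReducedAlphabet-class display summary
#' @param object a ReducedAlphabet
#' @export
setMethod("show", "ReducedAlphabet", function(object) {
  cat("ReducedAlphabet", object@name, "with", object@size, "groups\n")
  reps <- unique(object@mapping)
  for (r in reps) {
    members <- names(object@mapping)[object@mapping == r]
    cat(" ", r, "<- {", paste(members, collapse = ""), "}\n")
  }
})
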