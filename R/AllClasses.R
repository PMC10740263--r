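#' @import methods
NULL

setClassUnion("ListOrNULL", c("list", "NULL"))

#' ReducedAlphabet: a grouping of the 20 amino acids
#'
#' A surjective mapping from the 20 standard amino acids onto `size` group
#' representative letters, following the hierarchical residue groupings of
#' Li, Fan, Wang & Wang (2003, Protein Engineering 16:323-330).  Size 20 is
#' the identity.  The representative of a group is the first member in the
#' documented group listing, so applying the mapping to its own range is the
#' identity.
#'
#' @slot size integer group count, 3..20.
#' @slot mapping named character vector; names are the 20 amino-acid letters,
#'   values the group representative letters.
#' @slot name text tag, e.g. `"li-16"`.
#' @export
setClass("ReducedAlphabet",
  representation(size = "integer", mapping = "character", name = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@mapping) != 20L ||
        !setequal(names(object@mapping), .AA20))
      msg <- c(msg, "mapping must have the 20 standard amino acids as names")
    if (length(unique(object@mapping)) != object@size)
      msg <- c(msg, "mapping must have exactly `size` distinct values")
    reps <- unique(object@mapping)
    if (!all(object@mapping[reps] == reps))
      msg <- c(msg, "group representatives must map to themselves")
    if (length(msg)) msg else TRUE
  })

#' ModelAlignment: an IMGT-labelled rectangular multiple alignment
#'
#' Rows are V x J permutation sequences (row ids `"Vid|Jid"`); columns carry
#' IMGT position labels, strictly increasing under [imgtKey()].
#'
#' @slot rows named character vector of equal-length aligned rows ('-' gaps).
#' @slot labels character vector of per-column IMGT labels.
#' @slot regions character vector of per-column region names.
#' @export
setClass("ModelAlignment",
  representation(rows = "character", labels = "character",
                 regions = "character"),
  validity = function(object) {
    msg <- character(0)
    w <- unique(nchar(object@rows))
    if (length(w) > 1L) msg <- c(msg, "rows are not all the same length")
    ncol <- if (length(object@rows)) nchar(object@rows[[1]]) else 0L
    if (length(object@labels) != ncol)
      msg <- c(msg, "one IMGT label per column required")
    if (length(object@regions) != ncol)
      msg <- c(msg, "one region per column required")
    if (ncol > 1L && any(diff(imgtKey(object@labels)) <= 0))
      msg <- c(msg, "column labels must be strictly increasing in IMGT order")
    if (length(msg)) msg else TRUE
  })

#' ProfileHMM: a trained profile hidden Markov model
#'
#' Match-state emission distributions over the (possibly reduced) amino-acid
#' alphabet, background (insert) emissions, and Plan7-style transition
#' distributions per inter-match junction.  All probabilities are strictly
#' positive (Laplace pseudocounts) and each distribution sums to 1.
#'
#' @slot nMatch number of match states.
#' @slot alphabetSize alphabet size the model was trained in.
#' @slot symbols group representative letters (emission columns).
#' @slot matchEmis nMatch x K matrix of match emission probabilities.
#' @slot background length-K background (insert) emission probabilities.
#' @slot transitions list of numeric vectors `mm, mi, md, im, ii, dm, dd`,
#'   each of length nMatch - 1 (junction j is between match j and j+1).
#' @export
setClass("ProfileHMM",
  representation(nMatch = "integer", alphabetSize = "integer",
                 symbols = "character", matchEmis = "matrix",
                 background = "numeric", transitions = "list"),
  validity = function(object) {
    msg <- character(0)
    M <- object@nMatch
    if (nrow(object@matchEmis) != M)
      msg <- c(msg, "matchEmis must have one row per match state")
    if (ncol(object@matchEmis) != length(object@symbols))
      msg <- c(msg, "matchEmis must have one column per symbol")
    if (any(object@matchEmis <= 0) || any(object@background <= 0))
      msg <- c(msg, "all probabilities must be strictly positive")
    if (M > 0L && any(abs(rowSums(object@matchEmis) - 1) > 1e-9))
      msg <- c(msg, "match emissions must sum to 1")
    if (abs(sum(object@background) - 1) > 1e-9)
      msg <- c(msg, "background must sum to 1")
    tr <- object@transitions
    need <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
    if (!all(need %in% names(tr))) {
      msg <- c(msg, "transitions must contain mm, mi, md, im, ii, dm, dd")
    } else if (M > 1L) {
      if (any(vapply(tr[need], length, 1L) != M - 1L))
        msg <- c(msg, "each transition vector must have nMatch - 1 entries")
      else {
        sums <- tr$mm + tr$mi + tr$md
        if (any(abs(sums - 1) > 1e-9)) msg <- c(msg, "M transitions must sum to 1")
        if (any(abs(tr$im + tr$ii - 1) > 1e-9)) msg <- c(msg, "I transitions must sum to 1")
        if (any(abs(tr$dm + tr$dd - 1) > 1e-9)) msg <- c(msg, "D transitions must sum to 1")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' ProfileModel: a registered annotation model
#'
#' The unit stored in the model registry: a trained [ProfileHMM-class]
#' together with its match-column IMGT labels, region map, alphabet size and
#' build provenance.
#'
#' @slot name registry name.
#' @slot alphabetSize alphabet size queries are reduced to before alignment.
#' @slot profile the trained [ProfileHMM-class].
#' @slot columnLabels IMGT label of each match state.
#' @slot columnRegions region of each match state.
#' @slot anchorConservation named numeric: fraction of training rows carrying
#'   the canonical residue at each conserved anchor present in the model.
#' @slot provenance list of build parameters and input digests.
#' @export
setClass("ProfileModel",
  representation(name = "character", alphabetSize = "integer",
                 profile = "ProfileHMM", columnLabels = "character",
                 columnRegions = "character", anchorConservation = "numeric",
                 provenance = "list"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@columnLabels) != object@profile@nMatch)
      msg <- c(msg, "one IMGT label per match state required")
    if (length(object@columnRegions) != object@profile@nMatch)
      msg <- c(msg, "one region per match state required")
    if (!grepl("^[A-Za-z0-9_.-]+$", object@name))
      msg <- c(msg, "model name must match [A-Za-z0-9_.-]+")
    if (length(msg)) msg else TRUE
  })

#' DomainHit: one local alignment of a query to a profile
#'
#' @slot modelName model the hit comes from.
#' @slot bitScore alignment score in bits.
#' @slot start,end 0-based half-open query interval.
#' @slot path data.frame with columns `qpos` (0-based query index, strictly
#'   increasing), `state` (`"M"` or `"I"`) and `label` (IMGT label for match
#'   states, NA for inserts).
#' @export
setClass("DomainHit",
  representation(modelName = "character", bitScore = "numeric",
                 start = "integer", end = "integer", path = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    p <- object@path
    if (!all(c("qpos", "state", "label") %in% names(p)))
      msg <- c(msg, "path needs columns qpos, state, label")
    else {
      if (nrow(p) > 1L && any(diff(p$qpos) <= 0))
        msg <- c(msg, "path query indices must be strictly increasing")
      if (nrow(p) && (min(p$qpos) < object@start || max(p$qpos) >= object@end))
        msg <- c(msg, "path query indices must lie within [start, end)")
      lab <- p$label[p$state == "M"]
      if (length(lab) > 1L && any(diff(imgtKey(lab)) <= 0))
        msg <- c(msg, "IMGT labels along the path must be strictly increasing")
    }
    if (length(msg)) msg else TRUE
  })

#' ConsensusNumbering: merged per-residue IMGT assignment
#'
#' The consensus extracted from one or more [DomainHit-class] alignments of
#' the same domain: every covered query residue carries exactly one IMGT
#' label, strictly increasing under the CDR3-insertion comparator.
#'
#' @slot entries data.frame with columns `qpos` (0-based, strictly
#'   increasing), `label`, `residue`.
#' @slot modelName model the consensus was built against.
#' @slot sourceHits list of the merged [DomainHit-class] objects.
#' @slot findings character vector of merge findings (e.g. "ambiguous_merge").
#' @export
setClass("ConsensusNumbering",
  representation(entries = "data.frame", modelName = "character",
                 sourceHits = "list", findings = "character"),
  validity = function(object) {
    msg <- character(0)
    e <- object@entries
    if (!all(c("qpos", "label", "residue") %in% names(e)))
      msg <- c(msg, "entries needs columns qpos, label, residue")
    else if (nrow(e) > 1L) {
      if (any(diff(e$qpos) <= 0))
        msg <- c(msg, "entry query indices must be strictly increasing")
      if (any(diff(imgtKey(e$label)) <= 0))
        msg <- c(msg, "entry IMGT labels must be strictly increasing")
    }
    if (length(msg)) msg else TRUE
  })

#' AnnotationResult: the per-query outcome of annotation
#'
#' @slot queryId query record id.
#' @slot status `"annotated"` or `"rejected"`.
#' @slot rejectReasons machine-readable reason codes for rejected queries.
#' @slot modelName chosen model ("" when none matched).
#' @slot bitScore summed bit score over the merged hits.
#' @slot numbering the [ConsensusNumbering-class], or NULL when rejected early.
#' @slot regions data.frame with columns `region`, `start`, `end`,
#'   `sequence` (0-based half-open query coordinates), FR1..FR4 order.
#' @slot frame translation frame tag ("+1".."-3") for nucleotide input, or NA.
#' @slot origId original (pre-translation) record id, or the query id.
#' @export
setClass("AnnotationResult",
  representation(queryId = "character", status = "character",
                 rejectReasons = "character", modelName = "character",
                 bitScore = "numeric", numbering = "ANY",
                 regions = "data.frame", frame = "character",
                 origId = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!object@status %in% c("annotated", "rejected"))
      msg <- c(msg, "status must be 'annotated' or 'rejected'")
    if (object@status == "annotated" && nrow(object@regions) == 0L)
      msg <- c(msg, "annotated results must carry regions")
    if (length(msg)) msg else TRUE
  })
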