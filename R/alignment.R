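#' Germline alignment construction
#'
#' A model alignment is generated from the permutation of all V x J germline
#' pairs: each row is one V sequence concatenated with one J sequence, gapped
#' into IMGT-labelled columns.  V segments are anchored by their two conserved
#' cysteines (assigned IMGT 23 and 104) and the conserved Trp (IMGT 41); J
#' segments by the conserved Trp/Phe (IMGT 118).  Residues between anchors
#' are spread per the standard IMGT V-domain gapping (CDR loops shorter than
#' their span are gapped in the middle).
#'
#' @name alignment
#' @keywords internal
NULL

# accept named character, AAStringSet, or data.frame(id, sequence)
.asNamedSeqs <- function(x, what) {
  if (is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  if (is.data.frame(x)) x <- setNames(x$sequence, x$id)
  x <- setNames(toupper(as.character(x)), names(x))
  if (length(x) == 0L) stop("empty ", what, " input: at least one ", what,
                            " segment is required", call. = FALSE)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " sequences must be named (FASTA ids)", call. = FALSE)
  if (any(!nzchar(x))) stop(what, " sequences must be non-empty", call. = FALSE)
  x
}

# Label the residues of a degapped germline (or germline-like) sequence with
# IMGT positions.  mode "V": V segment (Cys23 .. Cys104, optional short CDR3
# stub after 104).  mode "J": J segment (optional CDR3 tail, Trp/Phe 118,
# FR4 to <= 128).  mode "VJ": a full-domain sequence (used when re-deriving
# labels for imported aligned FASTA rows).
.labelResidues <- function(seq, id, mode = c("V", "J", "VJ")) {
  mode <- match.arg(mode)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  fail <- function(...) stop("cannot assign IMGT positions to segment '", id,
                             "': ", ..., call. = FALSE)
  if (mode == "J") {
    cand <- which(ch %in% c("W", "F") & (L - seq_len(L)) <= 10L)
    if (!length(cand)) fail("no Trp/Phe J anchor (IMGT 118) found")
    a <- cand[[1]]
    nb <- a - 1L
    if (nb > 13L) fail("too many residues before the J anchor")
    na <- L - a
    if (118L + na > 128L) fail("J segment extends past IMGT 128")
    return(as.character(c(if (nb > 0L) seq.int(117L - nb + 1L, 117L),
                          118L, if (na > 0L) seq.int(119L, 118L + na))))
  }
  # V-side anchors
  win <- intersect(10:34, seq_len(L))
  cys1 <- win[ch[win] == "C"]
  if (!length(cys1)) fail("no conserved Cys (IMGT 23) found near the start")
  cys1 <- cys1[order(abs(cys1 - 23L), cys1)][[1]]
  wwin <- intersect((cys1 + 12L):(cys1 + 22L), seq_len(L))
  trp <- wwin[ch[wwin] == "W"]
  if (!length(trp)) fail("no conserved Trp (IMGT 41) found")
  trp <- trp[order(abs(trp - (cys1 + 18L)), trp)][[1]]
  jAnchor <- NA_integer_
  if (mode == "VJ") {
    cand <- which(ch %in% c("W", "F") & (L - seq_len(L)) <= 10L)
    if (!length(cand)) fail("no Trp/Phe J anchor (IMGT 118) found")
    jAnchor <- max(cand)
  }
  cysCand <- which(ch == "C" & seq_len(L) >= trp + 10L)
  if (mode == "VJ") cysCand <- cysCand[cysCand < jAnchor]
  if (!length(cysCand)) fail("no conserved Cys (IMGT 104) found")
  cys2 <- max(cysCand)

  nb <- cys1 - 1L
  if (nb > 22L) fail("more than 22 residues before Cys 23")
  n2 <- trp - cys1 - 1L
  if (n2 < 5L || n2 > 17L) fail("CDR1 stretch between Cys 23 and Trp 41 ",
                                "does not fit IMGT 24-40 (", n2, " residues)")
  n3 <- cys2 - trp - 1L
  if (n3 < 52L || n3 > 62L) fail("stretch between Trp 41 and Cys 104 ",
                                 "does not fit IMGT 42-103 (", n3, " residues)")
  labels <- c(
    if (nb > 0L) as.character(seq.int(23L - nb, 22L)),
    "23",
    as.character(24:26),
    as.character(.middleGapSlots(n2 - 5L, 27L, 38L)),
    as.character(39:40),
    "41",
    as.character(42:55),
    as.character(.middleGapSlots(n3 - 52L, 56L, 65L)),
    as.character(66:103),
    "104")
  if (mode == "V") {
    stub <- L - cys2
    if (stub > 0L) {
      if (104L + stub > 116L) fail("V segment extends too far past Cys 104")
      labels <- c(labels, as.character(seq.int(105L, 104L + stub)))
    }
    return(labels)
  }
  # VJ: CDR3 between Cys 104 and the J anchor, then FR4
  nCdr3 <- jAnchor - cys2 - 1L
  na <- L - jAnchor
  if (118L + na > 128L) fail("J side extends past IMGT 128")
  c(labels, cdr3Labels(nCdr3), "118",
    if (na > 0L) as.character(seq.int(119L, 118L + na)))
}

#' Build an IMGT-labelled alignment from V and J germline sets
#'
#' Generates one row per ordered (V, J) pair -- `|V| x |J|` rows in total.
#' Each row is the V sequence concatenated with the J sequence, placed into
#' IMGT-labelled columns; columns in which every row is a gap do not occur
#' (the column set is the union of per-row labels).
#'
#' @param vSeqs,jSeqs named character vectors (or `AAStringSet`, or
#'   data.frames with `id` and `sequence`) of V- and J-region amino-acid
#'   germline sequences.
#' @return a [ModelAlignment-class].
#' @export
#' @examples
#' g <- makeGermlineSet(seed = 1, nV = 2, nJ = 2)
#' aln <- buildAlignment(g$V, g$J)
#' length(aln@rows)  # 4
buildAlignment <- function(vSeqs, jSeqs) {
  vSeqs <- .asNamedSeqs(vSeqs, "V")
  jSeqs <- .asNamedSeqs(jSeqs, "J")
  vLab <- lapply(names(vSeqs), function(id)
    .labelResidues(gsub("-", "", vSeqs[[id]], fixed = TRUE), id, "V"))
  names(vLab) <- names(vSeqs)
  jLab <- lapply(names(jSeqs), function(id)
    .labelResidues(gsub("-", "", jSeqs[[id]], fixed = TRUE), id, "J"))
  names(jLab) <- names(jSeqs)

  rowIds <- character(0); rowLabels <- list(); rowSeqs <- list()
  for (v in names(vSeqs)) for (j in names(jSeqs)) {
    lab <- c(vLab[[v]], jLab[[j]])
    if (any(diff(imgtKey(lab)) <= 0))
      stop("cannot assign IMGT positions to pair '", v, "|", j,
           "': V and J labels overlap", call. = FALSE)
    id <- paste0(v, "|", j)
    rowIds <- c(rowIds, id)
    rowLabels[[id]] <- lab
    rowSeqs[[id]] <- paste0(gsub("-", "", vSeqs[[v]], fixed = TRUE),
                            gsub("-", "", jSeqs[[j]], fixed = TRUE))
  }
  allLabels <- unique(unlist(rowLabels))
  allLabels <- allLabels[order(imgtKey(allLabels))]
  rows <- vapply(rowIds, function(id) {
    cells <- rep("-", length(allLabels))
    cells[match(rowLabels[[id]], allLabels)] <-
      strsplit(rowSeqs[[id]], "", fixed = TRUE)[[1]]
    paste(cells, collapse = "")
  }, character(1))
  new("ModelAlignment", rows = rows, labels = allLabels,
      regions = imgtRegion(allLabels))
}

#' Validate a model alignment
#'
#' Checks an alignment before model training.  Findings are classified as
#' `fail` (structural: non-rectangular rows, duplicate row ids, a required
#' region with no occupied columns) or `warn` (conserved anchor columns --
#' IMGT 23, 41, 104, 118 -- where fewer than `anchorMin` of the occupying
#' rows carry the expected residue class; warnings do not fail validation,
#' since target species may be genuinely unusual at the anchors).  CDR3 is
#' not a required region: V x J permutation alignments have no CDR3 columns
#' by construction (V ends at IMGT 104, J starts at 117/118) and CDR3
#' diversity is handled at annotation time.
#'
#' @param aln a [ModelAlignment-class], or a list with elements `rows`
#'   (named character) and `labels` for pre-construction checking.
#' @param anchorMin conservation fraction below which an anchor warning is
#'   raised (default 0.9).
#' @return list with elements `pass` (logical) and `findings` (data.frame
#'   with columns `code`, `level`, `detail`).
#' @export
validateAlignment <- function(aln, anchorMin = 0.9) {
  if (is(aln, "ModelAlignment")) {
    rows <- aln@rows; labels <- aln@labels
  } else {
    rows <- aln$rows; labels <- aln$labels
  }
  findings <- data.frame(code = character(0), level = character(0),
                         detail = character(0), stringsAsFactors = FALSE)
  add <- function(code, level, detail)
    findings <<- rbind(findings, data.frame(code = code, level = level,
                                            detail = detail))
  ncol <- length(labels)
  bad <- names(rows)[nchar(rows) != ncol]
  for (id in bad) add("non_rectangular", "fail", id)
  dup <- unique(names(rows)[duplicated(names(rows))])
  for (id in dup) add("duplicate_row_id", "fail", id)

  if (!length(bad)) {
    mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    occupied <- colSums(mat != "-") > 0L
    regions <- imgtRegion(labels)
    for (r in setdiff(.REGION_ORDER, "CDR3")) {
      if (!any(occupied & regions == r)) add("empty_region", "fail", r)
    }
    anchorClass <- list("23" = "C", "41" = "W", "104" = "C", "118" = c("W", "F"))
    for (a in names(anchorClass)) {
      ci <- match(a, labels)
      if (is.na(ci)) { add("anchor_missing", "warn", a); next }
      col <- mat[, ci]
      col <- col[col != "-"]
      frac <- if (length(col)) mean(col %in% anchorClass[[a]]) else 0
      if (frac < anchorMin)
        add("anchor_conservation", "warn",
            sprintf("%s (%.0f%% conserved)", a, 100 * frac))
    }
  }
  list(pass = !any(findings$level == "fail"), findings = findings)
}

#' Write a model alignment to disk
#'
#' Two dialects: `"stockholm"` stores the IMGT column labels explicitly in a
#' `#=GF IMGT` line (space-separated, one label per column), so a re-import
#' is exact; `"fasta"` writes plain aligned FASTA, from which labels are
#' re-derived at import time by the same anchor-based labelling routine the
#' builder uses.
#'
#' @param aln a [ModelAlignment-class].
#' @param path output file path.
#' @param format `"stockholm"` (default) or `"fasta"`.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path, format = c("stockholm", "fasta")) {
  format <- match.arg(format)
  stopifnot(is(aln, "ModelAlignment"))
  if (format == "stockholm") {
    w <- max(nchar(names(aln@rows)))
    lines <- c("# STOCKHOLM 1.0",
               paste("#=GF IMGT", paste(aln@labels, collapse = " ")),
               sprintf("%-*s %s", w, names(aln@rows), aln@rows),
               "//")
  } else {
    lines <- as.vector(rbind(paste0(">", names(aln@rows)), aln@rows))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Import a model alignment from disk
#'
#' Auto-detects the dialect: files starting with `# STOCKHOLM` are parsed as
#' Stockholm with a mandatory `#=GF IMGT` per-column label line; anything
#' else is treated as aligned FASTA, whose column labels are re-derived by
#' the anchor-based labelling routine used by [buildAlignment()] (rows must
#' be full V(+CDR3)+J domain sequences).  This is the hook for fixing an
#' automatically generated alignment by hand and re-importing it.
#'
#' @param path alignment file.
#' @return a [ModelAlignment-class].
#' @export
importAlignment <- function(path) {
  if (!file.exists(path)) stop("cannot read alignment file: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && grepl("^# STOCKHOLM", lines[[1]]))
    return(.importStockholm(lines, path))
  .importAlignedFasta(path)
}

.importStockholm <- function(lines, path) {
  labLine <- grep("^#=GF IMGT ", lines, value = TRUE)
  if (!length(labLine))
    stop("Stockholm alignment ", path, " lacks the mandatory ",
         "'#=GF IMGT' column label line", call. = FALSE)
  labels <- strsplit(sub("^#=GF IMGT ", "", labLine[[1]]), " +")[[1]]
  seqIdx <- which(!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines)))
  if (!length(seqIdx)) stop("alignment file ", path, " contains 0 records",
                            call. = FALSE)
  rows <- character(0)
  for (i in seqIdx) {
    f <- strsplit(trimws(lines[[i]]), " +")[[1]]
    if (length(f) != 2L)
      stop("parse error in ", path, " at line ", i, ": expected 'id sequence'",
           call. = FALSE)
    rows[f[[1]]] <- toupper(f[[2]])
  }
  if (length(unique(nchar(rows))) != 1L || nchar(rows[[1]]) != length(labels))
    stop("alignment rows in ", path, " are not rectangular or do not match ",
         "the IMGT label line", call. = FALSE)
  new("ModelAlignment", rows = rows, labels = labels,
      regions = imgtRegion(labels))
}

.importAlignedFasta <- function(path) {
  recs <- readFasta(path, molecule = "aa")
  if (nrow(recs) == 0L) stop("alignment file ", path, " contains 0 records",
                             call. = FALSE)
  rows <- setNames(toupper(recs$sequence), recs$id)
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows in ", path, " are not all the same length",
         call. = FALSE)
  ncol <- nchar(rows[[1]])
  colLab <- rep(NA_character_, ncol)
  for (id in names(rows)) {
    ch <- strsplit(rows[[id]], "", fixed = TRUE)[[1]]
    pos <- which(ch != "-")
    lab <- .labelResidues(paste(ch[pos], collapse = ""), id, "VJ")
    clash <- !is.na(colLab[pos]) & colLab[pos] != lab
    if (any(clash))
      stop("row '", id, "' assigns IMGT label ", lab[which(clash)[[1]]],
           " to a column previously labelled ", colLab[pos][which(clash)[[1]]],
           call. = FALSE)
    colLab[pos] <- lab
  }
  keep <- !is.na(colLab)
  rows <- vapply(rows, function(s)
    paste(strsplit(s, "", fixed = TRUE)[[1]][keep], collapse = ""),
    character(1))
  labels <- colLab[keep]
  if (any(diff(imgtKey(labels)) <= 0))
    stop("derived column labels of ", path, " are not in IMGT order",
         call. = FALSE)
  new("ModelAlignment", rows = rows, labels = labels,
      regions = imgtRegion(labels))
}

#' @describeIn ModelAlignment-class display summary
#' @param object a ModelAlignment
#' @export
setMethod("show", "ModelAlignment", function(object) {
  cat("ModelAlignment:", length(object@rows), "rows x",
      length(object@labels), "IMGT-labelled columns\n")
  if (length(object@labels))
    cat("  IMGT span:", object@labels[[1]], "..",
        object@labels[[length(object@labels)]], "\n")
  counts <- table(factor(object@regions, levels = .REGION_ORDER))
  cat("  columns per region:",
      paste(names(counts), counts, sep = "=", collapse = " "), "\n")
})
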