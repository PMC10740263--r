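#' Sequence input/output
#'
#' FASTA in (amino acid or nucleotide, auto-detected), annotated FASTA and
#' BED out, six-frame translation and stop-codon filtering for nucleotide
#' input.  FASTA parsing is backed by Biostrings.
#'
#' @name seqio
#' @keywords internal
NULL

#' Read a FASTA file
#'
#' Record ids are the first whitespace-delimited header token; the remainder
#' is kept as the description.  The molecule type is auto-detected per
#' record (>= 90% of characters in ACGTUN- means nucleotide) unless forced.
#'
#' @param path FASTA file, plain or gzip-compressed.
#' @param molecule `"auto"` (default), `"aa"` or `"nt"` to force detection.
#' @return data.frame with columns `id`, `description`, `sequence`,
#'   `molecule`, in file order; zero rows for an empty file.
#' @export
readFasta <- function(path, molecule = c("auto", "aa", "nt")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("cannot read FASTA file: ", path, call. = FALSE)
  # contract check Biostrings does not report: sequence before first header
  head <- readLines(path, n = 50L, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(head)))
  if (length(nonEmpty) && !startsWith(trimws(head[[nonEmpty[[1]]]]), ">"))
    stop("malformed FASTA in ", path, ": sequence before first header ",
         "at line ", nonEmpty[[1]], call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    return(data.frame(id = character(0), description = character(0),
                      sequence = character(0), molecule = character(0),
                      stringsAsFactors = FALSE))
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (any(!nzchar(seqs)))
    stop("empty sequence for record '", id[!nzchar(seqs)][[1]], "' in ",
         path, call. = FALSE)
  mol <- if (molecule == "auto") {
    vapply(seqs, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      if (mean(ch %in% c("A", "C", "G", "T", "U", "N", "-")) >= 0.9)
        "nt" else "aa"
    }, character(1), USE.NAMES = FALSE)
  } else rep(molecule, length(seqs))
  data.frame(id = id, description = desc, sequence = unname(seqs),
             molecule = mol, stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector, or a data.frame with `id`,
#'   `sequence` and optionally `description`.
#' @param path output path.
#' @param width line width (default 60).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 60) {
  if (is.data.frame(seqs)) {
    headers <- ifelse(nzchar(seqs$description %||% ""),
                      paste(seqs$id, seqs$description), seqs$id)
    seqv <- seqs$sequence
  } else {
    headers <- names(seqs)
    seqv <- as.character(seqs)
  }
  lines <- unlist(lapply(seq_along(seqv), function(k) {
    s <- seqv[[k]]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", headers[[k]]), substring(s, starts, starts + width - 1L))
  }))
  writeLines(as.character(lines %||% character(0)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.FRAME_TAGS <- c("+1", "+2", "+3", "-1", "-2", "-3")

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1, +2, +3 on the sequence and -1, -2, -3 on the reverse
#' complement; standard genetic code, trailing partial codons dropped, stop
#' codons rendered `*`, ambiguous codons (N) rendered `X`.  A non-IUPAC
#' nucleotide character raises an error (callers reject the record).
#'
#' @param seq nucleotide sequence (character scalar).
#' @param id record id; frame records are suffixed `"/frame+1"` etc.
#' @return data.frame of exactly 6 rows with columns `id`, `frame`,
#'   `sequence`.
#' @export
#' @examples
#' sixFrameTranslate("ATGGCC")$sequence  # "MA" "W" "G" "GH" "A" "P"
sixFrameTranslate <- function(seq, id = "seq") {
  .sixFrameTranslateSet(setNames(as.character(seq), id))[, c("id", "frame",
                                                             "sequence")]
}

# vectorised six-frame translation of a whole record set (one Biostrings
# call per frame); caller handles invalid-nucleotide rejection per record
.sixFrameTranslateSet <- function(seqs) {
  seqs <- setNames(toupper(gsub("\\s", "", as.character(seqs))), names(seqs))
  d <- Biostrings::DNAStringSet(seqs)  # errors on non-IUPAC characters
  rc <- Biostrings::reverseComplement(d)
  one <- function(x, off) {
    w <- Biostrings::width(x)
    n <- 3L * pmax((w - off) %/% 3L, 0L)
    out <- rep("", length(x))
    ok <- n > 0L
    if (any(ok))
      out[ok] <- as.character(Biostrings::translate(
        Biostrings::subseq(x[ok], off + 1L, (off + n)[ok]),
        if.fuzzy.codon = "solve", no.init.codon = TRUE))
    out
  }
  frames <- c(lapply(0:2, function(f) one(d, f)),
              lapply(0:2, function(f) one(rc, f)))
  do.call(rbind, lapply(seq_along(seqs), function(k)
    data.frame(origId = names(seqs)[[k]],
               id = paste0(names(seqs)[[k]], "/frame", .FRAME_TAGS),
               frame = .FRAME_TAGS,
               sequence = vapply(frames, `[[`, "", k),
               stringsAsFactors = FALSE)))
}

#' Drop records containing a stop codon
#'
#' Removes every amino-acid record whose sequence contains `*`; the number
#' of dropped records is reported as a message.
#'
#' @param records data.frame with a `sequence` column, or named character.
#' @return the filtered records, same shape as the input.
#' @export
filterStops <- function(records) {
  seqs <- if (is.data.frame(records)) records$sequence else records
  keep <- !grepl("*", seqs, fixed = TRUE)
  if (any(!keep))
    message(sum(!keep), " record(s) containing a stop codon removed")
  if (is.data.frame(records)) records[keep, , drop = FALSE]
  else records[keep]
}

# BED score: integer-rounded bit score, capped to 0..1000
.bedScore <- function(bits) {
  if (is.na(bits)) return(0L)
  max(0L, min(1000L, as.integer(round(bits))))
}

#' Write annotation results as BED6
#'
#' One line per region of every annotated result: query id, 0-based start,
#' half-open end, region name, integer-rounded bit score (capped 0-1000) and
#' strand (`-`, with the original nucleotide read id, when the annotated
#' frame was a reverse frame).  Lines are grouped by query with regions in
#' FR1..FR4 order; rejected results emit no lines.  The file is written
#' atomically: on failure no partial file is left behind.
#'
#' @param results list of [AnnotationResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(results, path) {
  lines <- unlist(lapply(results, function(r) {
    if (r@status != "annotated") return(character(0))
    strand <- if (!is.na(r@frame) && startsWith(r@frame, "-")) "-" else "+"
    id <- if (!is.na(r@frame)) r@origId else r@queryId
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", id, r@regions$start, r@regions$end,
            r@regions$region, .bedScore(r@bitScore), strand)
  }))
  tmp <- paste0(path, ".tmp")
  ok <- tryCatch({ writeLines(as.character(lines %||% character(0)), tmp)
                   TRUE },
                 error = function(e) { unlink(tmp); stop(e) })
  if (!file.rename(tmp, path)) { unlink(tmp)
    stop("cannot write BED file to ", path, call. = FALSE) }
  invisible(path)
}

#' Write region sequences of annotation results as FASTA
#'
#' Headers have the form `id|region|start-end|model`; sequences are exactly
#' the region substrings.  The selector `"full"` emits the whole spanned
#' domain substring (first to last annotated residue).
#'
#' @param results list of [AnnotationResult-class].
#' @param path output path.
#' @param which character vector of region selectors: any of FR1..FR4,
#'   CDR1..CDR3, `"full"`.
#' @return `path`, invisibly.
#' @export
writeFastaRegions <- function(results, path, which = "full") {
  valid <- c(.REGION_ORDER, "full")
  if (!all(which %in% valid))
    stop("unknown region selector: ", setdiff(which, valid)[[1]],
         call. = FALSE)
  recs <- list()
  for (r in results) {
    if (r@status != "annotated") next
    reg <- r@regions
    for (w in which) {
      if (w == "full") {
        start <- min(reg$start); end <- max(reg$end)
        seqtxt <- paste(reg$sequence, collapse = "")
      } else {
        row <- reg[reg$region == w, ]
        start <- row$start; end <- row$end; seqtxt <- row$sequence
      }
      if (!nzchar(seqtxt)) next
      hdr <- sprintf("%s|%s|%d-%d|%s", r@queryId, w, start, end, r@modelName)
      recs[[hdr]] <- seqtxt
    }
  }
  tmp <- paste0(path, ".tmp")
  ok <- tryCatch({
    writeFasta(unlist(recs) %||% character(0), tmp); TRUE
  }, error = function(e) { unlink(tmp); stop(e) })
  if (!file.rename(tmp, path)) { unlink(tmp)
    stop("cannot write FASTA file to ", path, call. = FALSE) }
  invisible(path)
}
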