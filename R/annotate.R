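#' Consensus annotation of antibody sequences
#'
#' The annotation pipeline: reduce the query with each model's alphabet,
#' align it against every model, select the best-matching model, merge the
#' (possibly multiple) domain hits into one consensus IMGT numbering --
#' stitching ultralong CDR3 loops across hits with insertion codes, with no
#' length cap -- validate the consensus against heuristics derived from the
#' model, and cut the seven FR/CDR regions.
#'
#' @name annotator
#' @keywords internal
NULL

#' Annotation configuration
#'
#' All tunables of the annotation pipeline with their defaults.
#'
#' @param bitThreshold minimum hit score in bits (default 8).
#' @param minHitLength minimum hit span in query residues (default 5).
#' @param maxHits maximum masking iterations per query per model (default 4).
#' @param mergeMargin bits by which one of two conflicting hits must dominate
#'   to be preferred silently (default 1; below it the earlier-starting hit
#'   is kept and an `ambiguous_merge` finding recorded).
#' @param frCoverage minimum fraction of each FR1-FR3 model column set the
#'   consensus must cover (default 0.8).
#' @param anchorConservation model conservation above which the Cys-23/104
#'   anchors are checked in the query (default 0.9; mismatch is a warning).
#' @param minSpan minimum total matched query residues (default 20; shorter
#'   inputs fail alignment rather than being force-annotated).
#' @param domainScoreFloor a dropped incompatible hit scoring at least this
#'   many bits signals a second domain and rejects the query as
#'   `multiple_domains` (default 40).
#' @param bestFrame for nucleotide input, keep only the best-scoring frame
#'   per original read (default TRUE).
#' @param workers default worker count for [annotateBatch()] (default 1).
#' @return a named list of settings (class `igpConfig`).
#' @export
annotationConfig <- function(bitThreshold = 8, minHitLength = 5, maxHits = 4,
                             mergeMargin = 1, frCoverage = 0.8,
                             anchorConservation = 0.9, minSpan = 20,
                             domainScoreFloor = 40, bestFrame = TRUE,
                             workers = 1) {
  structure(list(bitThreshold = bitThreshold, minHitLength = minHitLength,
                 maxHits = maxHits, mergeMargin = mergeMargin,
                 frCoverage = frCoverage,
                 anchorConservation = anchorConservation, minSpan = minSpan,
                 domainScoreFloor = domainScoreFloor, bestFrame = bestFrame,
                 workers = workers),
            class = "igpConfig")
}

#' Select the best-matching model
#'
#' The model whose best single-hit bit score is maximal wins; ties are broken
#' by total summed hit score, then lexicographic model name.
#'
#' @param hitsByModel named list: model name -> list of [DomainHit-class].
#' @return the winning model name, or `NA_character_` when every hit list is
#'   empty (no match).
#' @export
selectBestModel <- function(hitsByModel) {
  stopifnot(length(hitsByModel) > 0L)
  best <- vapply(hitsByModel, function(h)
    if (length(h)) max(vapply(h, function(x) x@bitScore, numeric(1))) else -Inf,
    numeric(1))
  tot <- vapply(hitsByModel, function(h)
    if (length(h)) sum(vapply(h, function(x) x@bitScore, numeric(1))) else -Inf,
    numeric(1))
  if (all(!is.finite(best))) return(NA_character_)
  ord <- order(-best, -tot, names(hitsByModel))
  names(hitsByModel)[ord[[1]]]
}

# label range of a hit under the IMGT comparator
.hitLabelRange <- function(hit) {
  lab <- hit@path$label[hit@path$state == "M"]
  range(imgtKey(lab))
}

#' Merge domain hits into a consensus IMGT numbering
#'
#' The consensus is the maximum-agreement subset of all per-residue IMGT
#' assignments made by the hits: over the pooled match entries
#' `(query index, IMGT label)` of every hit, the algorithm selects the
#' heaviest subsequence that is strictly increasing in both query index and
#' IMGT order.  Each entry weighs 1 residue; ties break towards entries from
#' higher-scoring hits, and stretches of unassigned residues between chosen
#' entries are lightly penalised *except* when the flanking labels bracket
#' the CDR3 pivot (<= 111 on the left, >= 112 on the right), so arbitrarily
#' long CDR3 loops are free but spurious single-column matches that would
#' open a long gap elsewhere lose.  This resolves conflicting hits at
#' residue resolution: a stray conserved-column match at the edge of one hit
#' is outvoted by the hit that aligns the full region.
#'
#' Unassigned residues between consecutive chosen entries are then
#' labelled: CDR3-bracketing gaps receive the IMGT CDR3 insertion labels
#' (free integers 105..117, then 111.1, 111.2, ..., 112.2, 112.1), with no
#' upper bound on CDR3 length; other gaps use free integer positions and
#' overflow gets ascending insertion codes on the preceding position.
#'
#' @param hits non-empty list of [DomainHit-class] from one model.
#' @param query the full query sequence (original residues; annotation may
#'   have run on a reduced copy).
#' @param config an [annotationConfig()] list.
#' @return a [ConsensusNumbering-class].  Findings: a hit that loses more
#'   than half of its assignments to the consensus adds `multiple_domains`
#'   when it scores >= `config$domainScoreFloor` bits (a second,
#'   non-mergeable domain), or `ambiguous_merge` when its score is within
#'   `config$mergeMargin` bits of the best conflicting hit.
#' @export
mergeHits <- function(hits, query, config = annotationConfig()) {
  stopifnot(length(hits) > 0L)
  scores <- vapply(hits, function(h) h@bitScore, numeric(1))
  pool <- do.call(rbind, lapply(seq_along(hits), function(k) {
    p <- hits[[k]]@path
    if (!"odds" %in% names(p)) p$odds <- 0
    p <- p[p$state == "M", c("qpos", "label", "odds")]
    p$hit <- k
    p
  }))
  pool <- pool[order(pool$qpos, -scores[pool$hit]), , drop = FALSE]
  key <- imgtKey(pool$label)
  base <- .imgtBase(pool$label)
  n <- nrow(pool)
  # 1 residue each; small terms prefer well-matching entries (emission
  # log-odds) and, last, entries from higher-scoring hits
  w <- 1 + 1e-3 * pool$odds + 1e-9 * scores[pool$hit]
  gapPenalty <- 0.01                    # per unassigned non-CDR3 residue
  dp <- w
  parent <- rep(0L, n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    j <- which(pool$qpos[seq_len(i - 1L)] < pool$qpos[i] &
               key[seq_len(i - 1L)] < key[i])
    if (!length(j)) next
    gap <- pool$qpos[i] - pool$qpos[j] - 1L
    pen <- ifelse(base[j] <= 111L & base[i] >= 112L, 0, gapPenalty * gap)
    cand <- dp[j] - pen
    b <- which.max(cand)
    if (cand[b] > 0) {
      dp[i] <- w[i] + cand[b]
      parent[i] <- j[b]
    }
  }
  sel <- integer(0)
  i <- which.max(dp)
  while (i > 0L) { sel <- c(i, sel); i <- parent[i] }
  chosen <- pool[sel, , drop = FALSE]

  findings <- character(0)
  kept <- table(factor(chosen$hit, levels = seq_along(hits)))
  total <- table(factor(pool$hit, levels = seq_along(hits)))
  retention <- as.numeric(kept) / as.numeric(total)
  bestKept <- max(scores[retention >= 0.5], -Inf)
  for (k in which(retention < 0.5)) {
    if (scores[k] >= config$domainScoreFloor)
      findings <- c(findings, "multiple_domains")
    else if (scores[k] >= bestKept - config$mergeMargin)
      findings <- c(findings, "ambiguous_merge")
  }
  contributing <- which(retention > 0)
  contributing <- contributing[order(vapply(hits[contributing],
                                            function(h) h@start, integer(1)))]

  # label every unassigned residue between consecutive chosen entries
  qch <- strsplit(query, "", fixed = TRUE)[[1]]
  qpos <- chosen$qpos; lab <- chosen$label; src <- rep("match", nrow(chosen))
  outQ <- integer(0); outL <- character(0); outS <- character(0)
  for (k in seq_along(qpos)) {
    outQ <- c(outQ, qpos[k]); outL <- c(outL, lab[k]); outS <- c(outS, src[k])
    if (k == length(qpos)) break
    gapN <- qpos[k + 1L] - qpos[k] - 1L
    if (gapN > 0L) {
      labs <- imgtGapLabels(lab[k], lab[k + 1L], gapN)
      outQ <- c(outQ, qpos[k] + seq_len(gapN))
      outL <- c(outL, labs)
      outS <- c(outS, rep("gap", gapN))
    }
  }
  entries <- data.frame(qpos = outQ, label = outL, residue = qch[outQ + 1L],
                        source = outS, stringsAsFactors = FALSE)
  new("ConsensusNumbering", entries = entries,
      modelName = hits[[1]]@modelName, sourceHits = hits[contributing],
      findings = unique(findings))
}

#' Validate a consensus numbering against its model
#'
#' Heuristic checks derived from the input model: (a) coverage -- at least
#' `frCoverage` of the model's FR1-FR3 match columns present, and FR4
#' present at all; (b) order -- IMGT labels strictly increasing (hard fail);
#' (c) anchors -- Cys expected at IMGT 23 and 104 when the model is >= 90%
#' Cys there (warning only); (d) length -- total matched span of at least
#' `minSpan` query residues.  There is deliberately no upper bound on CDR3
#' length: a cap would reject ultralong (e.g. bovine) CDR3 loops.
#'
#' @param cn a [ConsensusNumbering-class].
#' @param model the [ProfileModel-class] it was built against.
#' @param config an [annotationConfig()] list.
#' @return list with `pass` (logical) and `findings` (data.frame `code`,
#'   `level`, `detail`).
#' @export
validateConsensus <- function(cn, model, config = annotationConfig()) {
  stopifnot(nrow(cn@entries) > 0L)
  findings <- data.frame(code = character(0), level = character(0),
                         detail = character(0), stringsAsFactors = FALSE)
  add <- function(code, level, detail = "")
    findings <<- rbind(findings, data.frame(code = code, level = level,
                                            detail = detail))
  labels <- cn@entries$label
  # (b) order
  if (nrow(cn@entries) > 1L && any(diff(imgtKey(labels)) <= 0))
    add("label_order", "fail")
  # (a) coverage per framework region
  for (r in c("FR1", "FR2", "FR3")) {
    cols <- model@columnLabels[model@columnRegions == r]
    if (!length(cols)) next
    frac <- mean(cols %in% labels)
    if (frac < config$frCoverage)
      add("low_coverage", "fail", sprintf("%s (%.0f%%)", r, 100 * frac))
  }
  fr4 <- model@columnLabels[model@columnRegions == "FR4"]
  if (length(fr4) && !any(fr4 %in% labels)) add("low_coverage", "fail", "FR4")
  # (c) anchors
  for (a in c("23", "104")) {
    cons <- model@anchorConservation[a]
    if (!is.na(cons) && cons >= config$anchorConservation) {
      res <- cn@entries$residue[labels == a]
      if (length(res) && res != "C")
        add("anchor_mismatch", "warn", paste0("IMGT ", a, " is ", res))
    }
  }
  # (d) matched span
  nMatched <- if ("source" %in% names(cn@entries))
    sum(cn@entries$source == "match") else nrow(cn@entries)
  if (nMatched < config$minSpan)
    add("short_span", "fail", paste0(nMatched, " matched residues"))
  list(pass = !any(findings$level == "fail"), findings = findings)
}

#' Cut the seven FR/CDR regions out of a consensus
#'
#' Each consensus entry is assigned to its region through the IMGT boundary
#' table; a region's query interval is the min..max+1 of its entries.  A
#' region with no entries (e.g. a zero-length CDR3) is emitted with
#' start == end at the boundary between its neighbours, so the seven
#' intervals always partition the spanned query substring.
#'
#' @param cn a [ConsensusNumbering-class].
#' @param query the query sequence.
#' @return data.frame with columns `region`, `start`, `end` (0-based
#'   half-open), `sequence`, in FR1..FR4 order.
#' @export
extractRegions <- function(cn, query) {
  e <- cn@entries
  reg <- imgtRegion(e$label)
  out <- data.frame(region = .REGION_ORDER, start = NA_integer_,
                    end = NA_integer_, sequence = "", stringsAsFactors = FALSE)
  for (k in seq_along(.REGION_ORDER)) {
    q <- e$qpos[reg == .REGION_ORDER[k]]
    if (length(q)) {
      out$start[k] <- min(q)
      out$end[k] <- max(q) + 1L
    }
  }
  # place empty regions at the boundary of their neighbours
  for (k in seq_along(.REGION_ORDER)) {
    if (!is.na(out$start[k])) next
    prevEnd <- rev(out$end[seq_len(k - 1L)])
    prevEnd <- prevEnd[!is.na(prevEnd)]
    if (length(prevEnd)) {
      out$start[k] <- out$end[k] <- prevEnd[[1]]
    } else {
      nxt <- out$start[k:nrow(out)]
      nxt <- nxt[!is.na(nxt)]
      out$start[k] <- out$end[k] <- if (length(nxt)) nxt[[1]] else 0L
    }
  }
  out$sequence <- substring(query, out$start + 1L, out$end)
  out
}

# build a rejected result
.rejected <- function(id, reasons, modelName = "", bitScore = NA_real_,
                      numbering = NULL, frame = NA_character_, origId = id) {
  new("AnnotationResult", queryId = id, status = "rejected",
      rejectReasons = reasons, modelName = modelName, bitScore = bitScore,
      numbering = numbering, regions = data.frame(), frame = frame,
      origId = origId)
}

#' Annotate one amino-acid query
#'
#' Runs the full pipeline against a set of models: per-model alphabet
#' reduction, local HMM alignment with iterative masking, best-model
#' selection, consensus merging, heuristic validation and region extraction.
#'
#' @param query amino-acid sequence (character scalar).
#' @param models a [ProfileModel-class] or list of them.
#' @param config an [annotationConfig()] list.
#' @param id query id recorded in the result.
#' @return an [AnnotationResult-class]; rejections carry machine-readable
#'   reason codes (`invalid_sequence`, `no_hit`, `multiple_domains`,
#'   `low_coverage`, `short_span`, `label_order`).
#' @export
#' @examples
#' g <- makeGermlineSet(seed = 1, nV = 2, nJ = 2)
#' aln <- buildAlignment(g$V, g$J)
#' model <- buildModel(aln, "toy", registry = tempfile(), overwrite = TRUE)
#' res <- annotate(paste0(g$V[[1]], "AKDRSTY", g$J[[1]]), model, id = "q1")
#' regions(res)
annotate <- function(query, models, config = annotationConfig(),
                     id = "query") {
  if (is(models, "ProfileModel")) models <- list(models)
  stopifnot(length(models) > 0L)
  names(models) <- vapply(models, function(m) m@name, character(1))
  query <- toupper(as.character(query))
  if (is.na(query) || !nzchar(query) ||
      grepl(paste0("[^", paste(.AA20, collapse = ""), "X]"), query))
    return(.rejected(id, "invalid_sequence"))
  hitsByModel <- lapply(models, function(m) {
    reduced <- reduceSequence(query, getAlphabet(m@alphabetSize))
    viterbiAlign(m@profile, reduced, modelName = m@name,
                 threshold = config$bitThreshold,
                 minLength = config$minHitLength, maxHits = config$maxHits,
                 labels = m@columnLabels)
  })
  bestName <- selectBestModel(hitsByModel)
  if (is.na(bestName)) return(.rejected(id, "no_hit"))
  model <- models[[bestName]]
  cn <- mergeHits(hitsByModel[[bestName]], query, config)
  if ("multiple_domains" %in% cn@findings)
    return(.rejected(id, "multiple_domains", modelName = bestName,
                     numbering = cn))
  rep <- validateConsensus(cn, model, config)
  score <- sum(vapply(cn@sourceHits, function(h) h@bitScore, numeric(1)))
  if (!rep$pass)
    return(.rejected(id, unique(rep$findings$code[rep$findings$level == "fail"]),
                     modelName = bestName, bitScore = score, numbering = cn))
  regions <- extractRegions(cn, query)
  new("AnnotationResult", queryId = id, status = "annotated",
      rejectReasons = character(0), modelName = bestName, bitScore = score,
      numbering = cn, regions = regions, frame = NA_character_, origId = id)
}

#' Annotate a batch of records
#'
#' Pure per-record computation distributed over `workers` forked processes;
#' output order equals input order and results are identical for any worker
#' count.  A failure inside one record's computation rejects that record
#' with reason `internal_error` and the batch continues.
#'
#' @param records named character vector of amino-acid sequences, or a
#'   data.frame with `id` and `sequence` columns (e.g. from [readFasta()]).
#' @param models a [ProfileModel-class] or list of them.
#' @param config an [annotationConfig()] list.
#' @param workers number of parallel workers (default `config$workers`).
#' @return list of [AnnotationResult-class], one per input record, in input
#'   order.
#' @export
annotateBatch <- function(records, models, config = annotationConfig(),
                          workers = config$workers) {
  if (is.data.frame(records)) records <- setNames(records$sequence, records$id)
  if (!length(records)) return(list())
  ids <- names(records)
  if (is.null(ids)) ids <- paste0("seq", seq_along(records))
  one <- function(k) {
    tryCatch(annotate(records[[k]], models, config, id = ids[[k]]),
             error = function(e) .rejected(ids[[k]], "internal_error"))
  }
  if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(records), one, mc.cores = workers)
  } else {
    lapply(seq_along(records), one)
  }
}

#' Annotate nucleotide records through the six-frame protocol
#'
#' Each record is translated into all six reading frames; frames containing
#' a stop codon are removed, surviving frames are annotated, and (with
#' `config$bestFrame`, the default) only the highest-scoring annotated frame
#' is kept per original read.  Frame ties break in the order +1, +2, +3,
#' -1, -2, -3.  A record whose frames are all removed or all unannotated is
#' rejected (`no_frame` / `no_hit`); invalid nucleotides reject the record
#' with `invalid_nucleotide`.
#'
#' @param records named character vector of nucleotide sequences, or a
#'   data.frame with `id` and `sequence`.
#' @param models a [ProfileModel-class] or list of them.
#' @param config an [annotationConfig()] list.
#' @param workers number of parallel workers.
#' @return list of [AnnotationResult-class]: one per original record with
#'   `bestFrame`, otherwise one per surviving frame.  Results carry the
#'   translated-frame id as `queryId`, the original read id as `origId` and
#'   the frame tag in `frame`.
#' @export
annotateNucleotide <- function(records, models, config = annotationConfig(),
                               workers = config$workers) {
  if (is.data.frame(records)) records <- setNames(records$sequence, records$id)
  ids <- names(records)
  valid <- grepl("^[ACGTUNRYSWKMBDHV]*$", toupper(gsub("\\s", "", records))) &
    nzchar(records)
  frames <- if (any(valid))
    .sixFrameTranslateSet(records[valid]) else NULL
  if (!is.null(frames)) {
    keep <- !grepl("*", frames$sequence, fixed = TRUE) &
      nzchar(frames$sequence)
    frames <- frames[keep, , drop = FALSE]
    res <- annotateBatch(setNames(frames$sequence, frames$id), models,
                         config, workers = workers)
    for (j in seq_along(res)) {
      res[[j]]@frame <- frames$frame[[j]]
      res[[j]]@origId <- frames$origId[[j]]
    }
  } else res <- list()
  byOrig <- split(res, factor(frames$origId, levels = ids[valid]))
  out <- list()
  for (id in ids) {
    if (!valid[[match(id, ids)]]) {
      out[[length(out) + 1L]] <- .rejected(id, "invalid_nucleotide")
      next
    }
    grp <- byOrig[[id]]
    if (!length(grp)) {
      out[[length(out) + 1L]] <- .rejected(id, "no_frame")
      next
    }
    if (isTRUE(config$bestFrame)) {
      annotated <- vapply(grp, function(r) r@status == "annotated", logical(1))
      out[[length(out) + 1L]] <- if (any(annotated)) {
        cand <- grp[annotated]
        cand[[which.max(vapply(cand, function(r) r@bitScore, numeric(1)))]]
      } else .rejected(id, "no_hit")
    } else {
      out <- c(out, grp)
    }
  }
  out
}

# ---- result accessors & show ----

#' Accessors for annotation results
#'
#' @param x an [AnnotationResult-class]
#' @return `regions()`: the region data.frame; `annotationStatus()`:
#'   "annotated" or "rejected"; `rejectReasons()`: reason codes;
#'   `bitScore()`: the summed bit score; `numbering()`: the
#'   [ConsensusNumbering-class].
#' @export
regions <- function(x) x@regions

#' @rdname regions
#' @export
annotationStatus <- function(x) x@status

#' @rdname regions
#' @export
rejectReasons <- function(x) x@rejectReasons

#' @rdname regions
#' @export
bitScore <- function(x) x@bitScore

#' @rdname regions
#' @export
numbering <- function(x) x@numbering

#' @describeIn AnnotationResult-class display summary
#' @param object an AnnotationResult
#' @export
setMethod("show", "AnnotationResult", function(object) {
  if (object@status == "annotated") {
    cat(sprintf("AnnotationResult '%s': annotated by %s (%.1f bits)\n",
                object@queryId, object@modelName, object@bitScore))
    r <- object@regions
    cat(paste(sprintf("  %-4s [%3d,%3d) %s", r$region, r$start, r$end,
                      r$sequence), collapse = "\n"), "\n")
  } else {
    cat(sprintf("AnnotationResult '%s': rejected (%s)\n", object@queryId,
                paste(object@rejectReasons, collapse = ", ")))
  }
})

#' @describeIn ConsensusNumbering-class display summary
#' @param object a ConsensusNumbering
#' @export
setMethod("show", "ConsensusNumbering", function(object) {
  e <- object@entries
  cat("ConsensusNumbering vs", object@modelName, "-", nrow(e), "residues,",
      length(object@sourceHits), "hit(s)\n")
  if (nrow(e))
    cat("  query", min(e$qpos), "..", max(e$qpos), " IMGT", e$label[[1]],
        "..", e$label[[nrow(e)]], "\n")
})
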