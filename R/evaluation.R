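#' Read a gold-standard annotation file
#'
#' Gold standards use the same TSV layout as annotations
#' (\code{\link{readAnnotations}}); the \code{window_id} column is ignored
#' for matching, which is by exact character offsets and concept id only.
#'
#' @param path TSV file path.
#' @return A data.frame of unique gold entries.
#' @export
readGoldStandard <- function(path) {
  gold <- readAnnotations(path)
  key <- paste(gold$doc_id, gold$start, gold$end, gold$concept_id,
               sep = "\r")
  gold[!duplicated(key), , drop = FALSE]
}

#' Label records as true or false positives by exact matching
#'
#' A record is a true positive iff its (doc_id, start, end, concept) —
#' identical offsets and identical concept id — appears in the gold
#' standard. When a graph is supplied, alternative ids on both sides are
#' resolved to canonical ids first (gold standards maintained across
#' ontology releases often carry alt ids). Partial span overlap never
#' counts.
#'
#' @param records scored (or raw) mention records.
#' @param gold gold-standard data.frame (\code{\link{readGoldStandard}}).
#' @param graph optional \code{\linkS4class{OntologyGraph}} for alt-id
#'   resolution.
#' @return \code{records} with a logical \code{tp} column.
#' @export
labelExact <- function(records, gold, graph = NULL) {
  canonRec <- records$concept_id
  canonGold <- gold$concept_id
  if (!is.null(graph)) {
    canonRec <- resolveTermId(graph, canonRec)
    canonGold <- resolveTermId(graph, canonGold)
  }
  keyRec <- paste(records$doc_id, records$start, records$end, canonRec,
                  sep = "\r")
  keyGold <- paste(gold$doc_id, gold$start, gold$end, canonGold,
                   sep = "\r")
  records$tp <- keyRec %in% keyGold
  records
}

#' Evaluate a validated subset against the full annotation set
#'
#' Computes the evaluation quantities for a subset of the annotations:
#' precision and recall of the subset, the percentage of the full set's
#' true positives it retains (TP ratio), and its precision increase
#' relative to the full set. Both inputs must carry the \code{tp} labels
#' from \code{\link{labelExact}}. The recall denominator is the number of
#' gold entries over the documents of the full annotation set.
#'
#' @param subset labelled records, a subset of \code{baseline}.
#' @param baseline the labelled full annotation set.
#' @param gold gold-standard data.frame.
#' @return An \code{\linkS4class{EvaluationReport}}.
#' @export
evaluateSubset <- function(subset, baseline, gold) {
  if (!("tp" %in% names(subset)) || !("tp" %in% names(baseline)))
    stop("records must carry 'tp' labels; run labelExact() first")
  if (nrow(subset) > nrow(baseline))
    stop("'subset' is larger than 'baseline'")
  goldHere <- gold[gold$doc_id %in% unique(baseline$doc_id), ,
                   drop = FALSE]
  nGold <- nrow(goldHere)
  tpBase <- sum(baseline$tp)
  pBase <- if (nrow(baseline)) 100 * tpBase / nrow(baseline) else NA_real_
  nSub <- nrow(subset)
  tpSub <- sum(subset$tp)
  prec <- if (nSub) 100 * tpSub / nSub else NA_real_
  new("EvaluationReport",
      nAnnotations = as.integer(nSub),
      tp = as.integer(tpSub),
      fp = as.integer(nSub - tpSub),
      precision = prec,
      recall = if (nGold) 100 * tpSub / nGold else NA_real_,
      tpRatio = if (tpBase) 100 * tpSub / tpBase else
        (if (tpSub == 0L) 0 else NA_real_),
      precisionIncrease = if (!is.na(prec) && !is.na(pBase) && pBase > 0)
        100 * (prec - pBase) / pBase else NA_real_,
      baselinePrecision = pBase,
      nGold = as.integer(nGold))
}

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport: ", object@nAnnotations, " annotations (",
      object@tp, " TP, ", object@fp, " FP) vs ", object@nGold,
      " gold entries\n", sep = "")
  fmt <- function(x) if (is.na(x)) "NA" else sprintf("%.2f", x)
  cat("  precision: ", fmt(object@precision), "%  recall: ",
      fmt(object@recall), "%\n", sep = "")
  cat("  TP ratio: ", fmt(object@tpRatio),
      "%  precision increase vs full set: ",
      fmt(object@precisionIncrease), "%\n", sep = "")
})

#' @rdname reportAsList
#' @export
setGeneric("reportAsList", function(x) standardGeneric("reportAsList"))

#' Convert an EvaluationReport to a plain list
#'
#' Useful for JSON serialisation (\code{\link{writeEvaluationReport}}).
#'
#' @param x an \code{\linkS4class{EvaluationReport}}.
#' @return A named list of counts and metrics.
#' @name reportAsList
#' @export
setMethod("reportAsList", "EvaluationReport", function(x) {
  list(n_annotations = x@nAnnotations, tp = x@tp, fp = x@fp,
       precision = x@precision, recall = x@recall, tp_ratio = x@tpRatio,
       precision_increase = x@precisionIncrease,
       baseline_precision = x@baselinePrecision, n_gold = x@nGold)
})

#' Write an EvaluationReport as JSON
#'
#' @param report an \code{\linkS4class{EvaluationReport}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEvaluationReport <- function(report, path) {
  jsonlite::write_json(reportAsList(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Precision / TP-ratio curve over validated-fraction thresholds
#'
#' Sweeps the fraction of validated entities over an even grid in (0, 1];
#' at each fraction the top-scoring subset is selected
#' (\code{\link{thresholdForFraction}}) and evaluated. Reference columns
#' give the expected behaviour of a random selection of the same size:
#' constant precision and a TP ratio that decays linearly with the
#' discarded fraction.
#'
#' @param records labelled, scored records (\code{\link{labelExact}}).
#' @param gold gold-standard data.frame.
#' @param nPoints number of grid points.
#' @return data.frame with columns \code{fraction}, \code{threshold},
#'   \code{precision}, \code{recall}, \code{tp_ratio},
#'   \code{random_precision}, \code{random_tp_ratio}.
#' @export
validationCurve <- function(records, gold, nPoints = 20L) {
  if (nrow(records) == 0L)
    stop("'records' must be non-empty")
  if (!("tp" %in% names(records)))
    stop("records must carry 'tp' labels; run labelExact() first")
  fullRep <- evaluateSubset(records, records, gold)
  pBase <- fullRep@baselinePrecision
  fr <- seq_len(nPoints) / nPoints
  rows <- lapply(fr, function(f) {
    sel <- thresholdForFraction(records, f)
    rep <- evaluateSubset(sel$validated, records, gold)
    data.frame(fraction = f, threshold = sel$threshold,
               precision = rep@precision, recall = rep@recall,
               tp_ratio = rep@tpRatio, random_precision = pBase,
               random_tp_ratio = 100 * f)
  })
  do.call(rbind, rows)
}

#' @rdname validationCurve
#' @param curve a curve data.frame from \code{validationCurve}.
#' @param path output TSV path.
#' @export
writeCurve <- function(curve, path) {
  write.table(curve, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Monte-Carlo baseline: true positives lost by random subset selection
#'
#' Simulates discarding annotations at random rather than by validation
#' score: draws uniform subsets of size round(fraction * n) from n
#' annotations of which \code{tp} are true positives, and reports the mean
#' percentage of true positives absent from the subset. In expectation a
#' random selection keeping a fraction f of the annotations loses
#' 100 * (1 - f) percent of the true positives (e.g. keeping 75 percent
#' loses 25 percent), which is the reference the validation score must
#' beat.
#'
#' @param n total number of annotations.
#' @param tp number of true positives among them (tp <= n).
#' @param fraction fraction retained, in (0, 1].
#' @param reps number of Monte-Carlo replicates.
#' @param seed RNG seed (required; the only stochastic step in the
#'   pipeline outside the synthetic generator).
#' @return Mean percentage of true positives lost, a single number.
#' @export
randomBaselineSimulation <- function(n, tp, fraction, reps = 1000L,
                                     seed) {
  if (tp > n || tp < 0L || n < 1L)
    stop("need 0 <= tp <= n and n >= 1")
  if (fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]")
  if (reps < 1L)
    stop("'reps' must be positive")
  if (missing(seed))
    stop("'seed' is required")
  set.seed(seed)
  k <- .roundHalfUp(fraction * n)
  if (tp == 0L) return(0)
  lost <- vapply(seq_len(reps), function(r) {
    kept <- sum(sample.int(n, k) <= tp)
    100 * (tp - kept) / tp
  }, numeric(1))
  mean(lost)
}

#' Five-number summaries of validation scores by group
#'
#' Summarises score distributions per annotation source (e.g. gold-derived
#' versus tool-produced annotations) for boxplot-style comparison:
#' minimum, lower quartile, median, upper quartile, maximum
#' (linear-interpolation quantiles).
#'
#' @param records scored records.
#' @param by grouping: the name of a column of \code{records}, or a vector
#'   with one label per record.
#' @return data.frame with columns \code{group}, \code{n}, \code{min},
#'   \code{q1}, \code{median}, \code{q3}, \code{max}.
#' @export
scoreDistributionSummary <- function(records, by) {
  labels <- if (is.character(by) && length(by) == 1L &&
                by %in% names(records)) records[[by]] else by
  if (length(labels) != nrow(records))
    stop("'by' must name a column or give one label per record")
  groups <- split(records$score, labels, drop = FALSE)
  empty <- names(groups)[vapply(groups, length, integer(1)) == 0L]
  if (length(empty))
    stop("empty group(s): ", paste(empty, collapse = ", "))
  rows <- lapply(names(groups), function(g) {
    q <- quantile(groups[[g]], probs = c(0, .25, .5, .75, 1),
                  type = 7, names = FALSE)
    data.frame(group = g, n = length(groups[[g]]), min = q[[1]],
               q1 = q[[2]], median = q[[3]], q3 = q[[4]], max = q[[5]])
  })
  do.call(rbind, rows)
}
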