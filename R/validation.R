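#' Read or write an annotation table
#'
#' Annotations are tab-separated with header columns \code{doc_id},
#' \code{window_id}, \code{start}, \code{end}, \code{text},
#' \code{concept_id}; character offsets are 0-based, half-open; encoding is
#' UTF-8. \code{writeAnnotations} additionally serialises any \code{score}
#' (fixed 6 decimals), \code{best_match} and \code{status} columns produced
#' by scoring.
#'
#' @param path TSV file path.
#' @param mentions a mention data.frame (see above).
#' @return \code{readAnnotations}: a validated mention data.frame.
#'   \code{writeAnnotations}: \code{path}, invisibly.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path))
    stop("annotation file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", fileEncoding = "UTF-8")
  req <- c("doc_id", "window_id", "start", "end", "text", "concept_id")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("annotation file lacks column(s): ", paste(miss, collapse = ", "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if ("score" %in% names(df)) df$score <- as.numeric(df$score)
  checkMentions(df)
  df
}

#' @rdname readAnnotations
#' @export
writeAnnotations <- function(mentions, path) {
  out <- mentions
  if ("score" %in% names(out))
    out$score <- sprintf("%.6f", out$score)
  if ("best_match" %in% names(out))
    out$best_match[is.na(out$best_match)] <- ""
  write.table(out, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, na = "",
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a mention table
#'
#' Checks the structural invariants of an annotation set: required columns,
#' offsets with 0 <= start < end, and uniqueness of
#' (doc_id, start, end, concept_id).
#'
#' @param mentions a mention data.frame.
#' @return \code{mentions}, invisibly; errors describe the first violation.
#' @export
checkMentions <- function(mentions) {
  req <- c("doc_id", "window_id", "start", "end", "text", "concept_id")
  miss <- setdiff(req, names(mentions))
  if (length(miss))
    stop("mention table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(mentions) == 0L) return(invisible(mentions))
  if (any(is.na(mentions$start)) || any(is.na(mentions$end)))
    stop("mention offsets contain NA")
  bad <- mentions$start < 0L | mentions$start >= mentions$end
  if (any(bad))
    stop("invalid offsets (need 0 <= start < end) at row(s): ",
         paste(head(which(bad), 5L), collapse = ", "))
  key <- paste(mentions$doc_id, mentions$start, mentions$end,
               mentions$concept_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (doc_id, start, end, concept_id) at row(s): ",
         paste(head(which(duplicated(key)), 5L), collapse = ", "))
  invisible(mentions)
}

#' Group mentions into text windows
#'
#' The validation score compares each mention with its co-mentions inside a
#' text window. Window membership is taken from the input, never computed
#' here: with \code{granularity = "document"} all mentions of a document
#' form one window; with \code{"window_field"} the precomputed
#' \code{window_id} column (a sentence or paragraph id assigned by the
#' caller's NLP pipeline) subdivides documents.
#'
#' @param mentions a mention data.frame (see \code{\link{readAnnotations}}).
#' @param granularity \code{"document"} or \code{"window_field"}.
#' @return A list of mention data.frames, one per window, each ordered by
#'   \code{start}; every input mention appears in exactly one window.
#' @export
buildWindows <- function(mentions,
                         granularity = c("document", "window_field")) {
  granularity <- match.arg(granularity)
  checkMentions(mentions)
  if (nrow(mentions) == 0L) return(list())
  key <- if (granularity == "document") mentions$doc_id
         else paste(mentions$doc_id, mentions$window_id, sep = "\r")
  idx <- split(seq_len(nrow(mentions)), key)
  idx <- unname(idx[order(names(idx))])
  lapply(idx, function(i) {
    w <- mentions[i, , drop = FALSE]
    w[order(w$start), , drop = FALSE]
  })
}

.aggregate <- function(values, agg) {
  switch(agg,
    max = max(values),
    mean = mean(values),
    top3_mean = mean(sort(values, decreasing = TRUE)[
      seq_len(min(3L, length(values)))]),
    stop("unknown aggregate function: ", agg))
}

#' Score the mentions of one text window
#'
#' For each mention, similarities to every other mention in the window are
#' computed (a mention is never compared with itself; other mentions of the
#' same concept are included by default, so a concept repeated in a window
#' scores maximally). The validation score is the aggregate of that
#' similarity list — the maximum by default, expressing confidence that the
#' mention has at least one semantically related neighbour. Mentions alone
#' in their window score 0 with no best match.
#'
#' @param window one window's mention data.frame (all rows share a window).
#' @param graph an acyclic \code{\linkS4class{OntologyGraph}}.
#' @param ic an \code{\linkS4class{ICTable}}.
#' @param measure \code{"resnik"}, \code{"simui"} or \code{"simgic"}.
#' @param agg aggregate over the similarity list: \code{"max"} (default),
#'   \code{"mean"} or \code{"top3_mean"} (mean of the three largest).
#' @param normalized normalise Resnik by the component maximum IC.
#' @param excludeSameConcept drop same-concept co-mentions from the
#'   similarity list (by default they count, with self-similarity).
#' @return The window data.frame with columns \code{score} (numeric),
#'   \code{best_match} (canonical id of the most similar co-mentioned
#'   concept; ties broken by smallest id; NA when alone) appended.
#' @export
scoreWindow <- function(window, graph, ic,
                        measure = c("resnik", "simui", "simgic"),
                        agg = c("max", "mean", "top3_mean"),
                        normalized = FALSE, excludeSameConcept = FALSE) {
  measure <- match.arg(measure)
  agg <- match.arg(agg)
  n <- nrow(window)
  out <- window
  out$score <- numeric(n)
  out$best_match <- rep(NA_character_, n)
  if (n <= 1L) return(out)
  canon <- tryCatch(.resolveLive(graph, window$concept_id),
                    error = function(e)
                      stop("cannot score window '", window$window_id[[1L]],
                           "' of document '", window$doc_id[[1L]], "': ",
                           conditionMessage(e), call. = FALSE))
  sets <- .ancestorSets(graph, canon)
  f <- .measureFun(measure, ic, normalized)
  uq <- unique(canon)
  S <- matrix(0, length(uq), length(uq), dimnames = list(uq, uq))
  for (i in seq_along(uq))
    for (j in i:length(uq))
      S[i, j] <- S[j, i] <- f(sets[[uq[[i]]]], sets[[uq[[j]]]])
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    if (excludeSameConcept)
      others <- others[canon[others] != canon[[i]]]
    if (!length(others)) next
    sims <- S[canon[[i]], canon[others]]
    out$score[[i]] <- .aggregate(sims, agg)
    top <- canon[others][sims == max(sims)]
    out$best_match[[i]] <- sort(top)[[1L]]
  }
  out
}

#' Score a whole annotation set
#'
#' Groups mentions into windows (\code{\link{buildWindows}}) and scores each
#' window independently (\code{\link{scoreWindow}}). A concept mentioned in
#' two windows receives two independent scores, reflecting its different
#' contexts.
#'
#' @inheritParams scoreWindow
#' @param mentions a mention data.frame.
#' @param granularity window grouping, see \code{\link{buildWindows}}.
#' @param skipUnmapped drop mentions whose concept id does not resolve in
#'   the ontology (with a message) instead of failing.
#' @return One data.frame of scored records (windows concatenated).
#' @export
scoreCorpus <- function(mentions, graph, ic,
                        measure = c("resnik", "simui", "simgic"),
                        agg = c("max", "mean", "top3_mean"),
                        granularity = c("document", "window_field"),
                        normalized = FALSE, excludeSameConcept = FALSE,
                        skipUnmapped = FALSE) {
  measure <- match.arg(measure)
  agg <- match.arg(agg)
  granularity <- match.arg(granularity)
  checkMentions(mentions)
  if (skipUnmapped && nrow(mentions)) {
    ok <- vapply(mentions$concept_id, function(id)
      !inherits(tryCatch(.resolveLive(graph, id), error = identity),
                "error"), logical(1))
    if (any(!ok))
      message("skipping ", sum(!ok),
              " mention(s) with unmapped concept ids")
    mentions <- mentions[ok, , drop = FALSE]
  }
  windows <- buildWindows(mentions, granularity)
  if (!length(windows)) {
    out <- mentions
    out$score <- numeric(0)
    out$best_match <- character(0)
    return(out)
  }
  scored <- lapply(windows, scoreWindow, graph = graph, ic = ic,
                   measure = measure, agg = agg, normalized = normalized,
                   excludeSameConcept = excludeSameConcept)
  out <- do.call(rbind, scored)
  rownames(out) <- NULL
  out
}

#' Partition scored records at an absolute threshold
#'
#' A record is validated when its score is strictly higher than the
#' threshold, otherwise it is an outlier with no significant semantic
#' relationship to any co-mentioned concept. Input order is preserved.
#'
#' @param records scored records from \code{\link{scoreCorpus}}.
#' @param threshold finite numeric threshold.
#' @return \code{records} with a \code{status} column
#'   (\code{"validated"}/\code{"outlier"}).
#' @export
applyThreshold <- function(records, threshold) {
  if (!is.finite(threshold))
    stop("'threshold' must be finite")
  records$status <- ifelse(records$score > threshold,
                           "validated", "outlier")
  records
}

#' Select a validated fraction of the records
#'
#' Instead of an absolute score cut-off, the user may ask for a fraction of
#' the entities to be validated: records are ranked by score (descending;
#' ties resolved by smaller concept id, then doc_id, then start, for full
#' determinism) and exactly \code{round(fraction * N)} top records (half-up
#' rounding) are validated. The reported threshold is the score of the last
#' validated record.
#'
#' @param records scored records from \code{\link{scoreCorpus}}.
#' @param fraction fraction of records to validate, in (0, 1].
#' @return A list with \code{threshold} (score of the k-th record, or
#'   \code{Inf} when k = 0), \code{records} (input order, \code{status}
#'   set), and \code{validated} (the selected subset in rank order).
#' @export
thresholdForFraction <- function(records, fraction) {
  if (nrow(records) == 0L)
    stop("'records' must be non-empty")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]")
  n <- nrow(records)
  k <- .roundHalfUp(fraction * n)
  ord <- order(-records$score, records$concept_id, records$doc_id,
               records$start)
  sel <- ord[seq_len(k)]
  records$status <- "outlier"
  records$status[sel] <- "validated"
  thr <- if (k == 0L) Inf else records$score[[sel[[k]]]]
  list(threshold = thr, records = records,
       validated = records[sel, , drop = FALSE])
}

# round() in R is round-half-even; the fraction contract uses half-up.
.roundHalfUp <- function(x) as.integer(floor(x + 0.5))
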