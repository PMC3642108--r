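#' @import methods
#' @importFrom stats quantile
#' @importFrom utils read.delim write.table head
NULL

#' OntologyGraph: a typed directed acyclic graph of ontology terms
#'
#' Holds every term parsed from an OBO file together with its typed parent
#' edges. Obsolete terms are retained for identifier resolution but take no
#' part in the graph structure, information content or similarity. The slot
#' \code{allowedRelations} records which relation types currently define the
#' DAG backbone; edges of other types are kept in \code{edges} but ignored by
#' all graph operations (see \code{\link{filterRelations}}).
#'
#' @slot nodes data.frame with columns \code{id}, \code{name},
#'   \code{obsolete} (one row per term, including obsolete terms).
#' @slot edges data.frame with columns \code{child}, \code{parent},
#'   \code{relation}; all typed edges of non-obsolete terms as parsed.
#' @slot altIds named character vector mapping alternative ids to canonical
#'   term ids.
#' @slot allowedRelations character vector of relation types that define the
#'   working graph.
#' @slot dag igraph object over the non-obsolete terms restricted to
#'   \code{allowedRelations}; edges point child -> parent.
#' @slot acyclicChecked logical; TRUE once \code{\link{filterRelations}} has
#'   verified the restricted graph is acyclic.
#'
#' @seealso \code{\link{parseOBO}}, \code{\link{filterRelations}},
#'   \code{\link{termAncestors}}, \code{\link{computeIC}}
#' @exportClass OntologyGraph
setClass("OntologyGraph",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    altIds = "character",
    allowedRelations = "character",
    dag = "ANY",
    acyclicChecked = "logical"
  )
)

setValidity("OntologyGraph", function(object) {
  msgs <- character()
  nd <- object@nodes
  if (!all(c("id", "name", "obsolete") %in% names(nd)))
    msgs <- c(msgs, "nodes must have columns id, name, obsolete")
  else {
    if (anyDuplicated(nd$id))
      msgs <- c(msgs, "duplicated term ids")
    if (any(!nzchar(nd$id)))
      msgs <- c(msgs, "empty term id")
  }
  ed <- object@edges
  if (!all(c("child", "parent", "relation") %in% names(ed)))
    msgs <- c(msgs, "edges must have columns child, parent, relation")
  else if (nrow(ed) > 0L) {
    known <- c(nd$id)
    bad <- setdiff(unique(c(ed$child, ed$parent)), known)
    if (length(bad))
      msgs <- c(msgs, paste0("edges reference unknown term ids: ",
                             paste(head(bad, 5L), collapse = ", ")))
  }
  if (length(object@altIds) && is.null(names(object@altIds)))
    msgs <- c(msgs, "altIds must be a named character vector")
  if (length(msgs)) msgs else TRUE
})

#' ICTable: intrinsic information content of ontology terms
#'
#' Maps each non-obsolete term to its intrinsic information content
#' IC(c) = -log p(c), where p(c) is derived from the ontology structure
#' (descendant counts by default) rather than corpus frequencies. IC is
#' normalised within each weakly connected component, so a sole root of a
#' component has IC 0 and leaves carry the component maximum.
#'
#' @slot ic named numeric vector, term id -> information content (log units).
#' @slot component named integer vector, term id -> component membership.
#' @slot logBase numeric, base of the logarithm used (default e).
#' @slot mode character, "descendants" or "children" (what was counted for
#'   p(c)).
#'
#' @seealso \code{\link{computeIC}}, \code{\link{simResnik}},
#'   \code{\link{simGIC}}
#' @exportClass ICTable
setClass("ICTable",
  representation(
    ic = "numeric",
    component = "integer",
    logBase = "numeric",
    mode = "character"
  )
)

setValidity("ICTable", function(object) {
  msgs <- character()
  if (is.null(names(object@ic)))
    msgs <- c(msgs, "ic must be a named numeric vector")
  if (any(object@ic < -1e-12, na.rm = TRUE))
    msgs <- c(msgs, "information content must be non-negative")
  if (!identical(sort(names(object@ic)), sort(names(object@component))))
    msgs <- c(msgs, "ic and component must be indexed by the same term ids")
  if (length(msgs)) msgs else TRUE
})

#' EvaluationReport: precision/recall of a validated subset
#'
#' Summarises how a validated subset of annotations compares with the full
#' annotation set and the gold standard: true/false positive counts,
#' precision, recall, the percentage of the full set's true positives
#' retained (TP ratio) and the relative precision increase over the full set.
#'
#' @slot nAnnotations integer, size of the subset.
#' @slot tp integer, true positives in the subset (exact matching).
#' @slot fp integer, false positives in the subset.
#' @slot precision numeric, 100 * tp / nAnnotations (NA for an empty subset).
#' @slot recall numeric, 100 * tp / |gold|.
#' @slot tpRatio numeric, 100 * tp / tp(full set).
#' @slot precisionIncrease numeric, 100 * (precision - precision(full set)) /
#'   precision(full set).
#' @slot baselinePrecision numeric, precision of the full set.
#' @slot nGold integer, number of gold-standard entries (recall denominator).
#'
#' @seealso \code{\link{evaluateSubset}}, \code{\link{validationCurve}}
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(
    nAnnotations = "integer",
    tp = "integer",
    fp = "integer",
    precision = "numeric",
    recall = "numeric",
    tpRatio = "numeric",
    precisionIncrease = "numeric",
    baselinePrecision = "numeric",
    nGold = "integer"
  )
)

setValidity("EvaluationReport", function(object) {
  msgs <- character()
  if (object@tp + object@fp != object@nAnnotations)
    msgs <- c(msgs, "tp + fp must equal nAnnotations")
  if (!is.na(object@precision) &&
      (object@precision < 0 || object@precision > 100))
    msgs <- c(msgs, "precision must lie in [0, 100]")
  if (!is.na(object@tpRatio) && (object@tpRatio < 0 || object@tpRatio > 100))
    msgs <- c(msgs, "tpRatio must lie in [0, 100]")
  if (length(msgs)) msgs else TRUE
})
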