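#' Most informative common ancestor (MICA) of two terms
#'
#' Intersects the reflexive ancestor sets of the two terms and returns the
#' common ancestor with maximal information content. Ties are broken by the
#' lexicographically smallest term id for determinism. Terms in different
#' connected components (e.g. a ChEBI Chemical Entity versus a Role) share
#' no ancestors and yield \code{NULL}.
#'
#' @param graph an acyclic \code{\linkS4class{OntologyGraph}}.
#' @param ic an \code{\linkS4class{ICTable}} from \code{\link{computeIC}}.
#' @param c1,c2 term ids (alt ids accepted).
#' @return \code{list(term =, ic =)} or \code{NULL} when no common ancestor
#'   exists.
#' @export
mica <- function(graph, ic, c1, c2) {
  sets <- .ancestorSets(graph, c(c1, c2))
  ids <- .resolveLive(graph, c(c1, c2))
  .micaFromSets(sets[[ids[[1L]]]], sets[[ids[[2L]]]], ic@ic)
}

.micaFromSets <- function(a, b, icv) {
  common <- intersect(a, b)
  if (!length(common)) return(NULL)
  vals <- icv[common]
  top <- common[vals == max(vals)]
  best <- sort(top)[[1L]]
  list(term = best, ic = unname(icv[[best]]))
}

#' Resnik semantic similarity
#'
#' The information content of the two terms' most informative common
#' ancestor. Unnormalised by default (the method's thresholds are
#' rank-based, so the scale is immaterial); with \code{normalized = TRUE}
#' the value is divided by the maximum IC of the shared component, giving a
#' [0,1] range. Pairs with no common ancestor score 0.
#'
#' @inheritParams mica
#' @param normalized divide by the maximum IC of the shared component.
#' @return A non-negative number; \code{simResnik(c, c)} equals IC(c).
#' @seealso \code{\link{simUI}}, \code{\link{simGIC}},
#'   \code{\link{pairwiseSimilarity}}
#' @export
simResnik <- function(graph, ic, c1, c2, normalized = FALSE) {
  m <- mica(graph, ic, c1, c2)
  if (is.null(m)) return(0)
  if (!normalized) return(m$ic)
  compMax <- .componentMaxIC(ic)
  mx <- compMax[[ic@component[[m$term]]]]
  if (mx <= 0) 0 else m$ic / mx
}

.componentMaxIC <- function(ic) {
  vapply(split(ic@ic, ic@component), max, numeric(1))
}

#' simUI semantic similarity
#'
#' The Jaccard index of the two terms' reflexive ancestor sets (each set is
#' all ancestors up to the root, the term itself included): the number of
#' shared ancestors divided by the number of ancestors of either term.
#'
#' @inheritParams mica
#' @return A number in [0, 1]; 1 for a term with itself.
#' @export
simUI <- function(graph, c1, c2) {
  sets <- .ancestorSets(graph, c(c1, c2))
  ids <- .resolveLive(graph, c(c1, c2))
  .simUIFromSets(sets[[ids[[1L]]]], sets[[ids[[2L]]]])
}

.simUIFromSets <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' simGIC semantic similarity
#'
#' An information-content-weighted Jaccard index: the summed IC of the
#' shared ancestors divided by the summed IC of the union of the two
#' reflexive ancestor sets. When the union carries no information (two
#' zero-IC roots), the value is 1 if the ancestor sets are identical and 0
#' otherwise, by continuity with the identical-set case.
#'
#' @inheritParams mica
#' @return A number in [0, 1]; 1 for a term with itself.
#' @export
simGIC <- function(graph, ic, c1, c2) {
  sets <- .ancestorSets(graph, c(c1, c2))
  ids <- .resolveLive(graph, c(c1, c2))
  .simGICFromSets(sets[[ids[[1L]]]], sets[[ids[[2L]]]], ic@ic)
}

.simGICFromSets <- function(a, b, icv) {
  uni <- union(a, b)
  sUni <- sum(icv[uni])
  if (sUni <= 0) return(if (setequal(a, b)) 1 else 0)
  sum(icv[intersect(a, b)]) / sUni
}

# Dispatch table shared by pairwiseSimilarity and the scoring module.
# Returns f(a, b) over precomputed reflexive ancestor sets.
.measureFun <- function(measure, icTab, normalized = FALSE) {
  measure <- match.arg(tolower(measure), c("resnik", "simui", "simgic"))
  icv <- icTab@ic
  switch(measure,
    simui = function(a, b) .simUIFromSets(a, b),
    simgic = function(a, b) .simGICFromSets(a, b, icv),
    resnik = if (normalized) {
      compMax <- .componentMaxIC(icTab)
      comp <- icTab@component
      function(a, b) {
        m <- .micaFromSets(a, b, icv)
        if (is.null(m)) return(0)
        mx <- compMax[[comp[[m$term]]]]
        if (mx <= 0) 0 else m$ic / mx
      }
    } else {
      function(a, b) {
        m <- .micaFromSets(a, b, icv)
        if (is.null(m)) 0 else m$ic
      }
    })
}

#' Pairwise similarity matrix for a list of concepts
#'
#' Computes the full symmetric similarity matrix between all pairs of the
#' given concepts under one measure. Ancestor sets are computed once per
#' distinct concept.
#'
#' @inheritParams mica
#' @param concepts non-empty character vector of term ids (alt ids accepted).
#' @param measure \code{"resnik"}, \code{"simui"} or \code{"simgic"}.
#' @param normalized for Resnik only: normalise by the component maximum IC.
#' @return A symmetric numeric matrix with \code{concepts} as dimnames; the
#'   diagonal holds self-similarities.
#' @export
pairwiseSimilarity <- function(graph, ic, concepts,
                               measure = c("resnik", "simui", "simgic"),
                               normalized = FALSE) {
  measure <- match.arg(measure)
  if (!length(concepts))
    stop("'concepts' must be non-empty")
  canon <- .resolveLive(graph, concepts)
  sets <- .ancestorSets(graph, canon)
  f <- .measureFun(measure, ic, normalized)
  n <- length(concepts)
  M <- matrix(0, n, n, dimnames = list(concepts, concepts))
  for (i in seq_len(n)) {
    for (j in i:n) {
      M[i, j] <- M[j, i] <- f(sets[[canon[[i]]]], sets[[canon[[j]]]])
    }
  }
  M
}
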