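#' @rdname OntologyGraph-accessors
#' @export
setGeneric("termIds", function(x, ...) standardGeneric("termIds"))
#' @rdname OntologyGraph-accessors
#' @export
setGeneric("nTerms", function(x) standardGeneric("nTerms"))
#' @rdname OntologyGraph-accessors
#' @export
setGeneric("ontologyRoots", function(x) standardGeneric("ontologyRoots"))
#' @rdname OntologyGraph-accessors
#' @export
setGeneric("allowedRelations", function(x) standardGeneric("allowedRelations"))

#' Accessors for OntologyGraph objects
#'
#' \code{termIds} returns the ids of non-obsolete terms (all terms with
#' \code{includeObsolete = TRUE}); \code{nTerms} counts non-obsolete terms;
#' \code{ontologyRoots} returns the terms with no parent under the allowed
#' relations; \code{allowedRelations} returns the relation types that define
#' the working DAG.
#'
#' @param x an \code{\linkS4class{OntologyGraph}}.
#' @param includeObsolete logical; also return obsolete term ids.
#' @param ... unused.
#' @return A character vector (ids) or a count.
#' @name OntologyGraph-accessors
NULL

#' @rdname OntologyGraph-accessors
#' @export
setMethod("termIds", "OntologyGraph", function(x, includeObsolete = FALSE) {
  if (includeObsolete) x@nodes$id else x@nodes$id[!x@nodes$obsolete]
})

#' @rdname OntologyGraph-accessors
#' @export
setMethod("nTerms", "OntologyGraph", function(x) sum(!x@nodes$obsolete))

#' @rdname OntologyGraph-accessors
#' @export
setMethod("ontologyRoots", "OntologyGraph", function(x) {
  deg <- igraph::degree(x@dag, mode = "out")
  sort(names(deg)[deg == 0L])
})

#' @rdname OntologyGraph-accessors
#' @export
setMethod("allowedRelations", "OntologyGraph",
          function(x) x@allowedRelations)

setMethod("show", "OntologyGraph", function(object) {
  nLive <- sum(!object@nodes$obsolete)
  nObs <- sum(object@nodes$obsolete)
  live <- igraph::ecount(object@dag)
  cat("OntologyGraph with ", nLive, " terms",
      if (nObs) paste0(" (+", nObs, " obsolete)"), ", ",
      nrow(object@edges), " typed edges (", live,
      " on allowed relations: ",
      paste(object@allowedRelations, collapse = ", "), ")\n", sep = "")
  r <- ontologyRoots(object)
  cat("roots: ", paste(head(r, 5L), collapse = ", "),
      if (length(r) > 5L) ", ...", "\n", sep = "")
})

#' Resolve term identifiers to canonical ids
#'
#' Accepts canonical ids and alternative ids (\code{alt_id} tags) and maps
#' each to its canonical term id. Unknown identifiers raise an error naming
#' them.
#'
#' @param graph an \code{\linkS4class{OntologyGraph}}.
#' @param ids character vector of term or alt ids.
#' @return Character vector of canonical ids, same length as \code{ids}.
#' @export
resolveTermId <- function(graph, ids) {
  ids <- as.character(ids)
  out <- ids
  known <- ids %in% graph@nodes$id
  viaAlt <- !known & ids %in% names(graph@altIds)
  out[viaAlt] <- unname(graph@altIds[ids[viaAlt]])
  bad <- !known & !viaAlt
  if (any(bad))
    stop("unknown term id(s): ", paste(unique(ids[bad]), collapse = ", "))
  out
}

.checkDag <- function(graph) {
  if (graph@acyclicChecked) return(invisible(TRUE))
  if (!igraph::is_dag(graph@dag)) {
    cyc <- .findCycle(graph@dag)
    stop("graph restricted to relations {",
         paste(graph@allowedRelations, collapse = ", "),
         "} contains a directed cycle: ",
         paste(cyc, collapse = " -> "),
         "; use filterRelations() to drop cyclic relation types")
  }
  invisible(TRUE)
}

.findCycle <- function(dag) {
  scc <- igraph::components(dag, mode = "strong")
  big <- which(scc$csize > 1L)
  if (length(big)) {
    members <- names(scc$membership)[scc$membership == big[[1L]]]
    return(c(sort(members), sort(members)[[1L]]))
  }
  loops <- igraph::which_loop(dag)
  if (any(loops)) {
    e <- igraph::ends(dag, igraph::E(dag)[loops][[1L]])
    return(c(e[1L], e[1L]))
  }
  "unlocated cycle"
}

#' Restrict an ontology to a set of relation types
#'
#' Keeps exactly the edges whose relation type is in \code{allowed} and
#' verifies that the result is acyclic. ChEBI ships cyclic relation types
#' (such as "is enantiomer of") that must be removed before ancestor or
#' information-content computations; the default whitelist is the
#' subsumption backbone \code{"is_a"}.
#'
#' @param graph an \code{\linkS4class{OntologyGraph}}.
#' @param allowed non-empty character vector of relation types to keep.
#' @return An \code{\linkS4class{OntologyGraph}} whose working DAG uses only
#'   \code{allowed} edges (verified acyclic).
#' @examples
#' g <- OntologyGraph(c("R", "A", "B"),
#'   data.frame(child = c("A", "B", "A", "B"),
#'              parent = c("R", "R", "B", "A"),
#'              relation = c("is_a", "is_a", "is_enantiomer_of",
#'                           "is_enantiomer_of")))
#' filterRelations(g)   # drops the enantiomer 2-cycle
#' @export
filterRelations <- function(graph, allowed = "is_a") {
  if (!length(allowed) || !all(nzchar(allowed)))
    stop("'allowed' must be a non-empty set of relation types")
  allowed <- unique(as.character(allowed))
  out <- graph
  out@allowedRelations <- allowed
  out@dag <- .buildDag(graph@nodes, graph@edges, allowed)
  out@acyclicChecked <- FALSE
  .checkDag(out)
  out@acyclicChecked <- TRUE
  validObject(out)
  out
}

#' Ancestor set of a term
#'
#' Returns the reflexive-transitive closure of the parent relation restricted
#' to the allowed relation types: the term itself plus every term reachable
#' toward the roots. Alt ids are resolved; obsolete terms have no ancestors
#' and are rejected.
#'
#' @param graph an \code{\linkS4class{OntologyGraph}} (acyclic under its
#'   allowed relations).
#' @param id a single term id (or alt id).
#' @return Character vector of term ids, including \code{id} itself.
#' @export
termAncestors <- function(graph, id) {
  .checkDag(graph)
  id <- .resolveLive(graph, id)
  sort(names(igraph::subcomponent(graph@dag, id, mode = "out")))
}

.resolveLive <- function(graph, ids) {
  ids <- resolveTermId(graph, ids)
  obs <- ids %in% graph@nodes$id[graph@nodes$obsolete]
  if (any(obs))
    stop("obsolete term(s) cannot take part in the graph: ",
         paste(unique(ids[obs]), collapse = ", "))
  ids
}

# Ancestor sets for many terms at once (named list, reflexive).
.ancestorSets <- function(graph, ids) {
  .checkDag(graph)
  ids <- .resolveLive(graph, ids)
  uq <- unique(ids)
  sets <- lapply(uq, function(v)
    names(igraph::subcomponent(graph@dag, v, mode = "out")))
  stats::setNames(sets, uq)
}

#' Intrinsic information content of every term
#'
#' Computes IC(c) = -log p(c) from the ontology structure alone, avoiding
#' any corpus bias: p(c) = (descendants(c) + 1) / N, where descendants(c)
#' counts the distinct proper descendants of c over the allowed relations and
#' N is the number of non-obsolete terms in c's weakly connected component.
#' A component's sole root thus has IC 0 and leaves attain the component
#' maximum. Components are normalised independently, so the sub-ontologies
#' of ChEBI (Chemical Entity, Role, Subatomic Particle) each get their own
#' scale and share no information.
#'
#' @param graph an acyclic \code{\linkS4class{OntologyGraph}}.
#' @param mode \code{"descendants"} (default; all proper descendants) or
#'   \code{"children"} (direct children only).
#' @param logBase base of the logarithm; natural log by default. Resnik
#'   values scale with the base; simGIC is invariant to it.
#' @return An \code{\linkS4class{ICTable}}.
#' @examples
#' g <- OntologyGraph(c("R", "a", "b"),
#'   data.frame(child = c("a", "b"), parent = c("R", "a"),
#'              relation = "is_a"))
#' icTab <- computeIC(g)
#' icValues(icTab)     # IC(R)=0, IC(a)=log(3/2), IC(b)=log(3)
#' @export
computeIC <- function(graph, mode = c("descendants", "children"),
                      logBase = exp(1)) {
  mode <- match.arg(mode)
  .checkDag(graph)
  live <- termIds(graph)
  if (!length(live))
    stop("cannot compute information content of an empty graph")
  comp <- igraph::components(graph@dag, mode = "weak")
  membership <- comp$membership[live]
  N <- comp$csize[membership]
  cnt <- if (mode == "descendants") {
    vapply(live, function(v)
      length(igraph::subcomponent(graph@dag, v, mode = "in")) - 1L,
      integer(1))
  } else {
    igraph::degree(graph@dag, v = live, mode = "in")
  }
  p <- (cnt + 1) / N
  icv <- -log(p) / log(logBase)
  icv[icv < 0] <- 0   # guard against -0 / rounding at p = 1
  new("ICTable", ic = stats::setNames(as.numeric(icv), live),
      component = stats::setNames(as.integer(membership), live),
      logBase = logBase, mode = mode)
}

#' @rdname ICTable-accessors
#' @export
setGeneric("icValues", function(x, ids) standardGeneric("icValues"))

#' Accessors for ICTable objects
#'
#' \code{icValues} returns the information content of every term (or of
#' \code{ids}); \code{icComponents} the component membership used for
#' per-component normalisation.
#'
#' @param x an \code{\linkS4class{ICTable}}.
#' @param ids optional character vector of term ids.
#' @return A named numeric (or integer) vector.
#' @name ICTable-accessors
NULL

#' @rdname ICTable-accessors
#' @export
setMethod("icValues", "ICTable", function(x, ids) {
  if (missing(ids)) return(x@ic)
  bad <- setdiff(ids, names(x@ic))
  if (length(bad))
    stop("no information content for term id(s): ",
         paste(bad, collapse = ", "))
  x@ic[ids]
})

#' @rdname ICTable-accessors
#' @export
setGeneric("icComponents", function(x) standardGeneric("icComponents"))

#' @rdname ICTable-accessors
#' @export
setMethod("icComponents", "ICTable", function(x) x@component)

setMethod("show", "ICTable", function(object) {
  cat("ICTable over ", length(object@ic), " terms in ",
      length(unique(object@component)), " component(s); mode=",
      object@mode, ", log base ", format(object@logBase, digits = 4),
      "\n", sep = "")
  cat("IC range: [", format(min(object@ic), digits = 4), ", ",
      format(max(object@ic), digits = 4), "]\n", sep = "")
})
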