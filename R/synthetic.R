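#' Parameters for the synthetic ontology / corpus generator
#'
#' Bundles the knobs of the synthetic test-bed: a random rooted DAG
#' standing in for an ontology like ChEBI, and an annotation corpus whose
#' true positives are drawn from semantically coherent neighbourhoods
#' (sibling/descendant sets of a per-window seed term, emulating the
#' premise that genuinely mentioned chemicals in one text window are
#' related) while false positives — emulating NER errors with no
#' systematic semantic relation to their context — are drawn uniformly
#' from the whole ontology.
#'
#' @param nTerms number of ontology terms.
#' @param maxChildren cap on direct children per term during growth.
#' @param multiParentProb probability that a new term gets a second parent
#'   (0 yields a tree).
#' @param nDocs number of documents.
#' @param windowsPerDoc text windows per document.
#' @param mentionsPerWindow mentions per window.
#' @param tpFraction fraction of mentions per window that are true
#'   positives (entered into the gold standard).
#' @param tpRelated draw TP concepts from the window seed's neighbourhood
#'   (default); \code{FALSE} gives the adverse-context mode where true
#'   mentions are mutually unrelated, as in mixture-listing sentences.
#' @param seed RNG seed; every generator output is deterministic given it.
#' @return A named list of class \code{"syntheticSpec"}.
#' @export
syntheticSpec <- function(nTerms = 300L, maxChildren = 8L,
                          multiParentProb = 0.1, nDocs = 30L,
                          windowsPerDoc = 5L, mentionsPerWindow = 8L,
                          tpFraction = 0.45, tpRelated = TRUE,
                          seed = 42L) {
  stopifnot(nTerms >= 1L, maxChildren >= 1L, nDocs >= 1L,
            windowsPerDoc >= 1L, mentionsPerWindow >= 1L,
            multiParentProb >= 0, multiParentProb <= 1,
            tpFraction >= 0, tpFraction <= 1)
  structure(list(nTerms = as.integer(nTerms),
                 maxChildren = as.integer(maxChildren),
                 multiParentProb = multiParentProb,
                 nDocs = as.integer(nDocs),
                 windowsPerDoc = as.integer(windowsPerDoc),
                 mentionsPerWindow = as.integer(mentionsPerWindow),
                 tpFraction = tpFraction, tpRelated = isTRUE(tpRelated),
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' Generate a random rooted ontology DAG
#'
#' Grows the graph top-down from a single root: each new term attaches by
#' an \code{is_a} edge to one uniformly chosen existing term (with fewer
#' than \code{maxChildren} children), plus a second distinct parent with
#' probability \code{multiParentProb}. Parents always precede children, so
#' the result is acyclic by construction.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return An \code{\linkS4class{OntologyGraph}} with allowed relation
#'   \code{"is_a"}.
#' @export
generateToyOntology <- function(spec) {
  set.seed(spec$seed)
  n <- spec$nTerms
  ids <- sprintf("T:%07d", seq_len(n))
  child <- character(0); parent <- character(0)
  nKids <- integer(n)
  for (i in seq_len(n)[-1]) {
    eligible <- which(nKids[seq_len(i - 1L)] < spec$maxChildren)
    if (!length(eligible)) eligible <- seq_len(i - 1L)
    p1 <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    parents <- p1
    if (i > 2L && stats::runif(1) < spec$multiParentProb) {
      rest <- setdiff(seq_len(i - 1L), p1)
      p2 <- if (length(rest) == 1L) rest else sample(rest, 1L)
      parents <- c(parents, p2)
    }
    child <- c(child, rep(ids[[i]], length(parents)))
    parent <- c(parent, ids[parents])
    nKids[parents] <- nKids[parents] + 1L
  }
  nodes <- data.frame(id = ids,
                      name = paste("synthetic term", seq_len(n)),
                      obsolete = FALSE, stringsAsFactors = FALSE)
  edges <- data.frame(child = child, parent = parent,
                      relation = rep("is_a", length(child)),
                      stringsAsFactors = FALSE)
  filterRelations(OntologyGraph(nodes, edges), "is_a")
}

# Seed term's semantic neighbourhood: its parents' descendant subtrees
# (siblings and their descendants, the seed included).
.neighbourhood <- function(graph, term) {
  dag <- graph@dag
  parents <- names(igraph::neighbors(dag, term, mode = "out"))
  anchors <- if (length(parents)) parents else term
  unique(unlist(lapply(anchors, function(a)
    names(igraph::subcomponent(dag, a, mode = "in")))))
}

#' Generate a synthetic annotation corpus with a gold standard
#'
#' For every text window a seed term is drawn; the window's true-positive
#' mentions take concepts from the seed's neighbourhood (and are entered
#' into the gold standard with their exact offsets), while false-positive
#' mentions take uniform-random concepts and stay out of the gold
#' standard. Surface text is synthesised from term names and carries no
#' information used by scoring; offsets are consecutive and
#' non-overlapping within each document. Deterministic given
#' \code{spec$seed}.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param graph ontology from \code{\link{generateToyOntology}} (or any
#'   acyclic \code{\linkS4class{OntologyGraph}}).
#' @return \code{list(mentions =, gold =)}, two mention data.frames.
#' @export
generateCorpus <- function(spec, graph) {
  set.seed(spec$seed + 1L)
  allTerms <- termIds(graph)
  nameOf <- stats::setNames(graph@nodes$name, graph@nodes$id)
  nTP <- .roundHalfUp(spec$tpFraction * spec$mentionsPerWindow)
  rows <- vector("list", spec$nDocs * spec$windowsPerDoc)
  ri <- 0L
  for (d in seq_len(spec$nDocs)) {
    docId <- sprintf("doc%03d", d)
    cursor <- 0L
    for (w in seq_len(spec$windowsPerDoc)) {
      winId <- sprintf("w%02d", w)
      seedTerm <- sample(allTerms, 1L)
      pool <- if (spec$tpRelated) .neighbourhood(graph, seedTerm)
              else allTerms
      m <- spec$mentionsPerWindow
      isTP <- c(rep(TRUE, nTP), rep(FALSE, m - nTP))
      concepts <- character(m)
      concepts[isTP] <- sample(pool, nTP, replace = TRUE)
      concepts[!isTP] <- sample(allTerms, m - nTP, replace = TRUE)
      ord <- sample.int(m)            # interleave TPs and FPs
      concepts <- concepts[ord]; isTP <- isTP[ord]
      text <- unname(nameOf[concepts])
      starts <- integer(m); ends <- integer(m)
      for (k in seq_len(m)) {
        starts[[k]] <- cursor
        ends[[k]] <- cursor + nchar(text[[k]])
        cursor <- ends[[k]] + 1L
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(doc_id = docId, window_id = winId,
                               start = starts, end = ends, text = text,
                               concept_id = concepts, tp = isTP,
                               stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, rows)
  # identical (doc, start, end, concept) keys cannot arise: starts increase
  mentions <- all[, c("doc_id", "window_id", "start", "end", "text",
                      "concept_id")]
  rownames(mentions) <- NULL
  gold <- all[all$tp, c("doc_id", "window_id", "start", "end", "text",
                        "concept_id")]
  rownames(gold) <- NULL
  list(mentions = mentions, gold = gold)
}
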