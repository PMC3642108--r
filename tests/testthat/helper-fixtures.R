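# Fixture ontologies built in code, plus brute-force oracles that are
# deliberately independent of the package's igraph-backed implementation:
# ancestor sets by recursive closure over a parent list, IC by counting
# which terms' closures contain a term, components by undirected BFS.

# 7-term fixture: root R; children X, Y; x1, x2 under X; y1 under Y;
# z under both X and Y.
fixtureOntology7 <- function() {
  edges <- data.frame(
    child  = c("X", "Y", "x1", "x2", "y1", "z", "z"),
    parent = c("R", "R", "X", "X", "Y", "X", "Y"),
    relation = "is_a", stringsAsFactors = FALSE)
  OntologyGraph(c("R", "X", "Y", "x1", "x2", "y1", "z"), edges)
}

chainOntology <- function(ids = c("R", "a", "b")) {
  n <- length(ids)
  OntologyGraph(ids, data.frame(child = ids[-1], parent = ids[-n],
                                relation = "is_a"))
}

# Random DAG as a plain edge table: term i attaches to 1 earlier term,
# plus a second with probability p2. Returns the edge data.frame and the
# OntologyGraph built from it.
randomDag <- function(nTerms, p2 = 0.3) {
  ids <- sprintf("D:%03d", seq_len(nTerms))
  child <- character(0); parent <- character(0)
  if (nTerms > 1L) {
    for (i in 2:nTerms) {
      ps <- sample.int(i - 1L, 1L)
      if (i > 2L && runif(1) < p2)
        ps <- c(ps, sample(setdiff(seq_len(i - 1L), ps), 1L))
      child <- c(child, rep(ids[[i]], length(ps)))
      parent <- c(parent, ids[ps])
    }
  }
  edges <- data.frame(child = child, parent = parent, relation = "is_a",
                      stringsAsFactors = FALSE)
  list(ids = ids, edges = edges, graph = OntologyGraph(ids, edges))
}

# --- oracles ---------------------------------------------------------------

# Reflexive ancestor sets for every term: recursive closure on a parent map.
oracleAncestorSets <- function(ids, edges) {
  parents <- split(edges$parent, factor(edges$child, levels = ids))
  memo <- new.env(parent = emptyenv())
  anc <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    out <- unique(c(v, unlist(lapply(parents[[v]], anc))))
    memo[[v]] <- out
    out
  }
  stats::setNames(lapply(ids, function(v) sort(anc(v))), ids)
}

# Weak components by BFS on the undirected edge list.
oracleComponents <- function(ids, edges) {
  nb <- lapply(stats::setNames(ids, ids), function(v)
    unique(c(edges$parent[edges$child == v], edges$child[edges$parent == v])))
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  k <- 0L
  for (v in ids) {
    if (!is.na(comp[[v]])) next
    k <- k + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[[u]])) next
      comp[[u]] <- k
      queue <- c(queue, nb[[u]][is.na(comp[nb[[u]]])])
    }
  }
  comp
}

# Intrinsic IC from scratch: desc(c) = #terms (other than c) whose ancestor
# closure contains c; p = (desc + 1) / N(component).
oracleIC <- function(ids, edges, logBase = exp(1)) {
  sets <- oracleAncestorSets(ids, edges)
  comp <- oracleComponents(ids, edges)
  N <- table(comp)
  desc <- vapply(ids, function(c)
    sum(vapply(ids, function(u) u != c && c %in% sets[[u]], logical(1))),
    numeric(1))
  ic <- -log((desc + 1) / as.numeric(N[as.character(comp[ids])])) /
    log(logBase)
  stats::setNames(pmax(ic, 0), ids)
}

oracleMica <- function(sets, ic, a, b) {
  common <- intersect(sets[[a]], sets[[b]])
  if (!length(common)) return(NULL)
  top <- common[ic[common] == max(ic[common])]
  best <- sort(top)[[1L]]
  list(term = best, ic = unname(ic[[best]]))
}

oracleSim <- function(measure, sets, ic, a, b) {
  A <- sets[[a]]; B <- sets[[b]]
  switch(measure,
    resnik = {
      m <- oracleMica(sets, ic, a, b)
      if (is.null(m)) 0 else m$ic
    },
    simui = length(intersect(A, B)) / length(union(A, B)),
    simgic = {
      s <- sum(ic[union(A, B)])
      if (s <= 0) { if (setequal(A, B)) 1 else 0 }
      else sum(ic[intersect(A, B)]) / s
    })
}

# Small helper to build a mention table concisely.
makeMentions <- function(concepts, doc = "d1", window = "w1",
                         width = 5L, gap = 1L) {
  n <- length(concepts)
  starts <- (seq_len(n) - 1L) * (width + gap)
  data.frame(doc_id = doc, window_id = window, start = starts,
             end = starts + width, text = concepts, concept_id = concepts,
             stringsAsFactors = FALSE)
}
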