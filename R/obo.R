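#' Construct an OntologyGraph from term and edge tables
#'
#' Low-level constructor used by \code{\link{parseOBO}}, the synthetic
#' generator and tests. Edges point from child to parent and carry a relation
#' type. The working DAG is restricted to \code{allowedRelations}.
#'
#' @param nodes data.frame with columns \code{id}, \code{name},
#'   \code{obsolete}; or a character vector of term ids (names default to the
#'   ids, nothing obsolete).
#' @param edges data.frame with columns \code{child}, \code{parent},
#'   \code{relation}.
#' @param altIds named character vector (alt id -> canonical id), optional.
#' @param allowedRelations relation types defining the working graph;
#'   defaults to every type present in \code{edges}.
#'
#' @return An \code{\linkS4class{OntologyGraph}}.
#' @examples
#' g <- OntologyGraph(c("R", "A"), data.frame(child = "A", parent = "R",
#'                                            relation = "is_a"))
#' termIds(g)
#' @export
OntologyGraph <- function(nodes, edges = NULL, altIds = character(),
                          allowedRelations = NULL) {
  if (is.character(nodes))
    nodes <- data.frame(id = nodes, name = nodes,
                        obsolete = logical(length(nodes)),
                        stringsAsFactors = FALSE)
  if (is.null(edges))
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(allowedRelations))
    allowedRelations <- unique(as.character(edges$relation))
  # obsolete terms keep their row (id resolution) but lose their edges
  obs <- nodes$id[nodes$obsolete]
  if (length(obs) && nrow(edges))
    edges <- edges[!(edges$child %in% obs) & !(edges$parent %in% obs), ,
                   drop = FALSE]
  dag <- .buildDag(nodes, edges, allowedRelations)
  new("OntologyGraph", nodes = nodes, edges = edges,
      altIds = altIds, allowedRelations = allowedRelations,
      dag = dag, acyclicChecked = FALSE)
}

.buildDag <- function(nodes, edges, allowed) {
  live <- nodes$id[!nodes$obsolete]
  keep <- edges[edges$relation %in% allowed, c("child", "parent"),
                drop = FALSE]
  igraph::graph_from_data_frame(keep, directed = TRUE,
                                vertices = data.frame(name = live))
}

#' Parse an OBO 1.2 flat file into an OntologyGraph
#'
#' Reads \code{[Term]} stanzas and records \code{id}, \code{name},
#' \code{alt_id}, \code{is_a}, typed \code{relationship} and
#' \code{is_obsolete} tags. Every typed edge is kept as parsed (including
#' relation types that form cycles, such as ChEBI's "is enantiomer of"
#' pairs); restrict to an acyclic backbone afterwards with
#' \code{\link{filterRelations}}. Obsolete terms are indexed for id
#' resolution only. OWL is not supported.
#'
#' @param path path to an OBO 1.2 file.
#' @return An \code{\linkS4class{OntologyGraph}}.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: A", "name: root", "",
#'              "[Term]", "id: B", "name: child", "is_a: A ! root"), obo)
#' g <- parseOBO(obo)
#' nTerms(g)
#' @export
parseOBO <- function(path) {
  if (!file.exists(path))
    stop("OBO file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  nodes <- list(); edges <- list(); alt <- list()
  inTerm <- FALSE
  cur <- NULL
  curLine <- 0L

  flush <- function(cur, curLine) {
    if (is.null(cur$id))
      stop("malformed [Term] stanza starting at line ", curLine,
           ": missing id")
    cur
  }
  terms <- list()
  for (i in seq_along(lines)) {
    ln <- sub("\\s+$", "", lines[[i]])
    if (grepl("^\\[", ln)) {
      if (inTerm) terms[[length(terms) + 1L]] <- flush(cur, curLine)
      inTerm <- identical(ln, "[Term]")
      if (inTerm) {
        cur <- list(id = NULL, name = NA_character_, alt = character(),
                    obsolete = FALSE,
                    edges = data.frame(parent = character(),
                                       relation = character()))
        curLine <- i
      }
      next
    }
    if (!inTerm || !nzchar(ln)) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("malformed tag at line ", i, ": ", ln)
    tag <- m[[2]]
    val <- sub("\\s*!.*$", "", m[[3]])       # strip trailing comment
    val <- sub("\\s*\\{[^}]*\\}\\s*$", "", val)  # strip trailing modifiers
    if (tag == "id") cur$id <- val
    else if (tag == "name") cur$name <- val
    else if (tag == "alt_id") cur$alt <- c(cur$alt, val)
    else if (tag == "is_obsolete") cur$obsolete <- tolower(val) == "true"
    else if (tag == "is_a") {
      if (!nzchar(val)) stop("malformed is_a tag at line ", i)
      cur$edges <- rbind(cur$edges,
                         data.frame(parent = val, relation = "is_a"))
    } else if (tag == "relationship") {
      parts <- strsplit(trimws(val), "\\s+")[[1]]
      if (length(parts) < 2L)
        stop("malformed relationship tag at line ", i, ": ", ln)
      cur$edges <- rbind(cur$edges,
                         data.frame(parent = parts[[2]],
                                    relation = parts[[1]]))
    }
    # other tags (def, synonym, xref, ...) are ignored
  }
  if (inTerm) terms[[length(terms) + 1L]] <- flush(cur, curLine)
  if (!length(terms))
    stop("no [Term] stanzas found in ", path)

  ids <- vapply(terms, function(t) t$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicated term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  nodes <- data.frame(
    id = ids,
    name = vapply(terms, function(t)
      if (is.na(t$name)) t$id else t$name, character(1)),
    obsolete = vapply(terms, function(t) t$obsolete, logical(1)),
    stringsAsFactors = FALSE)
  edgeList <- lapply(terms, function(t) {
    if (nrow(t$edges) == 0L || t$obsolete) return(NULL)
    data.frame(child = t$id, parent = t$edges$parent,
               relation = t$edges$relation, stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, c(edgeList,
                            list(data.frame(child = character(),
                                            parent = character(),
                                            relation = character()))))
  dangling <- setdiff(unique(edges$parent), ids)
  if (length(dangling))
    stop("parent reference(s) to unknown term id(s): ",
         paste(dangling, collapse = ", "))
  altPairs <- unlist(lapply(terms, function(t) {
    if (!length(t$alt)) return(NULL)
    stats::setNames(rep(t$id, length(t$alt)), t$alt)
  }))
  if (is.null(altPairs)) altPairs <- character()
  OntologyGraph(nodes, edges, altIds = altPairs)
}

#' Write an OntologyGraph as an OBO 1.2 flat file
#'
#' Emits one \code{[Term]} stanza per term with its \code{is_a} and typed
#' \code{relationship} tags; output round-trips through
#' \code{\link{parseOBO}}.
#'
#' @param graph an \code{\linkS4class{OntologyGraph}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeOBO <- function(graph, path) {
  nd <- graph@nodes
  ed <- graph@edges
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(nd))) {
    out <- c("[Term]",
             paste0("id: ", nd$id[[i]]),
             paste0("name: ", nd$name[[i]]))
    if (nd$obsolete[[i]]) out <- c(out, "is_obsolete: true")
    alts <- names(graph@altIds)[graph@altIds == nd$id[[i]]]
    out <- c(out, if (length(alts)) paste0("alt_id: ", alts))
    mine <- ed[ed$child == nd$id[[i]], , drop = FALSE]
    if (nrow(mine)) {
      isa <- mine$relation == "is_a"
      out <- c(out,
               if (any(isa)) paste0("is_a: ", mine$parent[isa]),
               if (any(!isa)) paste0("relationship: ",
                                     mine$relation[!isa], " ",
                                     mine$parent[!isa]))
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}
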