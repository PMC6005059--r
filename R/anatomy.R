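# Anatomy graphs: anatomical terms connected by typed directed edges.
#
# Relations carry the inference semantics (see R/inference.R):
#   part_of       subject is a part of object          (ray part_of fin)
#   is_a          subject is a subtype of object       (pectoral fin is_a paired fin)
#   develops_from subject develops from object         (fin develops_from fin bud)
#   depends_on    subject requires object to exist     (fin depends_on girdle)
#
# depends_on encodes the domain knowledge that paired fins are never present
# without their supporting girdle structures; it is stated as an explicit,
# testable edge rather than recovered from ontology axioms.

ANATOMY_RELATIONS <- c("part_of", "is_a", "develops_from", "depends_on")

#' Build and validate an anatomy graph
#'
#' @param edges data frame with columns `subject`, `relation`, `object`;
#'   relations must be one of `part_of`, `is_a`, `develops_from`,
#'   `depends_on`.
#' @param terms optional data frame with columns `term`, `label` declaring
#'   the vocabulary; defaults to the terms appearing in `edges`. An edge
#'   endpoint not in `terms` is an error (dangling term).
#' @return object of class `anatomy_graph`.
#' @details `part_of` and `is_a` must each be acyclic; a cycle is rejected.
#' @export
build_anatomy_graph <- function(edges, terms = NULL) {
  need <- c("subject", "relation", "object")
  if (!all(need %in% names(edges)))
    stop("edge table needs columns: ", paste(need, collapse = ", "))
  bad <- !(edges$relation %in% ANATOMY_RELATIONS)
  if (any(bad))
    stop("unknown relation label(s): ",
         paste(unique(edges$relation[bad]), collapse = ", "))
  if (is.null(terms)) {
    trm <- unique(c(edges$subject, edges$object))
    terms <- data.frame(term = trm, label = trm, stringsAsFactors = FALSE)
  } else {
    if (!all(c("term", "label") %in% names(terms)))
      stop("term table needs columns: term, label")
    dang <- setdiff(unique(c(edges$subject, edges$object)), terms$term)
    if (length(dang))
      stop("dangling term(s) in edges: ", paste(dang, collapse = ", "))
  }
  for (rel in c("part_of", "is_a")) {
    e <- edges[edges$relation == rel, , drop = FALSE]
    if (has_cycle(e$subject, e$object, terms$term))
      stop("cycle detected in '", rel, "' edges")
  }
  rownames(edges) <- NULL
  structure(list(terms = terms, edges = edges[, need]),
            class = "anatomy_graph")
}

# directed cycle check by repeated removal of sink-free nodes (Kahn)
has_cycle <- function(from, to, nodes) {
  if (length(from) == 0L) return(FALSE)
  repeat {
    sinks <- setdiff(nodes, from)
    keep <- !(to %in% sinks)
    if (!any(keep)) return(FALSE)
    if (all(keep)) return(TRUE)
    from <- from[keep]; to <- to[keep]
  }
}

#' @export
print.anatomy_graph <- function(x, ...) {
  cat("Anatomy graph:", nrow(x$terms), "terms,", nrow(x$edges), "edges (",
      paste(names(table(x$edges$relation)), collapse = ", "), ")\n")
  invisible(x)
}

# forward reachability (subject -> object) over a relation subset,
# start included
reach_forward <- function(graph, start, relations) {
  e <- graph$edges[graph$edges$relation %in% relations, , drop = FALSE]
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(e$object[e$subject %in% frontier], seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# backward reachability (object -> subject), start included
reach_backward <- function(graph, start, relations) {
  e <- graph$edges[graph$edges$relation %in% relations, , drop = FALSE]
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(e$subject[e$object %in% frontier], seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# character term plus its is_a descendants: the entities whose annotations a
# matrix column aggregates (part terms contribute only via inference)
character_entity_set <- function(graph, character) {
  reach_backward(graph, character, "is_a")
}

#' Read an anatomy graph from TSV edge and term tables
#'
#' @param edge_path TSV with columns `subject`, `relation`, `object`.
#' @param term_path optional TSV with columns `term`, `label`.
#' @return an `anatomy_graph`.
#' @export
read_anatomy_graph <- function(edge_path, term_path = NULL) {
  edges <- read_tsv(edge_path)
  terms <- if (!is.null(term_path)) read_tsv(term_path)
  build_anatomy_graph(edges, terms)
}

#' @rdname read_anatomy_graph
#' @param graph an `anatomy_graph`.
#' @export
write_anatomy_graph <- function(graph, edge_path, term_path = NULL) {
  write_tsv(graph$edges, edge_path)
  if (!is.null(term_path)) write_tsv(graph$terms, term_path)
  invisible(edge_path)
}

#' Paired-fin anatomy template
#'
#' The fixed fin-anatomy graph used throughout: for each paired fin
#' (pectoral, pelvic) it contains the fin, its fin ray and radial elements
#' (`part_of` the fin), the supporting girdle skeleton, and the larval fin
#' bud. The fin `depends_on` its girdle (a paired fin is never present
#' without its supporting girdle) and `develops_from` its larval bud (no bud,
#' no fin — but a bud alone does not imply the adult fin). Both fins are
#' `is_a` subtypes of "paired fin".
#'
#' @return an `anatomy_graph`.
#' @export
generate_anatomy_template <- function() {
  fins <- c("pectoral", "pelvic")
  edges <- do.call(rbind, lapply(fins, function(f) {
    fin <- paste(f, "fin")
    data.frame(
      subject = c(paste(f, "fin ray"), paste(f, "radial element"),
                  fin, fin, fin),
      relation = c("part_of", "part_of", "is_a", "depends_on",
                   "develops_from"),
      object = c(fin, fin, "paired fin", paste(f, "girdle skeleton"),
                 paste("larval", f, "fin bud")),
      stringsAsFactors = FALSE)
  }))
  terms <- unique(c(edges$subject, edges$object))
  build_anatomy_graph(edges,
                      data.frame(term = terms, label = terms,
                                 stringsAsFactors = FALSE))
}
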