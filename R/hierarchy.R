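#' Transitive closure of the is-a hierarchy
#'
#' Computes every (ancestor, descendant) pair of non-obsolete terms
#' connected by a chain of is-a edges, together with `min_depth`, the
#' smallest number of edges on any connecting path. With a `category` root
#' the closure is restricted to that category's sub-DAG (the root and all
#' its descendants); a term reachable from several categories participates
#' in each, and the global pair set is simply the union.
#'
#' @param ontology A [ontology()] object.
#' @param category Optional term id of a category root; `NULL` for the whole
#'   ontology.
#' @return A tibble with columns `ancestor_id`, `descendant_id`,
#'   `min_depth`, sorted by ancestor then descendant.
#' @examples
#' onto <- ontology(
#'   terms = tibble::tibble(id = c("a", "b", "c"), name = c("na", "nb", "nc")),
#'   edges = tibble::tibble(id = c("b", "c"), parent = c("a", "b"))
#' )
#' term_closure(onto)
#' @export
term_closure <- function(ontology, category = NULL) {
  stopifnot(inherits(ontology, "synsub_ontology"))
  ids <- active_terms(ontology)$id
  edges <- active_edges(ontology)
  if (!is.null(category)) {
    if (!category %in% ids) {
      abort(sprintf("unknown or obsolete category root: %s", category))
    }
  }
  empty <- tibble::tibble(ancestor_id = character(), descendant_id = character(),
                          min_depth = integer())
  if (nrow(edges) == 0) return(empty)
  g <- igraph::graph_from_data_frame(
    edges[, c("id", "parent")], directed = TRUE,
    vertices = data.frame(name = ids)
  )
  if (!igraph::is_dag(g)) abort("is_a graph is not acyclic")  # constructor guards
  members <- ids
  if (!is.null(category)) {
    members <- names(igraph::subcomponent(g, category, mode = "in"))
  }
  # edges run child -> parent, so "out" distances go from descendant to ancestor
  d <- igraph::distances(g, v = members, to = members, mode = "out")
  hit <- which(is.finite(d) & d > 0, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  dplyr::arrange(
    tibble::tibble(
      ancestor_id = colnames(d)[hit[, "col"]],
      descendant_id = rownames(d)[hit[, "row"]],
      min_depth = as.integer(d[hit])
    ),
    .data$ancestor_id, .data$descendant_id
  )
}
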