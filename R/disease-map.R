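#' Build the thresholded disease map
#'
#' Connects diseases whose pair result passes both thresholds (the map
#' defaults: at least two common causal genes and combined P-value at
#' most 0.001) into an undirected simple graph. Connected components are
#' labelled 1, 2, ... by decreasing size; ties are broken by the
#' lexicographically smallest member, so the labelling is invariant to
#' input order. Component 1 is the giant component.
#'
#' @param pairs Pair tibble from [all_pairs()] (duplicates are merged).
#' @param p_max,min_overlap Edge thresholds.
#' @param include_isolated If TRUE, diseases from `table` without any
#'   qualifying edge are kept as isolated nodes (component NA).
#' @param table Optional `assoc_tbl` supplying node names/sizes and the
#'   isolated-node universe.
#' @return A `disease_graph`: list with the igraph `graph`, a `nodes`
#'   tibble (`disease_id`, `component`, `degree`, optional `causal_genes`)
#'   and the `edges` tibble actually used.
#' @export
build_map <- function(pairs, p_max = 0.001, min_overlap = 2L,
                      include_isolated = FALSE, table = NULL) {
  ed <- pairs %>%
    dplyr::filter(.data$overlap >= min_overlap, .data$p_combined <= p_max) %>%
    dplyr::mutate(a = pmin(.data$entity_a, .data$entity_b),
                  b = pmax(.data$entity_a, .data$entity_b)) %>%
    dplyr::distinct(.data$a, .data$b, .keep_all = TRUE) %>%
    dplyr::transmute(entity_a = .data$a, entity_b = .data$b,
                     overlap = .data$overlap, p_combined = .data$p_combined)
  verts <- sort(unique(c(ed$entity_a, ed$entity_b)))
  if (include_isolated && !is.null(table)) {
    verts <- sort(unique(c(verts, table$disease_id)))
  }
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = verts))
  comp <- igraph::components(g)
  # order components by decreasing size, ties by smallest member name
  members <- split(verts, comp$membership)
  key <- vapply(members, function(v) min(v), "")
  ord <- order(-lengths(members), key)
  relabel <- match(seq_along(members), ord)
  node_comp <- relabel[comp$membership]
  deg <- igraph::degree(g)
  node_comp[deg == 0] <- NA_integer_
  nodes <- tibble::tibble(
    disease_id = verts,
    component = node_comp,
    degree = as.integer(deg)
  )
  if (!is.null(table)) {
    dd <- disease_degrees(table)
    nodes$causal_genes <- dd$degree[match(nodes$disease_id, dd$disease_id)]
  }
  igraph::V(g)$component <- nodes$component
  structure(list(graph = g, nodes = nodes, edges = ed,
                 p_max = p_max, min_overlap = as.integer(min_overlap)),
            class = "disease_graph")
}

#' @export
print.disease_graph <- function(x, ...) {
  sizes <- sort(table(x$nodes$component), decreasing = TRUE)
  cat(sprintf("Disease map: %d nodes, %d edges (overlap >= %d, P <= %g)\n",
              nrow(x$nodes), nrow(x$edges), x$min_overlap, x$p_max))
  if (length(sizes) > 0) {
    cat("component sizes:", paste(utils::head(as.integer(sizes), 10), collapse = ", "),
        if (length(sizes) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
tidy.disease_graph <- function(x, ...) x$nodes

#' @export
glance.disease_graph <- function(x, ...) {
  cs <- table(x$nodes$component)
  tibble::tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_components = length(cs),
    giant_size = if (length(cs) > 0) max(as.integer(cs)) else 0L
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate q-values for a vector of P-values,
#' returned in the input order. This is the assumption-light tail-area
#' FDR used to choose the map's P-value cut-off.
#'
#' @param pvalues Numeric vector with values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
estimate_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Diseases in the vicinity of a query disease
#'
#' Extracts all diseases linked to the query through at least
#' `min_overlap` common causal genes at combined P-value below `p_max`
#' (the vicinity defaults: two genes, P <= 0.01), sorted by ascending
#' P-value, each with the list of shared causal genes.
#'
#' @param disease Query disease id.
#' @param pairs Pair tibble covering the query's comparisons.
#' @param table The `assoc_tbl` (for shared-gene lists).
#' @param p_max,min_overlap Thresholds.
#' @return A tibble `neighbor`, `overlap`, `p_combined`, `shared_genes`
#'   (list-column).
#' @export
vicinity <- function(disease, pairs, table, p_max = 0.01, min_overlap = 2L) {
  stopifnot(inherits(table, "assoc_tbl"))
  if (!disease %in% table$disease_id) {
    stop("unknown disease id: ", disease, call. = FALSE)
  }
  sets <- entity_sets(table)
  hits <- pairs %>%
    dplyr::filter(.data$entity_a == disease | .data$entity_b == disease,
                  .data$overlap >= min_overlap, .data$p_combined <= p_max) %>%
    dplyr::mutate(neighbor = ifelse(.data$entity_a == disease,
                                    .data$entity_b, .data$entity_a)) %>%
    dplyr::arrange(.data$p_combined)
  tibble::tibble(
    neighbor = hits$neighbor,
    overlap = hits$overlap,
    p_combined = hits$p_combined,
    shared_genes = lapply(hits$neighbor, function(nb)
      intersect(sets[[disease]], sets[[nb]]))
  )
}

#' Export a disease map to GraphML
#'
#' Node attributes: label, component, optional cluster; edge attributes:
#' overlap and combined P-value. Isolated nodes are excluded unless the
#' map was built with `include_isolated = TRUE`.
#'
#' @param map A `disease_graph`.
#' @param path Output path.
#' @param clusters Optional named vector disease -> cluster label.
#' @return `path`, invisibly.
#' @export
write_map_graphml <- function(map, path, clusters = NULL) {
  g <- map$graph
  igraph::V(g)$label <- igraph::V(g)$name
  if (!is.null(clusters)) {
    igraph::V(g)$cluster <- unname(clusters[igraph::V(g)$name])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a disease map to SIF
#'
#' One `diseaseA<TAB>shares_genes<TAB>diseaseB` line per edge.
#'
#' @param map A `disease_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_sif <- function(map, path) {
  readr::write_tsv(
    tibble::tibble(a = map$edges$entity_a, rel = "shares_genes",
                   b = map$edges$entity_b),
    path, col_names = FALSE)
  invisible(path)
}

#' Export a vicinity as a disease/gene bipartite GraphML
#'
#' The query disease, its vicinal diseases and the shared causal genes,
#' with a `type` node attribute distinguishing diseases from genes.
#'
#' @param disease Query disease id.
#' @param vic Tibble from [vicinity()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vicinity_graphml <- function(disease, vic, path) {
  if (nrow(vic) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(disease, type = "disease")
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  edges <- purrr::map2_dfr(c(vic$neighbor, disease),
                           c(vic$shared_genes, list(unique(unlist(vic$shared_genes)))),
                           function(d, gs) tibble::tibble(from = d, to = gs))
  verts <- tibble::tibble(
    name = unique(c(edges$from, edges$to)),
    type = ifelse(unique(c(edges$from, edges$to)) %in% c(disease, vic$neighbor),
                  "disease", "gene")
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Plot a disease map
#'
#' @param object A `disease_graph`.
#' @param ... Ignored.
#' @return A ggplot of the map laid out by Fruchterman-Reingold, nodes
#'   coloured by component.
#' @export
autoplot.disease_graph <- function(object, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  set.seed(1)
  xy <- igraph::layout_with_fr(object$graph)
  nd <- object$nodes
  nd$x <- xy[, 1]; nd$y <- xy[, 2]
  eg <- object$edges
  eg$x <- nd$x[match(eg$entity_a, nd$disease_id)]
  eg$y <- nd$y[match(eg$entity_a, nd$disease_id)]
  eg$xend <- nd$x[match(eg$entity_b, nd$disease_id)]
  eg$yend <- nd$y[match(eg$entity_b, nd$disease_id)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = eg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70") +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = factor(.data$component)), size = 2) +
    ggplot2::labs(colour = "component") +
    ggplot2::theme_void()
}
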