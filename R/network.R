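#' Read a molecular interaction network
#'
#' Accepts a 2-column edge-list TSV (`gene_a<TAB>gene_b`, an optional
#' third column marking direction) or SIF (`a<TAB>relation<TAB>b`).
#' Self-loops are dropped; for undirected graphs duplicate edges are
#' merged.
#'
#' @param path Input path; `.sif` files are parsed as SIF.
#' @param directed Build a directed graph (for reaction-step
#'   clustering).
#' @return An igraph graph.
#' @export
read_network <- function(path, directed = FALSE) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sif <- grepl("\\.sif$", path) | all(lengths(fields) == 3)
  edges <- if (sif && all(lengths(fields) >= 3)) {
    do.call(rbind, lapply(fields, function(f) c(f[1], f[3])))
  } else {
    do.call(rbind, lapply(fields, function(f) c(f[1], f[2])))
  }
  g <- igraph::graph_from_edgelist(edges, directed = directed)
  igraph::simplify(g, remove.multiple = !directed, remove.loops = TRUE)
}

network_from_edges <- function(edges, directed = FALSE) {
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = directed)
  igraph::simplify(g, remove.multiple = !directed, remove.loops = TRUE)
}

# Column-stochastic transition matrix of an undirected simple graph;
# degree-0 nodes get a self-loop to preserve stochasticity.
transition_matrix <- function(graph) {
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  A <- ((A + Matrix::t(A)) > 0) * 1           # symmetrize defensively
  deg <- Matrix::colSums(A)
  dangling <- which(deg == 0)
  if (length(dangling) > 0) {
    A[cbind(dangling, dangling)] <- 1
    deg[dangling] <- 1
  }
  A %*% Matrix::Diagonal(x = 1 / deg)
}

#' Random walk with restart on an interaction network
#'
#' Iterates `p <- (1 - r) * W * p + r * p0` from the uniform
#' distribution over the seed genes until the L1 change drops below
#' `tol`, where `W` is the column-normalized adjacency matrix. The
#' stationary scores measure global network proximity to the seed set;
#' ranks are reported as `N - r_order` (with `r_order` the 1-based
#' descending-score position), so larger rank values mean better
#' network scores.
#'
#' @param network An igraph graph (treated as undirected) or an edge
#'   tibble with `gene_a`, `gene_b`.
#' @param seeds Character vector of seed genes; at least one must be in
#'   the network.
#' @param restart Restart probability in (0, 1); default 0.75 following
#'   the candidate-gene prioritization literature this score adopts.
#' @param tol L1 convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 1e4).
#' @return An `rwr_result`: `scores` tibble (`gene`, `score`, `rank`),
#'   iteration count, convergence flag, and the seeds used.
#' @export
rwr <- function(network, seeds, restart = 0.75, tol = 1e-6, max_iter = 10000L) {
  stopifnot(restart > 0, restart < 1)
  g <- if (inherits(network, "igraph")) network else network_from_edges(network)
  g <- igraph::as_undirected(g, mode = "collapse")
  nodes <- igraph::V(g)$name
  seeds_in <- intersect(seeds, nodes)
  if (length(seeds_in) == 0) stop("no seed gene is present in the network", call. = FALSE)
  W <- transition_matrix(g)
  n <- length(nodes)
  p0 <- numeric(n)
  p0[match(seeds_in, nodes)] <- 1 / length(seeds_in)
  p <- p0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p_new <- as.numeric((1 - restart) * (W %*% p)) + restart * p0
    if (sum(abs(p_new - p)) < tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
  }
  ord <- order(-p, nodes)                      # deterministic tie-break
  r_order <- integer(n)
  r_order[ord] <- seq_len(n)
  structure(
    list(scores = tibble::tibble(gene = nodes, score = p,
                                 rank = n - r_order),
         restart = restart, iterations = iter, converged = converged,
         seeds = seeds_in, tol = tol),
    class = "rwr_result"
  )
}

#' @export
print.rwr_result <- function(x, ...) {
  cat(sprintf("RWR: %d nodes, restart %.2f, %d iterations (%s)\n",
              nrow(x$scores), x$restart, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
tidy.rwr_result <- function(x, ...) x$scores

#' Rank change of a test gene when predicted genes join the seeds
#'
#' Runs the random walk twice — seeds alone, then seeds plus the added
#' genes — and reports the test gene's network score and `N - r_order`
#' rank under both, with `rank_difference = rank_with - rank_without`
#' (positive values mean the added genes improved the test gene's
#' network score rank).
#'
#' @param network igraph graph or edge tibble.
#' @param base_seeds Known disease genes.
#' @param added_seeds Genes to add (e.g. association-based predictions);
#'   must not contain `test_gene`.
#' @param test_gene The held-out gene to score.
#' @inheritParams rwr
#' @return A one-row tibble: `test_gene`, `score_without`, `score_with`,
#'   `rank_without`, `rank_with`, `rank_difference`.
#' @export
rank_comparison <- function(network, base_seeds, added_seeds, test_gene,
                            restart = 0.75, tol = 1e-6, max_iter = 10000L) {
  if (test_gene %in% c(base_seeds, added_seeds)) {
    stop("test_gene must not be a seed", call. = FALSE)
  }
  r0 <- rwr(network, base_seeds, restart, tol, max_iter)
  r1 <- rwr(network, unique(c(base_seeds, added_seeds)), restart, tol, max_iter)
  if (!test_gene %in% r0$scores$gene) {
    stop("test_gene not in network: ", test_gene, call. = FALSE)
  }
  s0 <- r0$scores[r0$scores$gene == test_gene, ]
  s1 <- r1$scores[r1$scores$gene == test_gene, ]
  tibble::tibble(
    test_gene = test_gene,
    score_without = s0$score, score_with = s1$score,
    rank_without = s0$rank, rank_with = s1$rank,
    rank_difference = s1$rank - s0$rank
  )
}

#' Shortest-path network clusters of seed molecules
#'
#' Connects seed molecules through directed shortest paths of at most
#' `max_steps` reaction steps (default 3): for every ordered seed pair
#' whose shortest directed path is within the limit, all tied shortest
#' paths are added to a working subgraph. Clusters are the weakly
#' connected components of that subgraph that contain at least two
#' seeds; pathway intermediates are retained and labelled as
#' connectors.
#'
#' @param graph A directed igraph graph (undirected graphs are treated
#'   as bidirectional).
#' @param seeds Character vector of seed molecules.
#' @param max_steps Maximum number of reaction steps (edges) per path.
#' @return A list of clusters, each a list with `members` tibble
#'   (`name`, `role` in seed/connector) and the cluster `graph`.
#' @export
network_clusters <- function(graph, seeds, max_steps = 3L) {
  stopifnot(max_steps >= 1)
  seeds <- sort(intersect(unique(seeds), igraph::V(graph)$name))
  if (length(seeds) < 2) return(list())
  keep_nodes <- character()
  keep_edges <- matrix(character(), ncol = 2)
  d <- igraph::distances(graph, v = seeds, to = seeds, mode = "out")
  for (a in seeds) {
    reach <- seeds[is.finite(d[a, seeds]) & d[a, seeds] >= 1 &
                     d[a, seeds] <= max_steps]
    for (b in reach) {
      sp <- igraph::all_shortest_paths(graph, from = a, to = b, mode = "out")
      for (pth in sp$res) {
        nm <- igraph::V(graph)$name[as.integer(pth)]
        keep_nodes <- c(keep_nodes, nm)
        if (length(nm) > 1) {
          keep_edges <- rbind(keep_edges,
                              cbind(nm[-length(nm)], nm[-1]))
        }
      }
    }
  }
  if (length(keep_nodes) == 0) return(list())
  sub <- igraph::graph_from_edgelist(unique(keep_edges), directed = TRUE)
  comp <- igraph::components(sub, mode = "weak")
  out <- list()
  for (ci in seq_len(comp$no)) {
    members <- igraph::V(sub)$name[comp$membership == ci]
    n_seed <- sum(members %in% seeds)
    if (n_seed < 2) next
    out[[length(out) + 1]] <- list(
      members = tibble::tibble(
        name = sort(members),
        role = ifelse(sort(members) %in% seeds, "seed", "connector")
      ),
      graph = igraph::induced_subgraph(sub, members)
    )
  }
  # deterministic order: by decreasing seed count, then smallest member
  ord <- order(-vapply(out, function(cl) sum(cl$members$role == "seed"), 0L),
               vapply(out, function(cl) cl$members$name[1], ""))
  out[ord]
}

#' Write RWR scores to TSV
#'
#' @param result An `rwr_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rwr <- function(result, path) {
  readr::write_tsv(dplyr::arrange(result$scores, dplyr::desc(.data$score)),
                   path)
  invisible(path)
}

#' Write network clusters to GraphML
#'
#' One GraphML file containing all clusters, with a `role` node
#' attribute (seed or connector) and a `cluster` attribute.
#'
#' @param clusters Result of [network_clusters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters_graphml <- function(clusters, path) {
  if (length(clusters) == 0) {
    g <- igraph::make_empty_graph(directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  gs <- purrr::imap(clusters, function(cl, i) {
    g <- cl$graph
    igraph::V(g)$role <- cl$members$role[match(igraph::V(g)$name,
                                               cl$members$name)]
    igraph::V(g)$cluster <- i
    g
  })
  g <- Reduce(igraph::disjoint_union, gs)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
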