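#' One-tailed Fisher (hypergeometric) term enrichment
#'
#' For each annotation term, tests over-representation of the term's
#' genes in `gene_set` against the `universe` by the hypergeometric
#' upper tail: the probability of drawing at least `k` annotated genes
#' in `|gene_set|` draws without replacement from a universe containing
#' `K` annotated genes. Terms annotating no universe gene are skipped.
#'
#' @param gene_set Character vector, a subset of `universe`.
#' @param universe Character vector: all genes under consideration
#'   (typically every gene of the filtered association table).
#' @param term_map Tibble with `gene_symbol` and `term_id` columns
#'   (optional `term_name`).
#' @return A tibble `term_id`, `term_name`, `k`, `K`, `p` with one row
#'   per term present in the universe.
#' @export
fisher_enrichment <- function(gene_set, universe, term_map) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (length(gene_set) == 0) stop("empty gene set", call. = FALSE)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (!all(gene_set %in% universe)) {
    stop("gene_set must be a subset of universe", call. = FALSE)
  }
  tm <- term_map %>%
    dplyr::filter(.data$gene_symbol %in% universe) %>%
    dplyr::distinct(.data$gene_symbol, .data$term_id, .keep_all = TRUE)
  if (!"term_name" %in% names(tm)) tm$term_name <- ""
  n <- length(gene_set)
  N <- length(universe)
  tm %>%
    dplyr::group_by(.data$term_id) %>%
    dplyr::summarise(
      term_name = dplyr::first(.data$term_name),
      k = sum(.data$gene_symbol %in% gene_set),
      K = dplyr::n(), .groups = "drop"
    ) %>%
    dplyr::mutate(p = stats::phyper(.data$k - 1, .data$K, N - .data$K, n,
                                    lower.tail = FALSE)) %>%
    dplyr::arrange(.data$p, .data$term_id)
}

#' Preponderance of the most significant enrichment P-value
#'
#' Given one enrichment P-value per cluster, sorts them ascending
#' (P1 <= P2 <= ... <= PN) and returns
#' `(log10(P2) - log10(P1)) * log10(P1) / sum_i log10(Pi)`:
#' the gap between the two most significant P-values on the log10 scale,
#' weighted by the share of the most significant P-value in the total
#' log10 mass. The value is non-negative, zero when the two smallest
#' P-values tie, and invariant under permutation of the input. P-values
#' equal to 1 contribute nothing to the sum.
#'
#' @param pvals Numeric vector of length >= 2, values in (0, 1], at
#'   least one strictly below 1 (all-ones is undefined and raises an
#'   error).
#' @return A single non-negative preponderance value.
#' @export
preponderance <- function(pvals) {
  if (length(pvals) < 2) stop("need P-values for at least two clusters", call. = FALSE)
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p <- sort(pvals)
  if (p[1] >= 1) {
    stop("preponderance undefined: all P-values equal 1", call. = FALSE)
  }
  lp <- log10(p)
  (lp[2] - lp[1]) * lp[1] / sum(lp)
}

#' Enrichment records across disease clusters
#'
#' Runs [fisher_enrichment()] for each cluster's gene set against a
#' common universe, assigns every term to the cluster with its smallest
#' P-value (first cluster on ties), and computes the preponderance value
#' from the term's P-value vector. Terms whose P-values are all 1 get
#' `prep = NA` (undefined, flagged rather than zero).
#'
#' @param gene_sets Named list of cluster gene sets.
#' @param universe Common gene universe.
#' @param term_map Tibble `gene_symbol`, `term_id` (optional `term_name`).
#' @return An `enrichment_records` tibble: `term_id`, `term_name`, one
#'   `p_<cluster>` column per cluster, `assigned_cluster`, `p_assigned`,
#'   `prep`, and `rank` within the assigned cluster (by decreasing
#'   preponderance; ties by `p_assigned` then term id).
#' @export
cluster_enrichment <- function(gene_sets, universe, term_map) {
  stopifnot(length(gene_sets) >= 2, !is.null(names(gene_sets)))
  per <- purrr::imap(gene_sets, function(gs, nm) {
    out <- fisher_enrichment(gs, universe, term_map) %>%
      dplyr::select("term_id", "term_name", "p")
    names(out)[names(out) == "p"] <- paste0("p_", nm)
    out
  })
  wide <- purrr::reduce(per, dplyr::full_join, by = c("term_id", "term_name"))
  pcols <- paste0("p_", names(gene_sets))
  # a term absent from a cluster's enrichment table was never tested with
  # k > 0 possible there; its upper tail at k = 0 is 1
  wide <- wide %>%
    dplyr::mutate(dplyr::across(dplyr::all_of(pcols), ~ dplyr::coalesce(.x, 1)))
  P <- as.matrix(wide[, pcols])
  assigned <- apply(P, 1, which.min)
  prep <- apply(P, 1, function(pv) {
    if (min(pv) >= 1) NA_real_ else preponderance(pv)
  })
  out <- wide %>%
    dplyr::mutate(
      assigned_cluster = names(gene_sets)[assigned],
      p_assigned = P[cbind(seq_len(nrow(P)), assigned)],
      prep = prep
    ) %>%
    dplyr::group_by(.data$assigned_cluster) %>%
    dplyr::arrange(dplyr::desc(.data$prep), .data$p_assigned, .data$term_id,
                   .by_group = TRUE) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$assigned_cluster, .data$rank)
  class(out) <- c("enrichment_records", class(out))
  out
}

#' Top terms of one cluster by preponderance
#'
#' @param records An `enrichment_records` tibble from
#'   [cluster_enrichment()].
#' @param cluster Cluster name.
#' @param top_k Number of terms to return (default 15, the figure
#'   convention for per-cluster biological-process rankings).
#' @return The cluster's terms ordered by decreasing preponderance
#'   (ties: smaller assigned P first, then term id), truncated to
#'   `top_k`; undefined-preponderance terms are dropped.
#' @export
rank_terms <- function(records, cluster, top_k = 15L) {
  records %>%
    dplyr::filter(.data$assigned_cluster == cluster, !is.na(.data$prep)) %>%
    dplyr::arrange(dplyr::desc(.data$prep), .data$p_assigned, .data$term_id) %>%
    utils::head(top_k)
}

#' Cluster-specific gene sets
#'
#' Given a disease-to-cluster labelling, collects each cluster's causal
#' genes and removes genes that occur in more than one cluster, yielding
#' the complementary cluster-specific sets used for the enrichment
#' comparison.
#'
#' @param table An `assoc_tbl`.
#' @param clusters Named character vector: disease id -> cluster label.
#' @return Named list of cluster-specific gene vectors.
#' @export
cluster_specific_genes <- function(table, clusters) {
  stopifnot(inherits(table, "assoc_tbl"))
  df <- tibble::as_tibble(table) %>%
    dplyr::filter(.data$disease_id %in% names(clusters)) %>%
    dplyr::mutate(cluster = unname(clusters[.data$disease_id])) %>%
    dplyr::distinct(.data$cluster, .data$gene_symbol)
  shared <- df %>%
    dplyr::count(.data$gene_symbol) %>%
    dplyr::filter(.data$n > 1) %>%
    dplyr::pull(.data$gene_symbol)
  df <- dplyr::filter(df, !.data$gene_symbol %in% shared)
  split(df$gene_symbol, df$cluster)
}

#' Write enrichment records to TSV
#'
#' @param records An `enrichment_records` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(records, path) {
  readr::write_tsv(tibble::as_tibble(records), path)
  invisible(path)
}

#' Plot the top preponderant terms per cluster
#'
#' @param object An `enrichment_records` tibble.
#' @param top_k Terms per cluster.
#' @param ... Ignored.
#' @return A ggplot of preponderance bars, faceted by cluster.
#' @export
autoplot.enrichment_records <- function(object, top_k = 15L, ...) {
  top <- object %>%
    dplyr::filter(!is.na(.data$prep)) %>%
    dplyr::group_by(.data$assigned_cluster) %>%
    dplyr::slice_min(.data$rank, n = top_k) %>%
    dplyr::ungroup()
  ggplot2::ggplot(top, ggplot2::aes(
    x = .data$prep,
    y = stats::reorder(.data$term_id, .data$prep))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~assigned_cluster, scales = "free_y") +
    ggplot2::labs(x = "preponderance", y = NULL) +
    ggplot2::theme_minimal()
}
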