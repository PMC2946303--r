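#' Configuration for the synthetic association-table generator
#'
#' The generator emulates the statistical shape of curated causal
#' disease/gene annotation corpora: a bipartite disease-gene table whose
#' gene degrees (diseases per gene) follow a heavy-tailed discrete power
#' law truncated at a maximum, optionally with planted disease modules
#' whose members draw their causal genes from a shared pool. Defaults
#' mirror the reference corpus scale the method was designed for:
#' 375 diseases, 3051 genes, and a degree law (exponent 1.8 truncated at
#' 78) under which about 86% of genes link to at most five diseases while
#' a hub gene may reach 78 links.
#'
#' @param n_diseases,n_genes Number of background diseases and genes.
#' @param power_law_exponent Exponent (> 1) of the discrete power law on
#'   gene degrees.
#' @param max_degree Truncation point of the degree law; must not exceed
#'   `n_diseases`.
#' @param planted_modules List of modules, each a list with elements
#'   `disease_ids` (character), `shared_gene_pool_size` and
#'   `per_disease_draw`: every module disease draws that many genes,
#'   without replacement, from the module's dedicated gene pool.
#' @param background_edge_rate Probability of an extra independent edge
#'   for each (disease, gene) pair, on top of the degree-law attachment
#'   (default 0).
#' @param seed Integer seed; identical seed and config give an identical
#'   table.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_diseases = 375L, n_genes = 3051L,
                             power_law_exponent = 1.8, max_degree = 78L,
                             planted_modules = list(),
                             background_edge_rate = 0, seed = 1L) {
  stopifnot(
    n_diseases >= 1, n_genes >= 0, power_law_exponent > 1,
    max_degree >= 1, max_degree <= n_diseases,
    background_edge_rate >= 0, background_edge_rate <= 1
  )
  for (m in planted_modules) {
    stopifnot(all(c("disease_ids", "shared_gene_pool_size", "per_disease_draw")
                  %in% names(m)))
    if (m$per_disease_draw > m$shared_gene_pool_size) {
      stop("infeasible module: per_disease_draw exceeds shared_gene_pool_size",
           call. = FALSE)
    }
  }
  structure(
    list(n_diseases = as.integer(n_diseases), n_genes = as.integer(n_genes),
         power_law_exponent = power_law_exponent,
         max_degree = as.integer(max_degree),
         planted_modules = planted_modules,
         background_edge_rate = background_edge_rate, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Read a synthetic-data configuration from YAML or JSON
#'
#' @param path Path to a YAML (or JSON) file with the fields of
#'   [synthetic_config()]; `seed` is read from the top level.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(synthetic_config, raw)
}

# P(degree <= q) under the truncated discrete power law; used both by the
# generator and as a closed-form check of the degree shape.
truncated_power_law_cdf <- function(q, exponent, max_degree) {
  k <- seq_len(max_degree)
  w <- k^(-exponent)
  sum(w[k <= q]) / sum(w)
}

#' Generate a synthetic association table
#'
#' Genes are assigned target degrees drawn from the truncated discrete
#' power law, then attached to uniformly chosen diseases without
#' replacement. Planted-module diseases then draw `per_disease_draw`
#' genes, without replacement, from their module's dedicated pool (pool
#' genes are named `M<i>_P<j>`), so any two member diseases overlap by a
#' hypergeometric number of shared pool genes. All edges are emitted as
#' type `"causal"`.
#'
#' @param config A [synthetic_config()].
#' @return An `assoc_tbl`; the module pools are attached as the
#'   `"modules"` attribute (a named list of gene vectors).
#' @export
generate_associations <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  diseases <- sprintf("D%04d", seq_len(config$n_diseases))
  genes <- if (config$n_genes > 0) sprintf("G%05d", seq_len(config$n_genes)) else character()

  k <- seq_len(config$max_degree)
  pk <- k^(-config$power_law_exponent)
  deg <- if (config$n_genes > 0) {
    sample(k, config$n_genes, replace = TRUE, prob = pk)
  } else integer()

  edge_disease <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    edge_disease[[i]] <- sample(diseases, deg[i], replace = FALSE)
  }
  df <- tibble::tibble(
    disease_id = unlist(edge_disease, use.names = FALSE),
    gene_symbol = rep(genes, times = deg)
  )

  if (config$background_edge_rate > 0 && config$n_genes > 0) {
    n_cells <- config$n_diseases * config$n_genes
    n_extra <- stats::rbinom(1, n_cells, config$background_edge_rate)
    if (n_extra > 0) {
      cells <- sample.int(n_cells, n_extra, replace = FALSE)
      df <- dplyr::bind_rows(df, tibble::tibble(
        disease_id = diseases[((cells - 1L) %% config$n_diseases) + 1L],
        gene_symbol = genes[((cells - 1L) %/% config$n_diseases) + 1L]
      ))
    }
  }

  modules <- list()
  for (mi in seq_along(config$planted_modules)) {
    m <- config$planted_modules[[mi]]
    pool <- sprintf("M%d_P%02d", mi, seq_len(m$shared_gene_pool_size))
    modules[[paste0("module", mi)]] <- pool
    for (d in m$disease_ids) {
      drawn <- sample(pool, m$per_disease_draw, replace = FALSE)
      df <- dplyr::bind_rows(df, tibble::tibble(disease_id = d, gene_symbol = drawn))
    }
  }

  df$disease_name <- ""
  df$association_type <- "causal"
  out <- as_association_table(df)
  attr(out, "modules") <- modules
  out
}

#' Generate a synthetic gene-to-GO-term annotation
#'
#' Every (gene, term) pair is annotated independently at `base_rate`;
#' genes named in a bias entry are annotated to that entry's terms at
#' odds multiplied by `odds_ratio`, planting the enrichment signal the
#' preponderance analysis is meant to detect.
#'
#' @param table An `assoc_tbl`; its genes form the annotation universe.
#' @param n_terms Number of GO-like terms (`T0001`, ...).
#' @param bias List of entries `list(genes=, terms=, odds_ratio=)`.
#' @param base_rate Background annotation probability per (gene, term).
#' @param seed Integer seed.
#' @return A tibble with columns `gene_symbol`, `term_id`.
#' @export
generate_go_annotation <- function(table, n_terms, bias = list(),
                                   base_rate = 0.05, seed = 1L) {
  stopifnot(inherits(table, "assoc_tbl"), n_terms >= 1,
            base_rate > 0, base_rate < 1)
  set.seed(seed)
  genes <- sort(unique(table$gene_symbol))
  terms <- sprintf("T%04d", seq_len(n_terms))
  prob <- matrix(base_rate, nrow = length(genes), ncol = n_terms,
                 dimnames = list(genes, terms))
  base_odds <- base_rate / (1 - base_rate)
  for (b in bias) {
    or <- if (is.null(b$odds_ratio)) 1 else b$odds_ratio
    p <- base_odds * or / (1 + base_odds * or)
    prob[intersect(b$genes, genes), intersect(b$terms, terms)] <- p
  }
  hit <- matrix(stats::runif(length(prob)), nrow = nrow(prob)) < prob
  idx <- which(hit, arr.ind = TRUE)
  tibble::tibble(gene_symbol = genes[idx[, 1]], term_id = terms[idx[, 2]]) %>%
    dplyr::arrange(.data$gene_symbol, .data$term_id)
}

#' Generate a synthetic molecular interaction network
#'
#' An Erdos-Renyi graph over the given genes at the requested edge
#' density, with any planted neighbour pairs guaranteed present.
#'
#' @param genes Character vector of node names.
#' @param edge_density Probability of each possible edge, in \[0, 1\].
#' @param planted_neighbors Named list: `gene -> character vector` of
#'   neighbours whose edges are always included.
#' @param seed Integer seed.
#' @return A tibble with columns `gene_a`, `gene_b` (undirected, simple,
#'   `gene_a < gene_b`).
#' @export
generate_network <- function(genes, edge_density, planted_neighbors = list(),
                             seed = 1L) {
  stopifnot(edge_density >= 0, edge_density <= 1)
  set.seed(seed)
  genes <- sort(unique(genes))
  n <- length(genes)
  edges <- tibble::tibble(gene_a = character(), gene_b = character())
  if (n >= 2 && edge_density > 0) {
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < edge_density
    edges <- tibble::tibble(gene_a = genes[pairs[1, keep]],
                            gene_b = genes[pairs[2, keep]])
  }
  for (g in names(planted_neighbors)) {
    nb <- planted_neighbors[[g]]
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      gene_a = pmin(g, nb), gene_b = pmax(g, nb)
    ))
  }
  edges %>%
    dplyr::filter(.data$gene_a != .data$gene_b) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Write a gene-to-term annotation to two-column TSV
#'
#' @param term_map Tibble with `gene_symbol`, `term_id` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_terms <- function(term_map, path) {
  readr::write_tsv(term_map[, c("gene_symbol", "term_id")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a gene-to-term annotation from two-column TSV
#'
#' Accepts `gene<TAB>term_id` or `gene<TAB>term_id|term_name` rows.
#'
#' @param path Input path.
#' @return Tibble with `gene_symbol`, `term_id`, `term_name` columns.
#' @export
read_gene_terms <- function(path) {
  df <- readr::read_tsv(path, col_names = c("gene_symbol", "term"),
                        col_types = "cc", progress = FALSE)
  parts <- strsplit(df$term, "|", fixed = TRUE)
  tibble::tibble(
    gene_symbol = df$gene_symbol,
    term_id = vapply(parts, `[`, "", 1),
    term_name = vapply(parts, function(p) if (length(p) > 1) p[2] else "", "")
  )
}

#' Write an interaction edge list to TSV
#'
#' @param edges Tibble with `gene_a`, `gene_b` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path) {
  readr::write_tsv(edges[, c("gene_a", "gene_b")], path, col_names = FALSE)
  invisible(path)
}
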