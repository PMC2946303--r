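#' Sample frequency-preserving random gene sets
#'
#' Implements the degree-preserving null: for each random set, every gene
#' `g` is included independently with probability
#' `gene_degree(g) / n_diseases` — exactly the inclusion law obtained by
#' sampling one disease uniformly for each gene and keeping the gene when
#' the sampled disease is associated with it. Genes therefore occur in
#' random sets with the same frequency as in the original data, unlike a
#' uniform (Fisher-type) null. For gene-side models, pass the transposed
#' table ([transpose_associations()]); the scheme is role-symmetric.
#'
#' Uniform deviates are consumed row-major over (set index, gene index)
#' with genes in sorted order, so a given seed yields the same sets
#' regardless of chunking.
#'
#' @param table An `assoc_tbl`.
#' @param n_sets Number of random sets.
#' @param seed Integer seed.
#' @param chunk_size Sets generated per internal block (memory knob; does
#'   not affect the result).
#' @return A sparse logical matrix (`n_sets` rows, one column per gene in
#'   sorted order) whose rows are the sampled sets.
#' @export
sample_random_sets <- function(table, n_sets, seed, chunk_size = 20000L) {
  stopifnot(inherits(table, "assoc_tbl"), n_sets >= 1)
  genes <- sort(unique(table$gene_symbol))
  n_dis <- dplyr::n_distinct(table$disease_id)
  deg <- gene_degrees(table)
  p <- deg$degree[match(genes, deg$gene_symbol)] / n_dis
  set.seed(seed)
  m <- length(genes)
  ii <- list(); jj <- list(); done <- 0L; blk <- 0L
  while (done < n_sets) {
    cs <- min(chunk_size, n_sets - done)
    u <- matrix(stats::runif(cs * m), nrow = cs, byrow = TRUE)
    hit <- u < matrix(p, cs, m, byrow = TRUE)
    idx <- which(hit, arr.ind = TRUE)
    blk <- blk + 1L
    ii[[blk]] <- idx[, 1] + done
    jj[[blk]] <- idx[, 2]
    done <- done + cs
  }
  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = TRUE,
    dims = c(n_sets, m), dimnames = list(NULL, genes)
  )
}

#' Aggregate overlaps with random sets into regression points
#'
#' For a focal causal gene set `A`, groups the random sets by size `X`
#' and records, per distinct size, the mean overlap `Y` of `A` with sets
#' of that size and the number `W` of such sets. These (X, Y, W) points
#' are the data for the weighted overlap regression.
#'
#' @param A Character vector: the focal entity's gene set.
#' @param random_sets Sparse set matrix from [sample_random_sets()].
#' @return A tibble with columns `X`, `Y`, `W` (ascending `X`);
#'   `sum(W)` equals the number of random sets. Size-0 sets, when they
#'   occur, contribute the point (0, 0, W).
#' @export
aggregate_overlap_curve <- function(A, random_sets) {
  stopifnot(length(A) > 0)
  sizes <- Matrix::rowSums(random_sets)
  cols <- intersect(unique(A), colnames(random_sets))
  ov <- if (length(cols) > 0) {
    Matrix::rowSums(random_sets[, cols, drop = FALSE])
  } else {
    rep(0, nrow(random_sets))
  }
  tibble::tibble(X = as.integer(sizes), ov = ov) %>%
    dplyr::group_by(.data$X) %>%
    dplyr::summarise(Y = mean(.data$ov), W = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(.data$X)
}

# Chunked curve computation for every entity of a table at once, without
# materializing the full set matrix. Returns list(curves = named list of
# (X, Y, W) tibbles, sizes = named entity set sizes).
overlap_curves <- function(table, n_sets, seed, chunk_size = 20000L) {
  stopifnot(inherits(table, "assoc_tbl"), n_sets >= 1)
  M <- membership_matrix(table)          # genes x entities
  genes <- rownames(M)
  entities <- colnames(M)
  n_dis <- length(entities)
  deg <- gene_degrees(table)
  p <- deg$degree[match(genes, deg$gene_symbol)] / n_dis
  m <- length(genes)

  w_count <- numeric(m + 1)                       # index = X + 1
  y_sum <- matrix(0, nrow = m + 1, ncol = n_dis)
  set.seed(seed)
  done <- 0L
  while (done < n_sets) {
    cs <- min(chunk_size, n_sets - done)
    u <- matrix(stats::runif(cs * m), nrow = cs, byrow = TRUE)
    hit <- u < matrix(p, cs, m, byrow = TRUE)
    idx <- which(hit, arr.ind = TRUE)
    S <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2], x = 1,
                              dims = c(cs, m))
    X <- as.integer(Matrix::rowSums(S))
    O <- S %*% M                                   # cs x entities
    xs <- sort(unique(X))
    G <- Matrix::sparseMatrix(i = seq_along(X), j = match(X, xs), x = 1,
                              dims = c(cs, length(xs)))
    sums <- as.matrix(Matrix::crossprod(G, O))
    w_count[xs + 1L] <- w_count[xs + 1L] + tabulate(match(X, xs), length(xs))
    y_sum[xs + 1L, ] <- y_sum[xs + 1L, ] + sums
    done <- done + cs
  }
  seen <- which(w_count > 0) - 1L
  curves <- lapply(seq_len(n_dis), function(j) {
    tibble::tibble(
      X = seen,
      Y = y_sum[seen + 1L, j] / w_count[seen + 1L],
      W = as.integer(w_count[seen + 1L])
    )
  })
  names(curves) <- entities
  sizes <- stats::setNames(as.integer(Matrix::colSums(M)), entities)
  list(curves = curves, sizes = sizes)
}
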