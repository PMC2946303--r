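#' P-values for one entity pair
#'
#' Scores the overlap `x = |A intersect B|` of two causal gene sets with
#' two directional Poisson tails — `p_a` uses entity A's model evaluated
#' at `|B|`, `p_b` uses entity B's model at `|A|` — and combines them by
#' their geometric mean, `exp((log p_a + log p_b) / 2)`, computed in log
#' space. Disjoint sets give all three P-values equal to 1.
#'
#' @param set_a,set_b Character vectors: the two causal gene sets.
#' @param model_a,model_b The entities' fitted [fit_overlap_model()]s.
#' @param entity_a,entity_b Identifiers carried into the result.
#' @return A one-row tibble: `entity_a`, `entity_b`, `overlap`, `p_a`,
#'   `p_b`, `p_combined`, and `clamped` (TRUE when either model was
#'   evaluated outside its valid size range and clamped to the boundary).
#' @export
pair_pvalue <- function(set_a, set_b, model_a, model_b,
                        entity_a = "A", entity_b = "B") {
  x <- length(intersect(set_a, set_b))
  lam_a <- predict_lambda(model_a, length(unique(set_b)))
  lam_b <- predict_lambda(model_b, length(unique(set_a)))
  clamped <- attr(lam_a, "clamped") | attr(lam_b, "clamped")
  log_pa <- poisson_tail(x, as.numeric(lam_a), log.p = TRUE)
  log_pb <- poisson_tail(x, as.numeric(lam_b), log.p = TRUE)
  tibble::tibble(
    entity_a = entity_a, entity_b = entity_b, overlap = as.integer(x),
    p_a = exp(log_pa), p_b = exp(log_pb),
    p_combined = exp((log_pa + log_pb) / 2),
    clamped = as.logical(clamped)
  )
}

#' All significant entity pairs of a table
#'
#' Computes, for every unordered pair of entities, the causal-set
#' overlap, and returns exactly the pairs with overlap at least
#' `min_overlap` and combined P-value at most `p_max` (the map defaults:
#' two common genes, P <= 0.001). Overlaps are counted by a sparse
#' cross-product, so only qualifying pairs incur a P-value evaluation.
#'
#' @param table The `assoc_tbl` the models were fitted on.
#' @param models An `overlap_models` object for the table's entities.
#' @param min_overlap Minimum number of shared genes (default 2).
#' @param p_max Maximum combined P-value (default 0.001).
#' @return A tibble of pair results sorted by `p_combined` with
#'   `entity_a < entity_b`.
#' @export
all_pairs <- function(table, models, min_overlap = 2L, p_max = 0.001) {
  stopifnot(inherits(table, "assoc_tbl"), inherits(models, "overlap_models"))
  M <- membership_matrix(table)
  entities <- colnames(M)
  if (!all(entities %in% names(models$models))) {
    stop("models missing for some entities of the table", call. = FALSE)
  }
  C <- Matrix::crossprod(M)
  tr <- Matrix::summary(C)
  tr <- tr[tr$i < tr$j & tr$x >= min_overlap, , drop = FALSE]
  if (nrow(tr) == 0) {
    return(tibble::tibble(entity_a = character(), entity_b = character(),
                          overlap = integer(), p_a = double(), p_b = double(),
                          p_combined = double(), clamped = logical()))
  }
  sizes <- models$sizes
  ea <- entities[tr$i]; eb <- entities[tr$j]
  lam_a <- vapply(seq_len(nrow(tr)), function(r)
    as.numeric(predict_lambda(models$models[[ea[r]]], sizes[[eb[r]]])), 0)
  lam_b <- vapply(seq_len(nrow(tr)), function(r)
    as.numeric(predict_lambda(models$models[[eb[r]]], sizes[[ea[r]]])), 0)
  cl_a <- vapply(seq_len(nrow(tr)), function(r)
    attr(predict_lambda(models$models[[ea[r]]], sizes[[eb[r]]]), "clamped"), TRUE)
  cl_b <- vapply(seq_len(nrow(tr)), function(r)
    attr(predict_lambda(models$models[[eb[r]]], sizes[[ea[r]]]), "clamped"), TRUE)
  log_pa <- poisson_tail(tr$x, lam_a, log.p = TRUE)
  log_pb <- poisson_tail(tr$x, lam_b, log.p = TRUE)
  out <- tibble::tibble(
    entity_a = pmin(ea, eb), entity_b = pmax(ea, eb),
    overlap = as.integer(tr$x),
    p_a = exp(log_pa), p_b = exp(log_pb),
    p_combined = exp((log_pa + log_pb) / 2),
    clamped = cl_a | cl_b
  )
  out %>%
    dplyr::filter(.data$p_combined <= p_max) %>%
    dplyr::arrange(.data$p_combined, .data$entity_a, .data$entity_b)
}

#' Write pair results to TSV
#'
#' P-values are serialized in scientific notation with six significant
#' digits.
#'
#' @param pairs Pair tibble from [all_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  out <- pairs %>%
    dplyr::mutate(dplyr::across(dplyr::all_of(c("p_a", "p_b", "p_combined")),
                                ~ formatC(.x, format = "e", digits = 5)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Serialize fitted overlap models to JSON
#'
#' One record per entity: intercept flag, `k_max`, coefficients, AIC,
#' valid size range and fallback flag, plus the sampling metadata.
#'
#' @param models An `overlap_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  rec <- purrr::imap(models$models, function(m, id) {
    list(entity = id, c = m$intercept, k_max = m$k_max,
         betas = as.list(m$betas), aic = m$aic,
         valid_range = m$valid_range, fallback = m$fallback,
         set_size = unname(models$sizes[id]))
  })
  jsonlite::write_json(
    list(n_sets = models$n_sets, seed = models$seed,
         check_range = models$check_range, models = unname(rec)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
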