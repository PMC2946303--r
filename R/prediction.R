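#' Thresholds for two-step causal-gene prediction
#'
#' The working defaults follow the reference analysis: similarity
#' P-value 0.01 and a minimal overlap of two shared causal genes (step
#' 1, disease similarity) or two shared diseases (step 2, gene
#' similarity).
#'
#' @param p_disease,p_gene Maximum combined P-value per step.
#' @param min_overlap_disease,min_overlap_gene Minimum overlap per step.
#' @return A `prediction_thresholds` list.
#' @export
prediction_thresholds <- function(p_disease = 0.01, p_gene = 0.01,
                                  min_overlap_disease = 2L,
                                  min_overlap_gene = 2L) {
  stopifnot(p_disease > 0, p_disease <= 1, p_gene > 0, p_gene <= 1,
            min_overlap_disease >= 1, min_overlap_gene >= 1)
  structure(list(p_disease = p_disease, p_gene = p_gene,
                 min_overlap_disease = as.integer(min_overlap_disease),
                 min_overlap_gene = as.integer(min_overlap_gene)),
            class = "prediction_thresholds")
}

#' Predict causal genes for a disease of interest
#'
#' Two-step guilt-by-association search. Step 1 collects diseases
#' similar to the query (combined P-value at most `p_disease`, overlap
#' at least `min_overlap_disease` shared causal genes). Step 2 tests
#' every gene of the selected diseases — restricted to the
#' gene-comparison universe the gene models were fitted on — against
#' each known causal gene of the query (its anchors in that universe),
#' and predicts genes that share at least `min_overlap_gene` diseases
#' with an anchor at combined P-value at most `p_gene`. Genes already
#' associated with the query are excluded and reported separately.
#'
#' Candidates whose best P-value lies within 10% of `p_gene` are flagged
#' `borderline`: their inclusion is sensitive to the sampling noise of
#' the empirical Poisson-parameter estimation.
#'
#' @param disease Query disease id.
#' @param disease_models [fit_overlap_models()] result on the
#'   disease-comparison table.
#' @param gene_models [fit_overlap_models()] result on the transposed
#'   gene-comparison table (genes with at least five disease links).
#' @param thresholds A [prediction_thresholds()].
#' @return A `prediction_report`: query, thresholds, `similar_diseases`
#'   tibble, `candidates` tibble (gene, best anchor, P-value, shared
#'   disease count, supporting anchors, borderline flag) sorted by
#'   ascending P-value, and `excluded_known`.
#' @export
predict_genes <- function(disease, disease_models, gene_models,
                          thresholds = prediction_thresholds()) {
  stopifnot(inherits(disease_models, "overlap_models"),
            inherits(gene_models, "overlap_models"),
            inherits(thresholds, "prediction_thresholds"))
  dsets <- disease_models$sets
  if (!disease %in% names(dsets)) {
    stop("unknown disease id: ", disease, call. = FALSE)
  }
  set_a <- dsets[[disease]]

  # Step 1: similar diseases
  others <- setdiff(names(dsets), disease)
  sims <- purrr::map_dfr(others, function(b) {
    x <- length(intersect(set_a, dsets[[b]]))
    if (x < thresholds$min_overlap_disease) return(NULL)
    pair_pvalue(set_a, dsets[[b]],
                disease_models$models[[disease]], disease_models$models[[b]],
                disease, b)
  })
  if (nrow(sims) > 0) {
    sims <- sims %>%
      dplyr::filter(.data$p_combined <= thresholds$p_disease) %>%
      dplyr::arrange(.data$p_combined)
  } else {
    sims <- tibble::tibble(entity_a = character(), entity_b = character(),
                           overlap = integer(), p_a = double(), p_b = double(),
                           p_combined = double(), clamped = logical())
  }

  gsets <- gene_models$sets          # gene -> diseases, within the universe
  universe <- names(gsets)
  anchors <- intersect(set_a, universe)
  pool <- unique(unlist(dsets[sims$entity_b], use.names = FALSE))
  excluded_known <- intersect(pool, set_a)
  cand_genes <- setdiff(intersect(pool, universe), set_a)

  candidates <- purrr::map_dfr(cand_genes, function(g) {
    hits <- purrr::map_dfr(anchors, function(a) {
      x <- length(intersect(gsets[[g]], gsets[[a]]))
      if (x < thresholds$min_overlap_gene) return(NULL)
      pair_pvalue(gsets[[g]], gsets[[a]],
                  gene_models$models[[g]], gene_models$models[[a]], g, a)
    })
    if (nrow(hits) == 0) return(NULL)
    hits <- dplyr::filter(hits, .data$p_combined <= thresholds$p_gene)
    if (nrow(hits) == 0) return(NULL)
    best <- hits[which.min(hits$p_combined), ]
    tibble::tibble(
      gene = g, anchor = best$entity_b, p_combined = best$p_combined,
      shared_diseases = best$overlap,
      supporting_anchors = list(hits$entity_b),
      borderline = best$p_combined > 0.9 * thresholds$p_gene
    )
  })
  if (nrow(candidates) > 0) {
    candidates <- dplyr::arrange(candidates, .data$p_combined, .data$gene)
  } else {
    candidates <- tibble::tibble(gene = character(), anchor = character(),
                                 p_combined = double(),
                                 shared_diseases = integer(),
                                 supporting_anchors = list(),
                                 borderline = logical())
  }
  structure(
    list(disease = disease, thresholds = thresholds,
         similar_diseases = sims, candidates = candidates,
         excluded_known = sort(excluded_known)),
    class = "prediction_report"
  )
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("Prediction for %s: %d similar diseases, %d candidate genes (P <= %g, overlap >= %d)\n",
              x$disease, nrow(x$similar_diseases), nrow(x$candidates),
              x$thresholds$p_gene, x$thresholds$min_overlap_gene))
  if (nrow(x$candidates) > 0) print(utils::head(x$candidates, 10))
  invisible(x)
}

#' @export
tidy.prediction_report <- function(x, ...) x$candidates

#' @export
glance.prediction_report <- function(x, ...) {
  tibble::tibble(disease = x$disease,
                 n_similar = nrow(x$similar_diseases),
                 n_candidates = nrow(x$candidates),
                 n_borderline = sum(x$candidates$borderline),
                 n_excluded_known = length(x$excluded_known))
}

#' Serialize a prediction report
#'
#' @param report A `prediction_report`.
#' @param path Output path; `.json` writes JSON, anything else a flat
#'   TSV of candidates.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(disease = report$disease,
           thresholds = unclass(report$thresholds),
           similar_diseases = report$similar_diseases,
           candidates = dplyr::mutate(
             report$candidates,
             supporting_anchors = purrr::map_chr(
               .data$supporting_anchors, paste, collapse = ",")),
           excluded_known = report$excluded_known),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    flat <- report$candidates %>%
      dplyr::mutate(supporting_anchors = purrr::map_chr(
        .data$supporting_anchors, paste, collapse = ","))
    readr::write_tsv(flat, path)
  }
  invisible(path)
}

#' Sweep the prediction P-value threshold
#'
#' Applies the same P-value cut-off to both prediction steps across a
#' grid (the evaluation range 0.001 to 0.1), with the overlap minima
#' fixed, and scores predictions against a truth set: true positive
#' rate over the truth set, false positive rate over the non-truth
#' candidate universe (gene-comparison universe minus the query's known
#' genes and the truth set), and the false-positive proportion among
#' predictions.
#'
#' @param disease Query disease id.
#' @param disease_models,gene_models As in [predict_genes()].
#' @param truth_set Non-empty character vector of reference genes.
#' @param p_grid Numeric vector of P-value thresholds.
#' @param min_overlap Fixed overlap minimum for both steps (default 2).
#' @return A `sweep_result` tibble: `p_threshold`, `n_predicted`, `tp`,
#'   `fp`, `tpr`, `fpr`, `fp_proportion`.
#' @export
threshold_sweep <- function(disease, disease_models, gene_models, truth_set,
                            p_grid = c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1),
                            min_overlap = 2L) {
  if (length(p_grid) == 0) stop("empty threshold grid", call. = FALSE)
  if (length(truth_set) == 0) stop("empty truth set", call. = FALSE)
  known <- disease_models$sets[[disease]]
  universe <- names(gene_models$sets)
  fp_universe <- setdiff(universe, union(known, truth_set))
  rows <- purrr::map_dfr(sort(p_grid), function(p) {
    rep <- predict_genes(disease, disease_models, gene_models,
                         prediction_thresholds(p, p, min_overlap, min_overlap))
    pred <- rep$candidates$gene
    tp <- length(intersect(pred, truth_set))
    fp <- length(setdiff(pred, truth_set))
    tibble::tibble(
      p_threshold = p, n_predicted = length(pred), tp = tp, fp = fp,
      tpr = tp / length(truth_set),
      fpr = if (length(fp_universe) > 0) fp / length(fp_universe) else NA_real_,
      fp_proportion = if (length(pred) > 0) fp / length(pred) else NA_real_
    )
  })
  class(rows) <- c("sweep_result", class(rows))
  rows
}

#' Best-precision threshold of a sweep
#'
#' The P-value cut-off achieving the maximal proportion of true
#' positives among predictions while requiring at least one false
#' positive gene; ties prefer more true positives, then the smaller
#' threshold.
#'
#' @param sweep A [threshold_sweep()] result.
#' @return One row of the sweep with a `precision` column, or an empty
#'   tibble when no threshold yields a false positive.
#' @export
best_precision_threshold <- function(sweep) {
  cand <- sweep %>%
    dplyr::filter(.data$fp >= 1) %>%
    dplyr::mutate(precision = .data$tp / (.data$tp + .data$fp)) %>%
    dplyr::arrange(dplyr::desc(.data$precision), dplyr::desc(.data$tp),
                   .data$p_threshold)
  utils::head(cand, 1)
}

#' Plot a threshold sweep
#'
#' @param object A `sweep_result`.
#' @param ... Ignored.
#' @return A ggplot: ROC curve plus false-positive proportion against
#'   the threshold.
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Leave-k-out cross-validation of gene prediction
#'
#' Per round, removes `n_remove` randomly chosen causal genes of the
#' query disease, re-estimates the Poisson parameters on both axes from
#' fresh random sets on the modified table, re-runs the two-step
#' prediction, and records which removed genes were recovered. The
#' reference protocol uses 20 rounds removing 5 genes with 1e5 random
#' sets per axis.
#'
#' @param disease Query disease id.
#' @param table The disease-comparison `assoc_tbl`.
#' @param n_rounds,n_remove Rounds and genes removed per round
#'   (`n_remove` must be smaller than the query's causal set; 0
#'   reproduces the baseline in every round).
#' @param thresholds A [prediction_thresholds()].
#' @param n_sets_disease,n_sets_gene Random sets per axis for
#'   re-estimation.
#' @param min_gene_diseases Gene-universe threshold (default 5 disease
#'   links).
#' @param seed Integer seed driving removals and all re-sampling.
#' @param baseline Optional precomputed baseline [predict_genes()]
#'   report on the unmodified table.
#' @param chunk_size Sets per sampling block.
#' @return A `cv_report`: per-round tibble (`round`, `removed`,
#'   `n_predicted`, `n_recovered`, `recovery`), per-gene frequency
#'   tibble (`gene`, `freq`, `class` in original-prediction /
#'   removed-known / new), the baseline report and the call parameters.
#' @export
cross_validate <- function(disease, table, n_rounds = 20L, n_remove = 5L,
                           thresholds = prediction_thresholds(),
                           n_sets_disease = 100000L, n_sets_gene = 100000L,
                           min_gene_diseases = 5L, seed = 1L,
                           baseline = NULL, chunk_size = 20000L) {
  stopifnot(inherits(table, "assoc_tbl"))
  known <- entity_sets(table)[[disease]]
  if (is.null(known)) stop("unknown disease id: ", disease, call. = FALSE)
  if (n_remove >= length(known)) {
    stop("n_remove must be smaller than the causal gene set", call. = FALSE)
  }
  set.seed(seed)
  removals <- lapply(seq_len(n_rounds), function(i)
    if (n_remove > 0) sample(known, n_remove) else character())
  round_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_rounds),
                        ncol = 2)

  if (is.null(baseline)) {
    dm <- fit_overlap_models(table, n_sets_disease, seed, chunk_size = chunk_size)
    gt <- transpose_associations(
      filter_min_degree(table, "gene", min_gene_diseases))
    gm <- fit_overlap_models(gt, n_sets_gene, seed + 1L, chunk_size = chunk_size)
    baseline <- predict_genes(disease, dm, gm, thresholds)
  }
  base_pred <- baseline$candidates$gene

  rounds <- vector("list", n_rounds)
  for (i in seq_len(n_rounds)) {
    rem <- removals[[i]]
    tab_r <- new_assoc_tbl(
      dplyr::filter(tibble::as_tibble(table),
                    !(.data$disease_id == disease & .data$gene_symbol %in% rem)))
    dm_r <- fit_overlap_models(tab_r, n_sets_disease, round_seeds[i, 1],
                               chunk_size = chunk_size)
    gt_r <- transpose_associations(
      filter_min_degree(tab_r, "gene", min_gene_diseases))
    gm_r <- fit_overlap_models(gt_r, n_sets_gene, round_seeds[i, 2],
                               chunk_size = chunk_size)
    rep_r <- predict_genes(disease, dm_r, gm_r, thresholds)
    pred <- rep_r$candidates$gene
    rounds[[i]] <- tibble::tibble(
      round = i, removed = list(rem), predicted = list(pred),
      n_predicted = length(pred),
      n_recovered = length(intersect(pred, rem)),
      recovery = if (n_remove > 0) length(intersect(pred, rem)) / n_remove
                 else NA_real_
    )
  }
  rounds <- dplyr::bind_rows(rounds)
  all_pred <- unlist(rounds$predicted, use.names = FALSE)
  gene_freq <- tibble::tibble(gene = all_pred) %>%
    dplyr::count(.data$gene, name = "n_rounds_predicted") %>%
    dplyr::mutate(
      freq = .data$n_rounds_predicted / n_rounds,
      class = dplyr::case_when(
        .data$gene %in% base_pred ~ "original-prediction",
        .data$gene %in% known ~ "removed-known",
        TRUE ~ "new"
      )
    ) %>%
    dplyr::arrange(dplyr::desc(.data$freq), .data$gene)
  structure(
    list(disease = disease, rounds = rounds, gene_freq = gene_freq,
         baseline = baseline, thresholds = thresholds,
         n_rounds = as.integer(n_rounds), n_remove = as.integer(n_remove),
         seed = as.integer(seed)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation for %s: %d rounds removing %d; mean recovery %.2f\n",
              x$disease, x$n_rounds, x$n_remove, mean(x$rounds$recovery)))
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) x$gene_freq

#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    disease = x$disease, n_rounds = x$n_rounds, n_remove = x$n_remove,
    mean_recovery = mean(x$rounds$recovery),
    median_recovery = stats::median(x$rounds$recovery),
    n_genes_predicted = nrow(x$gene_freq)
  )
}

#' Serialize a cross-validation report
#'
#' @param report A `cv_report`.
#' @param path Output path; `.json` writes JSON, anything else the
#'   per-gene frequency TSV.
#' @return `path`, invisibly.
#' @export
write_cv <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(disease = report$disease,
           rounds = dplyr::mutate(
             report$rounds,
             removed = purrr::map_chr(.data$removed, paste, collapse = ","),
             predicted = purrr::map_chr(.data$predicted, paste, collapse = ",")),
           gene_freq = report$gene_freq,
           mean_recovery = mean(report$rounds$recovery)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_tsv(report$gene_freq, path)
  }
  invisible(path)
}

#' Plot cross-validation gene frequencies
#'
#' @param object A `cv_report`.
#' @param ... Ignored.
#' @return A ggplot: per-gene prediction frequency bars coloured by
#'   classification.
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$gene_freq, ggplot2::aes(
    x = stats::reorder(.data$gene, -.data$freq),
    y = .data$freq, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of CV rounds", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
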