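fit_both_axes <- function(tab, n_sets = 10000, seed = 1) {
  dm <- fit_overlap_models(tab, n_sets, seed)
  gt <- transpose_associations(filter_min_degree(tab, "gene", 5))
  gm <- fit_overlap_models(gt, n_sets, seed + 1L)
  list(dm = dm, gm = gm)
}

test_that("a query without similar diseases yields no candidates", {
  tab <- null_table(21, n_diseases = 40, n_genes = 200)
  ms <- fit_both_axes(tab, 5000, seed = 2)
  d <- names(ms$dm$models)[1]
  rep <- predict_genes(d, ms$dm, ms$gm,
                       prediction_thresholds(1e-8, 1e-8, 10, 10))
  expect_equal(nrow(rep$similar_diseases), 0)
  expect_equal(nrow(rep$candidates), 0)
  expect_error(predict_genes("nope", ms$dm, ms$gm), "unknown disease")
})

test_that("prediction recovers a planted gene removed from one module disease", {
  tab <- module_cv_table(11)
  rem_gene <- pick_removable_gene(tab, "PM01")
  tab2 <- as_association_table(dplyr::filter(
    tibble::as_tibble(tab),
    !(disease_id == "PM01" & gene_symbol == rem_gene)))
  ms <- fit_both_axes(tab2, 10000, seed = 3)
  rep <- predict_genes("PM01", ms$dm, ms$gm,
                       prediction_thresholds(0.01, 0.01, 2, 2))
  expect_true(rem_gene %in% rep$candidates$gene)
  # structural invariants of the report
  known <- entity_sets(tab2)[["PM01"]]
  expect_length(intersect(rep$candidates$gene, known), 0)
  expect_true(all(rep$candidates$p_combined <= 0.01))
  expect_true(all(rep$candidates$shared_diseases >= 2))
  expect_true(all(rep$excluded_known %in% known))
  # borderline flag marks candidates within 10% of the cut-off
  bl <- rep$candidates$p_combined > 0.009
  expect_equal(rep$candidates$borderline, bl)
})

test_that("threshold sweeps are monotone and score against the truth set", {
  tab <- module_cv_table(12)
  rem <- grep("^M1_", entity_sets(tab)[["PM01"]], value = TRUE)[1:3]
  tab2 <- as_association_table(dplyr::filter(
    tibble::as_tibble(tab),
    !(disease_id == "PM01" & gene_symbol %in% rem)))
  ms <- fit_both_axes(tab2, 10000, seed = 5)
  sw <- threshold_sweep("PM01", ms$dm, ms$gm, truth_set = rem,
                        p_grid = c(1e-12, 0.001, 0.01, 0.05, 0.1))
  expect_equal(sw$n_predicted[1], 0)           # unattainably strict threshold
  expect_equal(sw$tpr[1], 0)
  expect_true(all(diff(sw$tpr) >= 0))
  expect_true(all(diff(sw$fpr) >= 0))
  expect_true(all(diff(sw$n_predicted) >= 0))
  expect_error(threshold_sweep("PM01", ms$dm, ms$gm, rem, numeric()), "grid")
  expect_error(threshold_sweep("PM01", ms$dm, ms$gm, character()), "truth")
})

test_that("the best-precision rule follows the stated definition", {
  sw <- tibble::tibble(
    p_threshold = c(0.001, 0.005, 0.01, 0.05),
    n_predicted = c(2L, 5L, 8L, 20L),
    tp = c(2L, 4L, 6L, 8L), fp = c(0L, 1L, 2L, 12L),
    tpr = NA_real_, fpr = NA_real_, fp_proportion = NA_real_)
  best <- best_precision_threshold(sw)
  # 0.001 has no false positive and is ineligible; 0.005 gives 4/5
  expect_equal(best$p_threshold, 0.005)
  expect_equal(best$precision, 0.8)
})

test_that("cross-validation with nothing removed reproduces the baseline", {
  tab <- module_cv_table(13)
  cv <- cross_validate("PM01", tab, n_rounds = 2, n_remove = 0,
                       n_sets_disease = 5000, n_sets_gene = 5000, seed = 4)
  base <- sort(cv$baseline$candidates$gene)
  for (i in 1:2) {
    expect_setequal(cv$rounds$predicted[[i]], base)
  }
  expect_true(all(is.na(cv$rounds$recovery)))
  expect_true(all(cv$gene_freq$class == "original-prediction"))
})

test_that("cross-validation is deterministic and classifies genes exhaustively", {
  tab <- module_cv_table(14)
  cv1 <- cross_validate("PM01", tab, n_rounds = 3, n_remove = 3,
                        n_sets_disease = 5000, n_sets_gene = 5000, seed = 9)
  cv2 <- cross_validate("PM01", tab, n_rounds = 3, n_remove = 3,
                        n_sets_disease = 5000, n_sets_gene = 5000, seed = 9)
  expect_identical(cv1$rounds$removed, cv2$rounds$removed)
  expect_identical(cv1$gene_freq, cv2$gene_freq)
  expect_true(all(cv1$gene_freq$class %in%
                    c("original-prediction", "removed-known", "new")))
  expect_true(all(cv1$gene_freq$freq > 0 & cv1$gene_freq$freq <= 1))
  expect_true(all(cv1$rounds$recovery >= 0 & cv1$rounds$recovery <= 1))
  # every original-prediction class member is a baseline candidate
  orig <- cv1$gene_freq$gene[cv1$gene_freq$class == "original-prediction"]
  expect_true(all(orig %in% cv1$baseline$candidates$gene))
  expect_error(cross_validate("PM01", tab, n_rounds = 1,
                              n_remove = length(entity_sets(tab)[["PM01"]])),
               "smaller")
})
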