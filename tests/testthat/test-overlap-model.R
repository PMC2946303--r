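test_that("random-set inclusion frequencies match gene degrees", {
  # a gene linked to every disease is in every set; frequencies track degree/n
  tab <- as_association_table(tibble::tibble(
    disease_id = rep(sprintf("D%02d", 1:20), times = 3),
    gene_symbol = c(rep("all", 20), rep("half", 10), rep("rare", 2),
                    sprintf("f%02d", 1:28)),
    association_type = "causal"
  ))
  S <- sample_random_sets(tab, 4000, seed = 1)
  expect_equal(sum(S[, "all"]), 4000)
  f_half <- sum(S[, "half"]) / 4000
  expect_lt(abs(f_half - 0.5), 3 * sqrt(0.25 / 4000))
  f_rare <- sum(S[, "rare"]) / 4000
  expect_lt(abs(f_rare - 0.1), 3 * sqrt(0.1 * 0.9 / 4000))
  # determinism and chunk invariance
  expect_identical(S, sample_random_sets(tab, 4000, seed = 1))
  expect_identical(S, sample_random_sets(tab, 4000, seed = 1, chunk_size = 7L))
})

test_that("overlap curves aggregate by set size exactly", {
  # hand-built collection: 2 sets of size 10 with overlaps 1 and 3 vs A
  genes <- sprintf("g%02d", 1:20)
  A <- genes[1:5]
  mk <- function(members) as.numeric(genes %in% members)
  S <- Matrix::Matrix(rbind(
    mk(c(genes[1], genes[6:14])),          # size 10, overlap 1
    mk(c(genes[1:3], genes[6:12]))         # size 10, overlap 3
  ), sparse = TRUE)
  colnames(S) <- genes
  cur <- aggregate_overlap_curve(A, S)
  expect_equal(cur, tibble::tibble(X = 10L, Y = 2.0, W = 2L))

  # all-distinct sizes give W = 1 everywhere
  S2 <- Matrix::Matrix(rbind(mk(genes[1]), mk(genes[1:4]), mk(genes[1:8])),
                       sparse = TRUE)
  colnames(S2) <- genes
  expect_equal(aggregate_overlap_curve(A, S2)$W, c(1L, 1L, 1L))

  # exhaustive enumeration oracle on 5 random sets
  set.seed(42)
  mem <- matrix(runif(5 * 20) < 0.4, nrow = 5)
  S3 <- Matrix::Matrix(mem * 1, sparse = TRUE)
  colnames(S3) <- genes
  sizes <- rowSums(mem)
  ovl <- apply(mem, 1, function(r) sum(genes[r] %in% A))
  exp_tbl <- tibble::tibble(X = sizes, ov = ovl) |>
    dplyr::group_by(X) |>
    dplyr::summarise(Y = mean(ov), W = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(X)
  got <- aggregate_overlap_curve(A, S3)
  expect_equal(got$X, as.integer(exp_tbl$X))
  expect_equal(got$Y, exp_tbl$Y)
  expect_equal(got$W, as.integer(exp_tbl$W))
  expect_equal(sum(got$W), 5L)
})

test_that("model selection recovers an exact linear generating model", {
  X <- 5:40
  pts <- tibble::tibble(X = X, Y = 0.1 * X, W = 1000L)
  m <- fit_overlap_model(pts, c(5, 40))
  expect_false(m$fallback)
  grid <- 5:40
  expect_lt(max(abs(predict_lambda(m, grid) - 0.1 * grid)), 1e-6)
})

test_that("constant data yields a flat prediction", {
  pts <- tibble::tibble(X = 5:30, Y = 2, W = 500L)
  m <- fit_overlap_model(pts, c(5, 30))
  expect_lt(max(abs(predict_lambda(m, 5:30) - 2)), 1e-6)
})

test_that("constraint checking rejects invalid low-AIC models", {
  # generating model 0.05*n - 0.2*sqrt(n) + 0.6 is decreasing for n < 4;
  # fit on data from n = 9..25 but check on [2, 25]
  X <- 9:25
  set.seed(1)
  Y <- 0.6 + 0.05 * X - 0.2 * sqrt(X) + rnorm(length(X), 0, 1e-4)
  pts <- tibble::tibble(X = X, Y = Y, W = 2000L)
  m <- fit_overlap_model(pts, c(2, 25))
  # independent oracle: fit all 8 models with plain lm, find valid ones
  oracle <- expand.grid(c = 0:1, k = 1:4)
  oracle$aic <- NA; oracle$valid <- FALSE
  for (i in seq_len(nrow(oracle))) {
    D <- causalmap:::model_design(X, oracle$c[i], oracle$k[i])
    fit <- stats::lm(Y ~ 0 + D, weights = pts$W)
    if (anyNA(coef(fit))) next
    oracle$aic[i] <- AIC(fit)
    pr <- causalmap:::model_design(2:25, oracle$c[i], oracle$k[i]) %*% coef(fit)
    oracle$valid[i] <- all(pr > 0) && all(diff(pr) >= -1e-9)
  }
  expect_true(any(!oracle$valid))             # the fixture bites
  best_global <- which.min(oracle$aic)
  best_valid <- which(oracle$valid)[which.min(oracle$aic[oracle$valid])]
  expect_false(best_global == best_valid)     # global best is rejected
  expect_equal(m$intercept, oracle$c[best_valid])
  expect_equal(m$k_max, oracle$k[best_valid])
  # chosen model's AIC matches the oracle's valid optimum
  expect_equal(m$aic, oracle$aic[best_valid], tolerance = 1e-8)
})

test_that("degenerate designs error and hopeless fits fall back", {
  expect_error(fit_overlap_model(tibble::tibble(X = 5, Y = 1, W = 10), c(1, 10)),
               "degenerate")
  # strictly decreasing data: every decreasing fit is rejected, and the
  # selection falls through to a non-decreasing positive model
  pts <- tibble::tibble(X = 5:20, Y = seq(4, 1, length.out = 16), W = 100L)
  m <- fit_overlap_model(pts, c(5, 20))
  pred <- predict_lambda(m, 5:20)
  expect_true(all(diff(pred) >= -1e-9))
  expect_true(all(pred > 0))
  # an all-zero curve admits no positive model: constant fallback, with
  # predictions floored at the model epsilon
  pts0 <- tibble::tibble(X = 5:20, Y = 0, W = 100L)
  m0 <- fit_overlap_model(pts0, c(5, 20))
  expect_true(m0$fallback)
  expect_equal(as.numeric(predict_lambda(m0, 10)), 1e-9)
})

test_that("poisson_tail matches hand-derived values and is monotone", {
  expect_equal(poisson_tail(0, 5), 1)
  expect_equal(poisson_tail(2, 1), 1 - 2 * exp(-1), tolerance = 1e-12)
  expect_equal(poisson_tail(1, 1e-12), 1e-12, tolerance = 1e-3)
  expect_error(poisson_tail(-1, 1), "x")
  expect_error(poisson_tail(1, 0), "lam")
  # strictly decreasing in x, strictly increasing in lambda
  for (lam in c(0.3, 2, 9)) {
    p <- poisson_tail(0:12, lam)
    expect_true(all(diff(p) < 0))
  }
  for (x in c(1, 4, 9)) {
    p <- poisson_tail(x, c(0.1, 0.5, 1, 3, 8))
    expect_true(all(diff(p) > 0))
  }
})

test_that("pair P-values combine geometrically and respect symmetry", {
  tab <- null_table(3, n_diseases = 40, n_genes = 200)
  m <- fit_overlap_models(tab, 3000, seed = 4)
  sets <- entity_sets(tab)
  ids <- names(sets)
  a <- ids[1]; b <- ids[2]
  r <- pair_pvalue(sets[[a]], sets[[b]], m$models[[a]], m$models[[b]], a, b)
  expect_equal(r$p_combined, sqrt(r$p_a * r$p_b), tolerance = 1e-12)
  r2 <- pair_pvalue(sets[[b]], sets[[a]], m$models[[b]], m$models[[a]], b, a)
  expect_equal(r$p_combined, r2$p_combined, tolerance = 1e-12)
  # disjoint sets: all P-values 1
  r3 <- pair_pvalue(c("zz1", "zz2"), c("qq1"), m$models[[a]], m$models[[b]])
  expect_equal(r3$overlap, 0L)
  expect_equal(r3$p_combined, 1)
  # monotone evidence: larger overlap never increases the combined P
  lam <- 1.7
  p_seq <- sapply(0:6, function(x) poisson_tail(x, lam))
  expect_true(all(diff(p_seq) < 0))
})

test_that("all_pairs equals a brute-force double loop", {
  tab <- null_table(5, n_diseases = 30, n_genes = 120)
  m <- fit_overlap_models(tab, 3000, seed = 6)
  sets <- entity_sets(tab)
  ids <- names(sets)
  got <- all_pairs(tab, m, min_overlap = 2, p_max = 0.5)
  brute <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    r <- pair_pvalue(sets[[ids[i]]], sets[[ids[j]]],
                     m$models[[ids[i]]], m$models[[ids[j]]], ids[i], ids[j])
    if (r$overlap >= 2 && r$p_combined <= 0.5) brute[[length(brute) + 1]] <- r
  }
  brute <- dplyr::bind_rows(brute) |>
    dplyr::arrange(p_combined, entity_a, entity_b)
  expect_equal(nrow(got), nrow(brute))
  expect_equal(got$entity_a, brute$entity_a)
  expect_equal(got$entity_b, brute$entity_b)
  expect_equal(got$p_combined, brute$p_combined, tolerance = 1e-12)
  # p_max = 0 excludes everything; min_overlap excludes 1-gene pairs
  expect_equal(nrow(all_pairs(tab, m, 2, 0)), 0)
  expect_true(all(all_pairs(tab, m, 2, 1)$overlap >= 2))
})

test_that("fitted rates agree with the closed-form expected overlap", {
  tab <- null_table(7, n_diseases = 80, n_genes = 400)
  m <- fit_overlap_models(tab, 20000, seed = 8)
  deg <- gene_degrees(tab)
  n_dis <- dplyr::n_distinct(tab$disease_id)
  p_gene <- setNames(deg$degree / n_dis, deg$gene_symbol)
  mean_size <- sum(p_gene)
  sets <- entity_sets(tab)
  ok <- 0; tot <- 0
  for (id in names(sets)[1:20]) {
    expected <- sum(p_gene[sets[[id]]])
    lam <- as.numeric(predict_lambda(m$models[[id]], mean_size))
    tot <- tot + 1
    if (abs(lam - expected) / expected < 0.15) ok <- ok + 1
  }
  expect_gte(ok / tot, 0.9)
})

test_that("Poisson tail tracks the exact Poisson-binomial and errs conservative", {
  tab <- null_table(9, n_diseases = 50, n_genes = 250)
  deg <- gene_degrees(tab)
  n_dis <- dplyr::n_distinct(tab$disease_id)
  # keep per-gene inclusion probabilities modest: the Poisson law is a good
  # surrogate for the Poisson-binomial only away from near-certain genes
  genes <- deg$gene_symbol[deg$degree / n_dis <= 0.21]  # cap at the corpus hub extreme
  set.seed(17)
  for (trial in 1:5) {
    A <- sample(genes, sample(6:12, 1))
    probs <- deg$degree[match(A, deg$gene_symbol)] / n_dis
    lam <- sum(probs)
    for (x in 1:6) {
      exact <- poisbinom_tail_oracle(x, probs)
      if (exact < 1e-6) break
      approx <- poisson_tail(x, lam)
      # the Poisson surrogate never understates the exact tail by 2x ...
      expect_gt(approx / exact, 0.5)
      # ... and within the bulk of the tail it agrees to within 2x; deeper
      # down it overstates (bounded support decays faster), i.e. the
      # resulting P-values are conservative, never anti-conservative
      if (exact >= 1e-2) expect_lt(approx / exact, 2)
    }
  }
})

test_that("model serialization round-trips predictions", {
  tab <- null_table(4, n_diseases = 30, n_genes = 120)
  m <- fit_overlap_models(tab, 2000, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_models(m, path)
  back <- read_models(path, tab)
  for (id in names(m$models)[1:5]) {
    expect_equal(as.numeric(predict_lambda(back$models[[id]], 10)),
                 as.numeric(predict_lambda(m$models[[id]], 10)),
                 tolerance = 1e-9)
  }
  expect_identical(back$sets, m$sets)
})
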