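#' Poisson upper-tail probability
#'
#' `P(X >= x)` for `X ~ Poisson(lam)`, the significance of observing at
#' least `x` shared genes when the expected overlap is `lam`. Computed
#' through the regularized incomplete gamma function (`stats::ppois`
#' upper tail), which is accurate for extreme tails; `x = 0` returns 1.
#'
#' @param x Non-negative integer count(s).
#' @param lam Positive Poisson mean(s).
#' @param log.p Return the natural log of the tail probability.
#' @return Tail probability in (0, 1] (or its log), vectorized.
#' @export
poisson_tail <- function(x, lam, log.p = FALSE) {
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  if (any(lam <= 0)) stop("lam must be > 0", call. = FALSE)
  stats::ppois(x - 1, lam, lower.tail = FALSE, log.p = log.p)
}

# Design matrix of the regression family: optional intercept plus
# n^(1/k) terms for k = 1..k_max. k_max = 0 encodes the constant
# fallback model (intercept only).
model_design <- function(n, intercept, k_max) {
  cols <- list()
  if (intercept == 1) cols$b0 <- rep(1, length(n))
  if (k_max >= 1) {
    for (k in seq_len(k_max)) cols[[paste0("b", k)]] <- n^(1 / k)
  }
  do.call(cbind, cols)
}

predict_family <- function(n, intercept, k_max, betas) {
  drop(model_design(n, intercept, k_max) %*% betas)
}

#' Fit the overlap-versus-size regression with AIC model selection
#'
#' Fits, by weighted least squares (weights `W`), all eight members of
#' the family `lambda(n) = c*b0 + sum_{k=1..k_max} b_k * n^(1/k)` with
#' `c` in \{0, 1\} and `k_max` in 1..4, and selects the lowest-AIC model
#' among those that are non-decreasing and strictly positive on the
#' integer grid spanned by `check_range` (the range of causal-set sizes
#' in the original data, where the model will be evaluated). If no
#' candidate satisfies the constraints, the intercept-free linear model
#' is used as a fallback; if even its slope is non-positive, a constant
#' model equal to the weighted mean overlap is returned. Fallbacks are
#' flagged.
#'
#' @param points Tibble with columns `X`, `Y`, `W` from
#'   [aggregate_overlap_curve()]; at least two distinct `X` are required.
#' @param check_range Length-2 numeric: the \[n_min, n_max\] interval on
#'   which monotonicity and positivity are enforced.
#' @return An `overlap_model`: list with `intercept`, `k_max`, `betas`,
#'   `aic`, `valid_range`, `fallback`, `floor_epsilon` and the candidate
#'   table.
#' @export
fit_overlap_model <- function(points, check_range) {
  stopifnot(all(c("X", "Y", "W") %in% names(points)), length(check_range) == 2)
  points <- points[points$W >= 1, , drop = FALSE]
  if (length(unique(points$X)) < 2) {
    stop("degenerate design: need at least two distinct set sizes", call. = FALSE)
  }
  grid <- seq(floor(check_range[1]), ceiling(check_range[2]))
  grid <- grid[grid >= 1]
  if (length(grid) == 0) grid <- 1

  cand <- expand.grid(intercept = 0:1, k_max = 1:4)
  fits <- vector("list", nrow(cand))
  aics <- rep(NA_real_, nrow(cand))
  valid <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    D <- model_design(points$X, cand$intercept[i], cand$k_max[i])
    df <- data.frame(Y = points$Y, D)
    fml <- stats::as.formula(paste("Y ~ 0 +", paste(colnames(D), collapse = " + ")))
    fit <- try(stats::lm(fml, data = df, weights = points$W), silent = TRUE)
    if (inherits(fit, "try-error") || anyNA(stats::coef(fit))) next
    betas <- stats::coef(fit)
    pred <- predict_family(grid, cand$intercept[i], cand$k_max[i], betas)
    fits[[i]] <- betas
    aics[i] <- stats::AIC(fit)
    valid[i] <- all(pred > 0) && all(diff(pred) >= -1e-9)
  }

  fallback <- FALSE
  if (any(valid)) {
    best <- which(valid)[which.min(aics[valid])]
    intercept <- cand$intercept[best]
    k_max <- cand$k_max[best]
    betas <- fits[[best]]
    aic <- aics[best]
  } else {
    fallback <- TRUE
    fit <- stats::lm(Y ~ 0 + X, data = points, weights = points$W)
    slope <- unname(stats::coef(fit)[1])
    if (is.finite(slope) && slope > 0) {
      intercept <- 0L; k_max <- 1L
      betas <- c(b1 = slope)
      aic <- stats::AIC(fit)
    } else {
      intercept <- 1L; k_max <- 0L
      betas <- c(b0 = stats::weighted.mean(points$Y, points$W))
      aic <- NA_real_
    }
  }

  structure(
    list(
      intercept = as.integer(intercept), k_max = as.integer(k_max),
      betas = betas, aic = aic,
      valid_range = as.integer(c(floor(check_range[1]), ceiling(check_range[2]))),
      fallback = fallback, floor_epsilon = 1e-9,
      candidates = tibble::tibble(intercept = cand$intercept, k_max = cand$k_max,
                                  aic = aics, valid = valid),
      points = tibble::as_tibble(points)
    ),
    class = "overlap_model"
  )
}

#' Predicted mean overlap at a given random-set size
#'
#' Evaluates the selected regression model at set size `n`. Sizes outside
#' the model's valid range are clamped to the nearest boundary (the model
#' is never extrapolated beyond the sizes it was validated on), and
#' predictions are floored at the model's epsilon so the Poisson tail
#' stays defined.
#'
#' @param model An `overlap_model`.
#' @param n Numeric vector of set sizes.
#' @return Numeric vector of Poisson rates; attribute `"clamped"` is a
#'   logical vector marking clamped inputs.
#' @export
predict_lambda <- function(model, n) {
  stopifnot(inherits(model, "overlap_model"))
  lo <- model$valid_range[1]; hi <- model$valid_range[2]
  clamped <- n < lo | n > hi
  nn <- pmin(pmax(n, lo), hi)
  lam <- if (model$k_max == 0) {
    rep(unname(model$betas["b0"]), length(nn))
  } else {
    predict_family(nn, model$intercept, model$k_max, model$betas)
  }
  lam <- pmax(lam, model$floor_epsilon)
  attr(lam, "clamped") <- clamped
  lam
}

#' @export
print.overlap_model <- function(x, ...) {
  form <- if (x$k_max == 0) "constant" else {
    paste0(if (x$intercept) "b0 + " else "",
           paste(sprintf("b%d*n^(1/%d)", 1:x$k_max, 1:x$k_max), collapse = " + "))
  }
  cat(sprintf("Overlap model: %s; AIC %.2f; valid on [%d, %d]%s\n",
              form, x$aic, x$valid_range[1], x$valid_range[2],
              if (x$fallback) " (fallback)" else ""))
  print(round(x$betas, 6))
  invisible(x)
}

#' Fit overlap models for every entity of a table
#'
#' Runs the full null-model pipeline: samples `n_sets` frequency-
#' preserving random sets, aggregates each entity's overlap curve, and
#' fits the AIC-selected regression per entity. The constraint grid is
#' the range of causal-set sizes observed among the table's entities
#' (the sizes at which the models will later be evaluated), unless
#' overridden.
#'
#' @param table An `assoc_tbl` (pass [transpose_associations()] output
#'   for gene-side models).
#' @param n_sets Number of random sets (200000 for the headline
#'   disease-side analysis, 100000 for gene-side and cross-validation
#'   re-estimation; tests use smaller values).
#' @param seed Integer seed for the sampling.
#' @param check_range Optional length-2 override of the constraint grid.
#' @param chunk_size Sets per internal block.
#' @return An `overlap_models` object: named list of per-entity
#'   `overlap_model`s plus the entity set sizes and sampling metadata.
#' @export
fit_overlap_models <- function(table, n_sets = 200000L, seed = 1L,
                               check_range = NULL, chunk_size = 20000L) {
  oc <- overlap_curves(table, n_sets, seed, chunk_size)
  if (is.null(check_range)) check_range <- range(oc$sizes)
  models <- lapply(oc$curves, fit_overlap_model, check_range = check_range)
  structure(
    list(models = models, sizes = oc$sizes, sets = entity_sets(table),
         n_sets = as.integer(n_sets), seed = as.integer(seed),
         check_range = check_range),
    class = "overlap_models"
  )
}

#' @export
print.overlap_models <- function(x, ...) {
  cat(sprintf("Overlap models for %d entities (n_sets = %d, seed = %d); %d fallback\n",
              length(x$models), x$n_sets, x$seed,
              sum(vapply(x$models, `[[`, TRUE, "fallback"))))
  invisible(x)
}

#' @export
tidy.overlap_models <- function(x, ...) {
  purrr::imap_dfr(x$models, function(m, id) {
    b <- stats::setNames(rep(NA_real_, 5), paste0("b", 0:4))
    b[names(m$betas)] <- m$betas
    tibble::tibble(entity = id, set_size = unname(x$sizes[id]),
                   intercept = m$intercept, k_max = m$k_max,
                   !!!as.list(b), aic = m$aic, fallback = m$fallback)
  })
}

#' @export
glance.overlap_models <- function(x, ...) {
  tibble::tibble(
    n_entities = length(x$models), n_sets = x$n_sets, seed = x$seed,
    n_fallback = sum(vapply(x$models, `[[`, TRUE, "fallback")),
    check_min = x$check_range[1], check_max = x$check_range[2]
  )
}

#' Plot an overlap regression curve and its selected model
#'
#' @param object An `overlap_model`.
#' @param ... Ignored.
#' @return A ggplot: regression points sized by weight with the fitted
#'   mean-overlap curve.
#' @export
autoplot.overlap_model <- function(object, ...) {
  grid <- seq(min(object$points$X), max(object$points$X), length.out = 200)
  fitted <- tibble::tibble(X = grid, Y = predict_lambda(object, grid))
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$X, y = .data$Y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$W), alpha = 0.5) +
    ggplot2::geom_line(data = fitted, colour = "firebrick") +
    ggplot2::labs(x = "random set size", y = "mean overlap",
                  size = "sets") +
    ggplot2::theme_minimal()
}
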