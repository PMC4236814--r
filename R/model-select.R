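#' van der Voet randomization test of two cross-validated models
#'
#' Compares a candidate model's held-out squared residuals to those of the
#' PRESS-minimizing reference. The statistic is
#' `C = sum(r_candidate^2 - r_reference^2)`; the null is built by swapping
#' the paired squared residuals within each (sample, response) cell with
#' probability 1/2, and the one-sided p-value is the proportion of
#' randomized statistics at least as large as the observed one (candidate
#' worse).
#'
#' @param residuals_candidate n x t held-out residual matrix of the
#'   candidate model.
#' @param residuals_reference matching residual matrix of the reference
#'   (PRESS-minimizing) model.
#' @param n_randomizations randomizations (default 2000; fewer than 100
#'   warns).
#' @param seed integer seed.
#' @return the randomization p-value.
#' @export
van_der_voet_test <- function(residuals_candidate, residuals_reference,
                              n_randomizations = 2000, seed = 1) {
  rc <- as.matrix(residuals_candidate); rr <- as.matrix(residuals_reference)
  if (!all(dim(rc) == dim(rr))) stop("residual matrices must match in shape")
  if (n_randomizations < 100)
    warning("fewer than 100 randomizations: unstable p-value")
  d <- as.vector(rc^2 - rr^2)
  obs <- sum(d)
  m <- length(d)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  signs <- matrix(ifelse(stats::runif(n_randomizations * m) < 0.5, -1, 1),
                  nrow = n_randomizations)
  stats_perm <- drop(signs %*% d)
  mean(stats_perm >= obs - 1e-12)
}

#' Cross-validated PRESS curve for PLS factor selection
#'
#' Runs k-fold cross-validation of [gbpls()] over candidate factor counts
#' 0..`max_factors` (0 = training-mean prediction) and records the root mean
#' PRESS, `sqrt(PRESS / (n * t))`, per count. For every count below the
#' PRESS-minimizing one, a van der Voet randomization p-value against the
#' minimizer is computed; the minimizer's own p is 1 by construction.
#'
#' Fold assignment is keyed to sample ids sorted lexicographically (row
#' order therefore does not affect the folds): `interleaved` deals every
#' k-th sample to the same fold; `seeded_random` shuffles with the seed.
#' Centering/scaling is recomputed inside each training fold.
#'
#' @param S,T_block predictor and response blocks (see [gbpls()]).
#' @param max_factors largest factor count evaluated; default as in
#'   [gbpls()].
#' @param k_folds folds (default 7).
#' @param fold_scheme `"interleaved"` (default) or `"seeded_random"`.
#' @param seed integer seed (fold shuffling and randomization tests).
#' @param n_randomizations randomizations per van der Voet test.
#' @param alpha significance level used by [select_n_factors()]
#'   (default 0.10).
#' @param scale passed to [gbpls()].
#' @return object of class `press_curve`: data frame `curve` (factors,
#'   root_mean_press, vdv_p), `folds`, held-out `residuals` per count,
#'   `argmin` and `selected` counts.
#' @export
cv_press <- function(S, T_block, max_factors = NULL, k_folds = 7,
                     fold_scheme = c("interleaved", "seeded_random"),
                     seed = 1, n_randomizations = 2000, alpha = 0.10,
                     scale = TRUE) {
  fold_scheme <- match.arg(fold_scheme)
  X <- as.matrix(S); Y <- as.matrix(T_block)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  n <- nrow(X); t <- ncol(Y)
  if (n < k_folds) stop("more folds than samples; use fewer folds")
  ids <- rownames(X) %||% sprintf("s%06d", seq_len(n))
  ord <- order(ids)
  folds <- integer(n)
  if (fold_scheme == "interleaved") {
    folds[ord] <- ((seq_len(n) - 1L) %% k_folds) + 1L
  } else {
    old <- set_local_seed(seed)
    folds[ord] <- sample(((seq_len(n) - 1L) %% k_folds) + 1L)
    restore_seed(old)
  }
  if (min(table(folds)) < 2)
    stop("a fold has fewer than 2 samples; use fewer folds")
  if (is.null(max_factors))
    max_factors <- min(ncol(X), t, n - ceiling(n / k_folds) - 1L, 10L)
  max_factors <- max(1L, max_factors)

  # residual array per candidate count: held-out residuals assembled over folds
  res <- lapply(0:max_factors, function(r) matrix(NA_real_, n, t))
  r_reached <- max_factors
  for (f in seq_len(k_folds)) {
    tr <- folds != f; te <- !tr
    fit <- suppressWarnings(
      gbpls(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
            max_factors = max_factors, scale = scale))
    r_reached <- min(r_reached, fit$n_factors)
    for (r in 0:max_factors) {
      r_use <- min(r, fit$n_factors)
      pred <- predict(fit, X[te, fit$x_names, drop = FALSE],
                      n_factors = r_use)
      res[[r + 1L]][te, ] <- Y[te, , drop = FALSE] - pred
    }
  }
  rmp <- vapply(res, function(m) sqrt(sum(m^2) / (n * t)), numeric(1))
  counts <- 0:max_factors
  argmin <- counts[which.min(rmp)]
  vdv <- rep(NA_real_, length(counts))
  vdv[counts == argmin] <- 1
  for (r in counts[counts < argmin]) {
    vdv[counts == r] <- van_der_voet_test(
      res[[r + 1L]], res[[argmin + 1L]],
      n_randomizations = n_randomizations, seed = seed + r + 1L)
  }
  curve <- structure(list(
    curve = data.frame(factors = counts, root_mean_press = rmp,
                       vdv_p = vdv),
    folds = folds, residuals = res, argmin = argmin,
    k_folds = k_folds, fold_scheme = fold_scheme, alpha = alpha,
    r_reached = r_reached), class = "press_curve")
  curve$selected <- select_n_factors(curve, alpha = alpha)
  curve
}

#' Select the number of genetic factors from a PRESS curve
#'
#' The final model is the one with the fewest factors whose root mean PRESS
#' is insignificantly larger than the minimum: the smallest count with van
#' der Voet p >= `alpha`; the PRESS-minimizing count if none qualifies.
#'
#' @param curve a `press_curve` from [cv_press()].
#' @param alpha significance level (default 0.10).
#' @return the selected factor count (integer, possibly 0).
#' @export
select_n_factors <- function(curve, alpha = 0.10) {
  stopifnot(inherits(curve, "press_curve"))
  cu <- curve$curve
  below <- cu[cu$factors < curve$argmin, , drop = FALSE]
  ok <- below$factors[!is.na(below$vdv_p) & below$vdv_p >= alpha]
  if (length(ok)) min(ok) else curve$argmin
}

#' @export
print.press_curve <- function(x, ...) {
  cat(sprintf("PRESS curve (%d-fold CV, %s folds): argmin at %d, selected %d\n",
              x$k_folds, x$fold_scheme, x$argmin, x$selected))
  print(x$curve, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.press_curve <- function(x, ...) {
  plot(x$curve$factors, x$curve$root_mean_press, type = "b",
       xlab = "extracted genetic factors", ylab = "root mean PRESS", ...)
  graphics::abline(v = x$selected, lty = 2)
  invisible(x)
}
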