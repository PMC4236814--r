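#' Mean-impute missing genotype codes
#'
#' Replaces missing values by the column mean of the observed values.
#'
#' @param X numeric matrix with possible `NA`s.
#' @return complete matrix. A fully-missing column is an error naming it.
#' @export
impute_missing <- function(X) {
  X <- as.matrix(X)
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (all(miss))
      stop("column '", colnames(X)[j] %||% j, "' is fully missing")
    if (any(miss)) X[miss, j] <- mean(X[!miss, j])
  }
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gene-based partial least squares (NIPALS)
#'
#' Fits a two-block PLS regression relating an S-gene SNP block `S` (the
#' predictors, n x s additive genotype codes) to a T-gene transcript block
#' `T` (the responses, n x t expression values). Latent factors are
#' extracted one at a time by the NIPALS algorithm: paired X- and Y-scores
#' are found that maximize the covariance between the blocks, both blocks
#' are deflated by the regression on the X-score, and the procedure repeats.
#' Both blocks are centered and unit-variance scaled using the training
#' statistics.
#'
#' @param S n x s predictor matrix (no missing values; see
#'   [impute_missing()]).
#' @param T_block n x t response matrix.
#' @param max_factors maximum factors to extract; default
#'   `min(s, t, n - 1, 10)`.
#' @param tol relative convergence tolerance of the NIPALS score iteration.
#' @param max_iter iteration cap per factor (non-convergence is a warning).
#' @param scale unit-variance scale both blocks (default TRUE).
#' @return an object of class `gbpls` with components: `weights_s` (s x r),
#'   `weights_t` (t x r), `scores_s`, `scores_t` (n x r), `loadings_s`
#'   (s x r), `loadings_t` (t x r, the combined Y-loadings used for
#'   deflation and prediction), `explained_s`, `explained_t` (per-factor
#'   proportions of block variance), `cancor` (per-factor score
#'   correlation), centering/scaling vectors, and `n_factors`.
#'
#' Zero-variance columns are dropped with a warning (their indices are kept
#' in `dropped_s` / `dropped_t`). The fitted object predicts via
#' [predict.gbpls()]; with 0 factors the prediction is the training mean.
#' @export
gbpls <- function(S, T_block, max_factors = NULL, tol = 1e-9,
                  max_iter = 500, scale = TRUE) {
  X0 <- as.matrix(S); Y0 <- as.matrix(T_block)
  if (nrow(X0) != nrow(Y0)) stop("S and T blocks must have equal row counts")
  n <- nrow(X0)
  if (n < 3) stop("need at least 3 samples")
  if (anyNA(X0) || anyNA(Y0))
    stop("missing values: impute genotypes upstream (impute_missing)")
  if (is.null(colnames(X0))) colnames(X0) <- paste0("x", seq_len(ncol(X0)))
  if (is.null(colnames(Y0))) colnames(Y0) <- paste0("y", seq_len(ncol(Y0)))

  drop_const <- function(M, what) {
    sds <- apply(M, 2, stats::sd)
    bad <- sds < 1e-12 | !is.finite(sds)
    if (any(bad))
      warning(sprintf("dropping %d zero-variance %s column(s): %s",
                      sum(bad), what,
                      paste(colnames(M)[bad], collapse = ", ")))
    list(m = M[, !bad, drop = FALSE], dropped = colnames(M)[bad])
  }
  dx <- drop_const(X0, "S-block")
  X0 <- dx$m
  # a constant T-block is legal input (zero signal); keep columns, scale = 1
  y_sd_raw <- apply(Y0, 2, stats::sd)

  if (ncol(X0) == 0L) stop("no non-constant S-block columns left")
  s <- ncol(X0); t <- ncol(Y0)
  if (is.null(max_factors)) max_factors <- min(s, t, n - 1L, 10L)
  max_factors <- max(1L, as.integer(max_factors))

  x_center <- colMeans(X0)
  y_center <- colMeans(Y0)
  x_scale <- if (scale) apply(X0, 2, stats::sd) else rep(1, s)
  y_scale <- if (scale) ifelse(y_sd_raw < 1e-12, 1, y_sd_raw) else rep(1, t)
  X <- sweep(sweep(X0, 2, x_center), 2, x_scale, "/")
  Y <- sweep(sweep(Y0, 2, y_center), 2, y_scale, "/")
  ssx0 <- sum(X^2); ssy0 <- sum(Y^2)

  W <- P <- matrix(0, s, 0); Q <- C <- matrix(0, t, 0)
  Ts <- U <- matrix(0, n, 0)
  expl_s <- expl_t <- cc <- numeric(0)

  for (a in seq_len(max_factors)) {
    if (sum(X^2) < 1e-10 * max(ssx0, 1)) break
    # zero Y residual: no covariance left to model
    if (sum(Y^2) < 1e-12 * max(ssy0, 1)) break
    u <- Y[, which.max(apply(Y, 2, stats::var))]
    if (stats::sd(u) < 1e-14) u <- Y[, 1]
    t_old <- rep(0, n); converged <- FALSE
    w <- q <- NULL; tt <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(X, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      tt <- drop(X %*% w)
      q <- crossprod(Y, tt)
      nq <- sqrt(sum(q^2))
      if (nq < 1e-14) break
      q <- q / nq
      u <- drop(Y %*% q)
      if (sqrt(sum((tt - t_old)^2)) < tol * max(sqrt(sum(tt^2)), 1e-300)) {
        converged <- TRUE; break
      }
      t_old <- tt
    }
    if (is.null(tt) || sum(tt^2) < 1e-14) break
    if (!converged && t > 1)
      warning(sprintf("NIPALS factor %d: not converged in %d iterations",
                      a, max_iter))
    # sign canonicalization: largest-magnitude X-weight entry positive
    jmax <- which.max(abs(w))
    if (w[jmax] < 0) { w <- -w; tt <- -tt; q <- -q; u <- -u }
    tt2 <- sum(tt^2)
    p <- crossprod(X, tt) / tt2          # X-loading
    cvec <- crossprod(Y, tt) / tt2       # combined Y-loading (for deflation)
    X <- X - tcrossprod(tt, p)
    Y <- Y - tcrossprod(tt, cvec)
    W <- cbind(W, w); P <- cbind(P, p); Q <- cbind(Q, q); C <- cbind(C, cvec)
    Ts <- cbind(Ts, tt); U <- cbind(U, u)
    expl_s <- c(expl_s, tt2 * sum(p^2) / ssx0)
    expl_t <- c(expl_t, if (ssy0 > 0) tt2 * sum(cvec^2) / ssy0 else 0)
    cc <- c(cc, if (stats::sd(u) > 1e-14 && stats::sd(tt) > 1e-14)
      stats::cor(tt, u) else NA_real_)
  }
  r <- ncol(W)
  dn <- function(m, cn) { if (!is.null(m) && ncol(m) > 0)
    dimnames(m) <- list(cn, paste0("f", seq_len(ncol(m)))); m }
  structure(list(
    n = n, s = s, t = t, n_factors = r,
    weights_s = dn(W, colnames(X0)), weights_t = dn(Q, colnames(Y0)),
    scores_s = dn(Ts, rownames(X0)), scores_t = dn(U, rownames(X0)),
    loadings_s = dn(P, colnames(X0)), loadings_t = dn(C, colnames(Y0)),
    explained_s = expl_s, explained_t = expl_t, cancor = cc,
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    x_names = colnames(X0), y_names = colnames(Y0),
    dropped_s = dx$dropped,
    call = match.call()), class = "gbpls")
}

# coefficient matrix mapping centered/scaled X to centered/scaled Y using
# the first r factors: B = W (P'W)^-1 C'
gbpls_coef_scaled <- function(object, n_factors) {
  r <- n_factors
  if (r == 0L) return(matrix(0, object$s, object$t))
  W <- object$weights_s[, seq_len(r), drop = FALSE]
  P <- object$loadings_s[, seq_len(r), drop = FALSE]
  C <- object$loadings_t[, seq_len(r), drop = FALSE]
  W %*% solve(crossprod(P, W), t(C))
}

#' PLS regression coefficients on the original scale
#'
#' @param object a [gbpls()] fit.
#' @param n_factors factors to use (default: all extracted).
#' @param ... unused.
#' @return list with `B` (s x t matrix so that `T_hat = S %*% B` plus
#'   intercept) and `intercept` (length-t vector).
#' @export
coef.gbpls <- function(object, n_factors = object$n_factors, ...) {
  Bsc <- gbpls_coef_scaled(object, n_factors)
  B <- diag(1 / object$x_scale, object$s) %*% Bsc %*%
    diag(object$y_scale, object$t)
  dimnames(B) <- list(object$x_names, object$y_names)
  intercept <- object$y_center - drop(object$x_center %*% B)
  list(B = B, intercept = intercept)
}

#' Predict transcript values from genotypes
#'
#' @param object a [gbpls()] fit.
#' @param newdata m x s matrix with the model's predictor columns (extra
#'   columns, e.g. ones dropped as constant at fit time, are ignored if
#'   named).
#' @param n_factors number of factors to use, `0..object$n_factors`;
#'   0 predicts the training mean of the T-block.
#' @param ... unused.
#' @return m x t matrix of predictions on the original response scale.
#' @export
predict.gbpls <- function(object, newdata, n_factors = object$n_factors,
                          ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$x_names %in% colnames(newdata)))
    newdata <- newdata[, object$x_names, drop = FALSE]
  if (ncol(newdata) != object$s)
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(newdata), object$s))
  if (n_factors < 0 || n_factors > object$n_factors)
    stop("n_factors must be in 0..", object$n_factors)
  co <- coef(object, n_factors = n_factors)
  out <- sweep(newdata %*% co$B, 2, co$intercept, "+")
  colnames(out) <- object$y_names
  out
}

#' @export
fitted.gbpls <- function(object, n_factors = object$n_factors, ...) {
  # reconstruct fitted scaled Y from X-scores and combined Y-loadings
  r <- n_factors
  Ysc <- if (r == 0L) matrix(0, object$n, object$t) else
    object$scores_s[, seq_len(r), drop = FALSE] %*%
    t(object$loadings_t[, seq_len(r), drop = FALSE])
  sweep(sweep(Ysc, 2, object$y_scale, "*"), 2, object$y_center, "+")
}

#' @export
residuals.gbpls <- function(object, T_block = NULL,
                            n_factors = object$n_factors, ...) {
  if (is.null(T_block))
    stop("supply the training T-block to compute residuals")
  as.matrix(T_block) - fitted(object, n_factors = n_factors)
}

#' Canonical correlation of a PLS factor
#'
#' Pearson correlation between the X-score and Y-score of a factor; the
#' first factor's value is the reported strength of an S-gene/T-gene
#' association.
#'
#' @param model a [gbpls()] fit.
#' @param factor factor index (default 1).
#' @return correlation in \[-1, 1\]; `NA` if a score has zero variance.
#' @export
canonical_correlation <- function(model, factor = 1) {
  stopifnot(inherits(model, "gbpls"))
  if (factor < 1 || factor > model$n_factors)
    stop("factor must be in 1..", model$n_factors)
  model$cancor[factor]
}

#' @export
print.gbpls <- function(x, ...) {
  cat(sprintf("gene-based PLS fit: n=%d, s=%d SNPs, t=%d probes, %d factor(s)\n",
              x$n, x$s, x$t, x$n_factors))
  if (x$n_factors > 0) {
    cat(sprintf("  first-factor canonical correlation: %.4f\n", x$cancor[1]))
    cat(sprintf("  explained variation: S-block %.3f, T-block %.3f\n",
                sum(x$explained_s), sum(x$explained_t)))
  }
  invisible(x)
}

#' @export
summary.gbpls <- function(object, ...) {
  tab <- data.frame(factor = seq_len(object$n_factors),
                    explained_s = object$explained_s,
                    explained_t = object$explained_t,
                    cum_explained_s = cumsum(object$explained_s),
                    cum_explained_t = cumsum(object$explained_t),
                    cancor = object$cancor)
  structure(list(fit = object, table = tab), class = "summary.gbpls")
}

#' @export
print.summary.gbpls <- function(x, ...) {
  print(x$fit)
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Score plot for a PLS fit
#'
#' Plots paired X- and Y-scores of one factor; a tight diagonal indicates a
#' strong S-gene/T-gene association.
#'
#' @param x a [gbpls()] fit.
#' @param factor factor to plot.
#' @param ... passed to [plot()].
#' @export
plot.gbpls <- function(x, factor = 1, ...) {
  if (x$n_factors < 1) stop("no factors to plot")
  plot(x$scores_s[, factor], x$scores_t[, factor],
       xlab = sprintf("S-block score (factor %d)", factor),
       ylab = sprintf("T-block score (factor %d)", factor),
       main = sprintf("canonical correlation = %.3f", x$cancor[factor]), ...)
  invisible(x)
}
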