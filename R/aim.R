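#' Linear discriminant fit on genotype codes
#'
#' Flexible discriminant analysis with a linear basis, i.e. linear
#' discriminant analysis with pooled within-class covariance and sample
#' priors. A singular within-class scatter (e.g. a SNP constant within
#' classes) is handled by a small ridge jitter with a warning.
#'
#' @param X n x m matrix of predictors (additive genotype codes).
#' @param labels length-n class vector (>= 2 classes, each with >= 2
#'   samples in `X`).
#' @param ridge ridge added to the within-class covariance diagonal when it
#'   is numerically singular (default 1e-8 of the mean diagonal).
#' @return object of class `fda_fit`: discriminant coefficients and
#'   intercepts per class, class `levels`, `priors`, training `predictions`
#'   and `accuracy`.
#' @export
fda_fit <- function(X, labels, ridge = 1e-8) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  g <- factor(labels)
  if (nlevels(g) < 2) stop("need at least 2 classes")
  if (any(table(g) < 2)) stop("every class needs >= 2 training samples")
  if (nrow(X) != length(g)) stop("X rows and labels differ in length")
  n <- nrow(X); m <- ncol(X); K <- nlevels(g)
  mu <- matrix(vapply(levels(g), function(lev)
    colMeans(X[g == lev, , drop = FALSE]), numeric(m)),
    nrow = K, ncol = m, byrow = TRUE,
    dimnames = list(levels(g), colnames(X)))
  Wc <- matrix(0, m, m)
  for (lev in levels(g)) {
    Xi <- X[g == lev, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    Wc <- Wc + crossprod(Xi)
  }
  Wc <- Wc / (n - K)
  ok <- tryCatch({ solve(Wc); TRUE }, error = function(e) FALSE)
  if (!ok || rcond(Wc) < 1e-12) {
    warning("singular within-class scatter: adding ridge jitter")
    Wc <- Wc + diag(ridge * max(mean(diag(Wc)), 1), m)
  }
  Wi <- solve(Wc)
  priors <- as.numeric(table(g)) / n
  coefs <- Wi %*% t(mu)                        # m x K
  icepts <- -0.5 * colSums(t(mu) * coefs) + log(priors)
  scores <- X %*% coefs + matrix(icepts, n, K, byrow = TRUE)
  pred <- factor(levels(g)[max.col(scores, ties.method = "first")],
                 levels = levels(g))
  structure(list(coefficients = coefs, intercepts = icepts,
                 levels = levels(g), priors = priors, means = mu,
                 var_names = colnames(X), predictions = pred,
                 accuracy = mean(pred == g)), class = "fda_fit")
}

#' @export
predict.fda_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$var_names %in% colnames(newdata)))
    newdata <- newdata[, object$var_names, drop = FALSE]
  if (ncol(newdata) != length(object$var_names))
    stop("newdata column count does not match the fit")
  scores <- newdata %*% object$coefficients +
    matrix(object$intercepts, nrow(newdata), length(object$levels),
           byrow = TRUE)
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.fda_fit <- function(x, ...) {
  cat(sprintf("linear discriminant fit: %d predictors, %d classes, training accuracy %.3f\n",
              length(x$var_names), length(x$levels), x$accuracy))
  invisible(x)
}

#' Within/between sum-of-squares ratio of a genotype vector
#'
#' `SS_within / SS_between` of the additive genotype codes across classes;
#' used as the tie-breaker in [forward_select()] (smaller = more
#' separable). Identical class means give an infinite sentinel.
#'
#' @param genotypes numeric vector of codes.
#' @param labels class vector.
#' @return the ratio (>= 0, possibly `Inf`).
#' @export
sums_of_squares_ratio <- function(genotypes, labels) {
  g <- factor(labels)
  if (nlevels(g) < 2) stop("need at least 2 classes")
  x <- as.numeric(genotypes)
  gm <- mean(x)
  mu <- tapply(x, g, mean)
  n_g <- tabulate(g)
  ss_between <- sum(n_g * (mu - gm)^2)
  ss_within <- sum((x - mu[as.integer(g)])^2)
  if (ss_between <= 0) return(Inf)
  ss_within / ss_between
}

#' Greedy forward selection of ancestry-predictive SNPs
#'
#' At each step, the candidate whose addition yields the largest increment
#' of training accuracy (under [fda_fit()]) joins the panel. Ties in
#' accuracy are broken by the minimum [sums_of_squares_ratio()], residual
#' ties lexicographically by SNP id. Selection stops when the training
#' accuracy reaches 1.0 or the best increment falls below `stop_delta`.
#' The baseline accuracy of the empty panel is the majority-class rate.
#'
#' @param X_candidates n x m matrix of candidate SNPs (column names = ids).
#' @param labels class vector.
#' @param stop_delta minimum accuracy increment to continue (default 0.001).
#' @return list with `panel` (ordered ids), `trace` (training accuracy after
#'   each addition; non-decreasing), and `baseline`.
#' @export
forward_select <- function(X_candidates, labels, stop_delta = 0.001) {
  X <- as.matrix(X_candidates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) == 0) stop("empty candidate set")
  g <- factor(labels)
  panel <- character(0)
  acc <- max(table(g)) / length(g)        # majority-class baseline
  baseline <- acc
  trace <- numeric(0)
  remaining <- colnames(X)
  while (length(remaining) > 0 && acc < 1) {
    cand_acc <- vapply(remaining, function(id)
      suppressWarnings(
        fda_fit(X[, c(panel, id), drop = FALSE], g)$accuracy),
      numeric(1))
    best_acc <- max(cand_acc)
    if (best_acc - acc < stop_delta) break
    best <- remaining[cand_acc >= best_acc - 1e-12]
    if (length(best) > 1) {
      ratios <- vapply(best, function(id)
        sums_of_squares_ratio(X[, id], g), numeric(1))
      best <- best[ratios <= min(ratios) + 1e-12]
      best <- sort(best)
    }
    chosen <- best[1]
    panel <- c(panel, chosen)
    remaining <- setdiff(remaining, chosen)
    acc <- best_acc
    trace <- c(trace, acc)
  }
  list(panel = panel, trace = trace, baseline = baseline)
}

# stratified fold assignment: within each class, seeded shuffle then deal
# round-robin; returns integer folds of length n
stratified_folds <- function(labels, k, seed) {
  g <- factor(labels)
  n <- length(g)
  if (any(table(g) < k))
    warning("a class has fewer samples than folds; fold sizes rebalanced")
  folds <- integer(n)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  offset <- 0L
  for (lev in levels(g)) {
    idx <- which(g == lev)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  folds
}

#' Nested cross-validated selection of an ancestry-predictive eQTL panel
#'
#' Outer stratified k-fold cross-validation; within each training portion a
#' panel is built by [forward_select()] and its discriminant model is
#' evaluated on the held-out fold. Of the k fold-models, the one with the
#' highest testing accuracy is returned (ties: smaller panel, then lower
#' fold index).
#'
#' @param X n x m candidate SNP matrix.
#' @param labels class vector.
#' @param k outer folds (default 10).
#' @param seed integer seed (fold assignment).
#' @param stop_delta passed to [forward_select()].
#' @return object of class `aim_panel`: the chosen `panel`, its refitted
#'   `model` ([fda_fit()] on that fold's training data), `fold_results`
#'   (per-fold panel size and training/testing accuracy), `chosen_fold`,
#'   and `test_accuracy`.
#' @export
nested_cv_classify <- function(X, labels, k = 10, seed = 1,
                               stop_delta = 0.001) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  g <- factor(labels)
  if (nrow(X) < k) stop("fewer samples than folds")
  folds <- stratified_folds(g, k, seed)
  fold_models <- vector("list", k)
  res <- data.frame(fold = seq_len(k), panel_size = NA_integer_,
                    train_accuracy = NA_real_, test_accuracy = NA_real_)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (nlevels(droplevels(g[tr])) < 2) stop("a class is absent from a fold")
    fs <- forward_select(X[tr, , drop = FALSE], g[tr],
                         stop_delta = stop_delta)
    if (length(fs$panel) == 0) {
      # empty panel: majority-class prediction
      maj <- names(which.max(table(g[tr])))
      pred <- factor(rep(maj, sum(te)), levels = levels(g))
      model <- NULL
      train_acc <- fs$baseline
    } else {
      model <- suppressWarnings(
        fda_fit(X[tr, fs$panel, drop = FALSE], g[tr]))
      pred <- predict(model, X[te, fs$panel, drop = FALSE])
      train_acc <- model$accuracy
    }
    fold_models[[f]] <- list(panel = fs$panel, model = model,
                             trace = fs$trace)
    res$panel_size[f] <- length(fs$panel)
    res$train_accuracy[f] <- train_acc
    res$test_accuracy[f] <- mean(pred == g[te])
  }
  best_acc <- max(res$test_accuracy)
  cand <- which(res$test_accuracy >= best_acc - 1e-12)
  cand <- cand[res$panel_size[cand] == min(res$panel_size[cand])]
  chosen <- min(cand)
  structure(list(panel = fold_models[[chosen]]$panel,
                 model = fold_models[[chosen]]$model,
                 trace = fold_models[[chosen]]$trace,
                 fold_results = res, chosen_fold = chosen,
                 test_accuracy = res$test_accuracy[chosen],
                 k = k, seed = seed), class = "aim_panel")
}

#' @export
print.aim_panel <- function(x, ...) {
  cat(sprintf("ancestry-predictive panel (%d-fold CV): %d SNP(s), testing accuracy %.4f (fold %d)\n",
              x$k, length(x$panel), x$test_accuracy, x$chosen_fold))
  if (length(x$panel)) cat("  ", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}

#' Candidate eQTL sets for classification from per-population scans
#'
#' Set algebra over per-population eQTL SNP lists mirroring the three
#' analyses: the union ("A or B"), the intersection ("A and B"), and the
#' symmetric difference of population-specific SNPs ("A-specific or
#' B-specific").
#'
#' @param snps_by_pop named list (two populations) of character vectors of
#'   eQTL SNP ids.
#' @param set `"union"`, `"intersection"` or `"specific"`.
#' @return character vector of candidate SNP ids, sorted.
#' @export
eqtl_candidate_set <- function(snps_by_pop,
                               set = c("union", "intersection",
                                       "specific")) {
  set <- match.arg(set)
  if (length(snps_by_pop) != 2) stop("need exactly 2 populations")
  a <- unique(snps_by_pop[[1]]); b <- unique(snps_by_pop[[2]])
  out <- switch(set,
                union = union(a, b),
                intersection = intersect(a, b),
                specific = union(setdiff(a, b), setdiff(b, a)))
  sort(out)
}
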