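# Seed hygiene: set a local seed and restore the caller's RNG state on exit,
# so library functions do not perturb the user's random stream.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# small deterministic polynomial string hash (31-bit) used to derive
# per-pair seeds and config hashes
str_hash <- function(x) {
  h <- 7
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Moore-Penrose pseudoinverse via SVD (for near-singular rank covariances)
pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
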