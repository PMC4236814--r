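#' Exact test of allelic homogeneity on a 2 x K table
#'
#' Freeman-Halton generalization of Fisher's exact test: conditioning on all
#' margins, the two-sided p-value is the sum of multivariate hypergeometric
#' probabilities of every table whose probability does not exceed the
#' observed table's (with a small relative tolerance guarding ties). All
#' probability arithmetic is in log space, so p-values far below double
#' underflow of individual terms (down to ~1e-23 and beyond) are computed
#' accurately.
#'
#' Enumeration walks the K-1 free cells of the first row (the column with
#' the largest margin is made the dependent one). When the table grid
#' exceeds `budget` tables, the method falls back to Monte Carlo sampling
#' from the conditional null (via [stats::r2dtable()]) with a warning.
#'
#' @param table 2 x K matrix of non-negative integer allele counts.
#' @param method `"auto"` (enumerate within budget), `"enumerate"` or
#'   `"monte_carlo"`.
#' @param mc_reps Monte Carlo replicates (default 1e5).
#' @param seed integer seed (Monte Carlo only).
#' @param budget maximum enumeration grid size for `"auto"`/`"enumerate"`.
#' @return the two-sided exact (or Monte Carlo) p-value.
#' @export
fisher_exact_2xk <- function(table, method = c("auto", "enumerate",
                                               "monte_carlo"),
                             mc_reps = 1e5, seed = 1, budget = 5e6) {
  method <- match.arg(method)
  tab <- as.matrix(table)
  if (nrow(tab) != 2 || ncol(tab) < 2)
    stop("need a 2 x K table with K >= 2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  cs <- colSums(tab); r1 <- sum(tab[1, ]); N <- sum(tab)
  if (r1 == 0 || r1 == N || any(cs == 0)) return(1)
  K <- ncol(tab)
  rel_tol <- 1e-12

  lp_table <- function(a) sum(lchoose(cs, a)) - lchoose(N, r1)
  lp_obs <- lp_table(tab[1, ])

  grid_size <- prod(sort(cs, decreasing = TRUE)[-1] + 1)
  if (method == "auto")
    method <- if (grid_size <= budget) "enumerate" else "monte_carlo"
  if (method == "enumerate" && grid_size > budget) {
    warning(sprintf(paste0("enumeration grid (%.3g tables) exceeds budget;",
                           " falling back to Monte Carlo"), grid_size))
    method <- "monte_carlo"
  }

  if (method == "enumerate") {
    dep <- which.max(cs)                  # largest margin as dependent cell
    free <- setdiff(seq_len(K), dep)
    g <- as.matrix(expand.grid(lapply(cs[free], function(m) 0:m),
                               KEEP.OUT.ATTRS = FALSE))
    last <- r1 - rowSums(g)
    ok <- last >= 0 & last <= cs[dep]
    g <- g[ok, , drop = FALSE]; last <- last[ok]
    lp <- -lchoose(N, r1) + lchoose(cs[dep], last)
    for (j in seq_along(free)) lp <- lp + lchoose(cs[free[j]], g[, j])
    # log-sum-exp over the tables at most as probable as the observed one
    sel <- lp <= lp_obs + rel_tol * abs(lp_obs) + 1e-12
    m <- max(lp[sel])
    min(1, exp(m) * sum(exp(lp[sel] - m)))
  } else {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old))
    draws <- stats::r2dtable(mc_reps, c(r1, N - r1), cs)
    lp <- vapply(draws, function(d) lp_table(d[1, ]), numeric(1))
    (1 + sum(lp <= lp_obs + rel_tol * abs(lp_obs) + 1e-12)) / (mc_reps + 1)
  }
}

# allele-count table (2 x K) for one SNP across populations, excluding
# missing genotypes; row 1 = B/ALT allele, row 2 = A/REF allele
allele_table <- function(geno_by_pop, snp_id) {
  cols <- lapply(geno_by_pop, function(g) {
    v <- g$values[, snp_id]
    v <- v[!is.na(v)]
    b <- sum(v)
    c(B = b, A = 2 * length(v) - b)
  })
  tab <- do.call(cbind, cols)
  colnames(tab) <- names(geno_by_pop)
  tab
}

#' Ancestry-informative eQTL detection
#'
#' For each SNP, builds the 2 x K allele-count table across populations
#' (missing genotypes excluded), runs the exact homogeneity test, adjusts
#' the p-values across the submitted set by Benjamini-Hochberg, and flags a
#' SNP as ancestry-informative when the adjusted p is below `fdr_alpha`.
#'
#' @param eqtl_snps character vector of SNP ids to test.
#' @param genotypes_by_pop named list of [genotype_matrix()] objects (K >= 2
#'   populations), each containing the SNPs.
#' @param fdr_alpha FDR threshold (default 0.05).
#' @param method,mc_reps,seed passed to [fisher_exact_2xk()].
#' @return data frame with columns `snp_id`, `p`, `adj_p`, `informative`,
#'   plus the table margins; SNPs monomorphic in all populations get p = 1.
#' @export
ancestry_informative_eqtl <- function(eqtl_snps, genotypes_by_pop,
                                      fdr_alpha = 0.05, method = "auto",
                                      mc_reps = 1e5, seed = 1) {
  if (length(genotypes_by_pop) < 2) stop("need >= 2 populations")
  eqtl_snps <- unique(eqtl_snps)
  p <- vapply(eqtl_snps, function(s) {
    tab <- allele_table(genotypes_by_pop, s)
    fisher_exact_2xk(tab, method = method, mc_reps = mc_reps,
                     seed = seed + str_hash(s) %% 1000L)
  }, numeric(1))
  adj <- bh_adjust(p)
  data.frame(snp_id = eqtl_snps, p = p, adj_p = adj,
             informative = adj < fdr_alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Rank-score multivariate test of expression differences across groups
#'
#' A multivariate Kruskal-Wallis-type statistic on component-wise mid-ranks:
#' `W = sum_g n_g (Rbar_g - Rbar)' V^-1 (Rbar_g - Rbar)` with `V` the rank
#' covariance across all samples (divisor n - 1). With a single response it
#' reduces exactly to the Kruskal-Wallis H statistic. The asymptotic
#' p-value uses a chi-square with `t * (K - 1)` degrees of freedom; the
#' permutation mode shuffles the group labels.
#'
#' @param T_gene_block n x t expression matrix (columns may be single
#'   probes or a whole T-gene block).
#' @param group_labels length-n vector of K >= 2 group labels, each group
#'   with >= 2 samples.
#' @param mode `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm label permutations (permutation mode).
#' @param seed integer seed.
#' @return list with `statistic`, `df`, `p_value`, `mode`.
#' @export
mnm_test <- function(T_gene_block, group_labels,
                     mode = c("asymptotic", "permutation"), n_perm = 999,
                     seed = 1) {
  mode <- match.arg(mode)
  Y <- as.matrix(T_gene_block)
  g <- factor(group_labels)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs >= 2 samples")
  n <- nrow(Y); t <- ncol(Y)
  R <- apply(Y, 2, rank)                 # mid-ranks, ties averaged
  if (t == 1) R <- matrix(R, ncol = 1)
  V <- stats::cov(R)
  Vi <- tryCatch(solve(V), error = function(e) {
    warning("singular rank covariance: using pseudo-inverse")
    pinv(V)
  })
  wstat <- function(gl) {
    rbar <- colMeans(R)
    sum(vapply(levels(gl), function(lev) {
      idx <- gl == lev
      d <- colMeans(R[idx, , drop = FALSE]) - rbar
      sum(idx) * drop(t(d) %*% Vi %*% d)
    }, numeric(1)))
  }
  W <- wstat(g)
  df <- t * (nlevels(g) - 1)
  if (mode == "asymptotic") {
    p <- stats::pchisq(W, df = df, lower.tail = FALSE)
  } else {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old))
    perm <- vapply(seq_len(n_perm), function(i)
      wstat(factor(sample(as.character(g)), levels = levels(g))),
      numeric(1))
    p <- (1 + sum(perm >= W - 1e-12)) / (n_perm + 1)
  }
  list(statistic = W, df = df, p_value = p, mode = mode)
}

#' Intersect ancestry-informative eQTL with a pharmacogenetic SNP list
#'
#' Inner join of the ancestry test results with an rsID-keyed
#' pharmacogenetic table (e.g. adverse-drug-reaction and drug-response SNP
#' lists). Pharma SNPs absent from the interrogated genotype panel are
#' reported separately.
#'
#' @param informative data frame from [ancestry_informative_eqtl()].
#' @param pharma_list data frame with columns `rsid`, `category` and
#'   optional `drugs` (duplicates deduplicated with a warning).
#' @param records optional eQTL record data frame ([genome_scan()] output);
#'   if given, the number of regulated T-genes per population is counted for
#'   each matched SNP.
#' @param panel_snps optional character vector of all interrogated SNP ids,
#'   used to fill the `not_interrogated` sidecar.
#' @return list with `matched` (data frame) and `not_interrogated`
#'   (character vector).
#' @export
intersect_pharma <- function(informative, pharma_list, records = NULL,
                             panel_snps = NULL) {
  ph <- pharma_list
  if (anyDuplicated(ph$rsid)) {
    warning("duplicate rsIDs in pharma list; deduplicated")
    ph <- ph[!duplicated(ph$rsid), , drop = FALSE]
  }
  if (is.null(ph$drugs)) ph$drugs <- NA_character_
  matched <- merge(informative, ph, by.x = "snp_id", by.y = "rsid")
  matched <- matched[order(matched$snp_id), , drop = FALSE]
  if (!is.null(records) && nrow(matched) > 0) {
    matched$t_genes_by_pop <- vapply(matched$snp_id, function(s) {
      hit <- records[vapply(strsplit(records$snp_ids, ","),
                            function(v) s %in% v, logical(1)), ,
                     drop = FALSE]
      if (nrow(hit) == 0) return("")
      cnt <- tapply(hit$t_gene, hit$population,
                    function(v) length(unique(v)))
      paste(sprintf("%s=%d", names(cnt), cnt), collapse = ";")
    }, character(1))
  }
  not_interrogated <- if (!is.null(panel_snps))
    setdiff(ph$rsid, panel_snps) else character(0)
  rownames(matched) <- NULL
  list(matched = matched, not_interrogated = sort(not_interrogated))
}
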