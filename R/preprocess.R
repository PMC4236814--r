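#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1, in the original
#' order. Thin validated wrapper around [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1))
    stop("p-values must be numeric in [0, 1] with no NA")
  stats::p.adjust(pvalues, method = "BH")
}

#' Permutation test of Hardy-Weinberg equilibrium
#'
#' The statistic is the absolute difference between the observed
#' heterozygote count and its expectation under HWE given the allele counts.
#' The null distribution is built by randomly re-pairing the 2N observed
#' alleles into N genotypes; p = (1 + #\{perm >= obs\}) / (n_perm + 1).
#'
#' @param genotypes vector of additive codes (0/1/2; `NA` dropped).
#' @param n_perm number of random re-pairings.
#' @param seed integer seed.
#' @return the permutation p-value. Monomorphic input returns 1 with a
#'   warning (no test possible).
#' @export
hwe_permutation_test <- function(genotypes, n_perm = 1000, seed = 1) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) < 2) stop("need at least 2 non-missing genotypes")
  n <- length(g)
  n_b <- sum(g)                       # count of B alleles
  n_a <- 2 * n - n_b
  if (n_a == 0 || n_b == 0) {
    warning("monomorphic SNP: HWE test not possible, returning p = 1")
    return(1)
  }
  obs_het <- sum(g == 1)
  exp_het <- 2 * n * (n_a / (2 * n)) * (n_b / (2 * n))
  stat_obs <- abs(obs_het - exp_het)
  alleles <- rep(c(0L, 1L), c(n_a, n_b))
  odd <- seq(1L, 2L * n, by = 2L)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  stat_perm <- vapply(seq_len(n_perm), function(i) {
    a <- sample(alleles)
    abs(sum(a[odd] != a[odd + 1L]) - exp_het)
  }, numeric(1))
  (1 + sum(stat_perm >= stat_obs - 1e-12)) / (n_perm + 1)
}

#' Sequential SNP quality control
#'
#' Removes SNPs in this order: non-autosomal, call rate below
#' `call_rate_min`, minor allele frequency (on non-missing calls) below
#' `maf_min`, HWE violations (permutation test p, BH-adjusted across the
#' SNPs surviving the MAF filter, below `hwe_alpha`), and finally inter-gene
#' SNPs (mapped to no gene).
#'
#' @param g a [genotype_matrix()] for one population.
#' @param map a `gene_map` from [build_gene_map()]; `NULL` skips the
#'   inter-gene step.
#' @param call_rate_min minimum genotype call rate (default 0.9).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_alpha threshold on the FDR-adjusted HWE p-value (default 0.001).
#' @param hwe_perms permutations per SNP for the HWE test (default 2000;
#'   note the permutation floor 1/(hwe_perms + 1) must lie below
#'   `hwe_alpha` for the step to be able to remove anything after FDR
#'   adjustment).
#' @param seed integer seed (HWE permutations).
#' @param autosomes character vector of autosome names.
#' @return list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report` (class `qc_report`: per-step removal counts and per-SNP call
#'   rate, MAF, HWE p and adjusted p).
#' @export
qc_snps <- function(g, map = NULL, call_rate_min = 0.9, maf_min = 0.01,
                    hwe_alpha = 0.001, hwe_perms = 2000, seed = 1,
                    autosomes = as.character(1:22)) {
  stopifnot(inherits(g, "genotype_matrix"))
  vals <- g$values
  n_in <- ncol(vals)
  status <- rep("retained", n_in)
  names(status) <- colnames(vals)

  auto_ok <- g$snp_meta$chrom %in% autosomes
  status[!auto_ok] <- "non_autosomal"

  call_rate <- colMeans(!is.na(vals))
  low_cr <- auto_ok & call_rate < call_rate_min
  status[low_cr] <- "low_call_rate"

  freq_b <- colMeans(vals, na.rm = TRUE) / 2
  maf <- pmin(freq_b, 1 - freq_b)
  maf[is.nan(maf)] <- 0
  low_maf <- auto_ok & !low_cr & maf < maf_min
  status[low_maf] <- "low_maf"

  surv_maf <- which(status == "retained")
  hwe_p <- rep(NA_real_, n_in)
  for (j in surv_maf) {
    hwe_p[j] <- suppressWarnings(
      hwe_permutation_test(vals[, j], n_perm = hwe_perms,
                           seed = seed + j))
  }
  hwe_adj <- rep(NA_real_, n_in)
  if (length(surv_maf))
    hwe_adj[surv_maf] <- bh_adjust(hwe_p[surv_maf])
  hwe_bad <- !is.na(hwe_adj) & hwe_adj < hwe_alpha
  status[hwe_bad] <- "hwe_violated"

  if (!is.null(map)) {
    inter <- status == "retained" &
      names(status) %in% map$intergenic_snps
    status[inter] <- "inter_gene"
  }

  keep <- status == "retained"
  if (!any(keep)) warning("no SNPs survive QC; returning empty matrix")
  out <- genotype_matrix(vals[, keep, drop = FALSE],
                         g$snp_meta[keep, , drop = FALSE])
  steps <- c("non_autosomal", "low_call_rate", "low_maf", "hwe_violated",
             "inter_gene")
  removed <- vapply(steps, function(s) sum(status == s), integer(1))
  report <- structure(list(
    n_input = n_in, removed = removed, n_retained = sum(keep),
    per_snp = data.frame(snp_id = colnames(vals), status = status,
                         call_rate = call_rate, maf = maf, hwe_p = hwe_p,
                         hwe_adj_p = hwe_adj, row.names = NULL,
                         stringsAsFactors = FALSE)),
    class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("SNP QC: %d in, %d retained\n", x$n_input, x$n_retained))
  for (s in names(x$removed))
    cat(sprintf("  removed %-15s %d\n", s, x$removed[[s]]))
  invisible(x)
}

# top-k id set by decreasing value; boundary ties are all included so the
# result does not depend on input order
top_k_ids <- function(v, k) {
  k <- min(k, length(v))
  rk <- rank(-v, ties.method = "min")
  names(v)[rk <= k]
}

#' Select transcript probes by cross-population variability
#'
#' Two probe lists are formed and combined: (A) the intersection over
#' populations of the `top_k` probes with the highest within-population
#' variability; (B) the union, over all population pairs, of the top
#' `rank_diff_frac` fraction of probes by absolute difference of
#' variability ranks. The union A | B is then restricted to probes from
#' `allowed_sources` and (optionally) to autosomes.
#'
#' @param expr_by_pop named list of [expression_matrix()] objects, one per
#'   population, sharing the same probe universe.
#' @param top_k probes taken per population in list A (capped at the probe
#'   count with a warning).
#' @param rank_diff_frac fraction of probes per pair in list B (default 0.01).
#' @param allowed_sources annotation sources to keep (default "RefSeq");
#'   `NULL` keeps all.
#' @param autosomes_only drop probes on non-autosomes or with unknown
#'   chromosome (default TRUE).
#' @param variability `"variance"` (default) or `"iqr"`.
#' @param autosomes autosome names.
#' @return list with `selected` (character vector of probe ids) and `report`
#'   (class `probe_selection`: the tallies of every step).
#' @export
select_probes <- function(expr_by_pop, top_k, rank_diff_frac = 0.01,
                          allowed_sources = "RefSeq", autosomes_only = TRUE,
                          variability = c("variance", "iqr"),
                          autosomes = as.character(1:22)) {
  variability <- match.arg(variability)
  if (length(expr_by_pop) < 2) stop("need at least 2 populations")
  probes <- colnames(expr_by_pop[[1]]$values)
  for (e in expr_by_pop)
    if (!identical(colnames(e$values), probes))
      stop("probe universe differs across populations")
  if (top_k > length(probes)) {
    warning("top_k exceeds probe count; capped")
    top_k <- length(probes)
  }
  vfun <- if (variability == "variance") {
    function(m) apply(m, 2, stats::var)
  } else {
    function(m) apply(m, 2, stats::IQR)
  }
  vars <- lapply(expr_by_pop, function(e) vfun(e$values))
  top_sets <- lapply(vars, top_k_ids, k = top_k)
  set_a <- Reduce(intersect, top_sets)

  ranks <- lapply(vars, function(v) rank(-v, ties.method = "average"))
  pops <- names(expr_by_pop)
  if (is.null(pops)) pops <- paste0("pop", seq_along(expr_by_pop))
  n_top <- max(1L, ceiling(rank_diff_frac * length(probes)))
  set_b <- character(0)
  pair_sizes <- integer(0)
  for (i in seq_along(ranks)) for (j in seq_along(ranks)) {
    if (i >= j) next
    d <- abs(ranks[[i]] - ranks[[j]])
    names(d) <- probes
    sel <- top_k_ids(d, n_top)
    set_b <- union(set_b, sel)
    pair_sizes <- c(pair_sizes,
                    stats::setNames(length(sel),
                                    paste(pops[i], pops[j], sep = "-")))
  }
  combined <- union(set_a, set_b)

  meta <- expr_by_pop[[1]]$probe_meta
  keep <- combined
  n_source_removed <- 0L
  if (!is.null(allowed_sources)) {
    src <- meta$source[match(keep, meta$probe_id)]
    ok <- !is.na(src) & src %in% allowed_sources
    n_source_removed <- sum(!ok)
    keep <- keep[ok]
  }
  n_autosome_removed <- 0L
  if (autosomes_only) {
    ch <- meta$chrom[match(keep, meta$probe_id)]
    ok <- !is.na(ch) & ch %in% autosomes
    n_autosome_removed <- sum(!ok)
    keep <- keep[ok]
  }
  keep <- sort(keep)
  report <- structure(list(
    n_probes = length(probes), top_k = top_k,
    set_a = sort(set_a), set_b = sort(set_b),
    n_a = length(set_a), n_b = length(set_b),
    n_union = length(combined), pair_sizes = pair_sizes,
    n_source_removed = n_source_removed,
    n_autosome_removed = n_autosome_removed,
    n_selected = length(keep), variability = variability),
    class = "probe_selection")
  list(selected = keep, report = report)
}

#' @export
print.probe_selection <- function(x, ...) {
  cat(sprintf(paste0(
    "probe selection: %d probes in; |A|=%d (top %d by %s), |B|=%d,",
    " union %d;\n  removed %d by source, %d non-autosomal -> %d selected\n"),
    x$n_probes, x$n_a, x$top_k, x$variability, x$n_b, x$n_union,
    x$n_source_removed, x$n_autosome_removed, x$n_selected))
  invisible(x)
}
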