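# Independent oracles and small fixture builders shared across tests.

# Exact conditional HWE p-value by full enumeration over heterozygote
# counts, for the same statistic as the permutation test (|het - E[het]|).
# P(h | allele counts) = n! 2^h / (nAA! h! naa!) * nA! na! / (2n)!
hwe_exact_p <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  n <- length(g); n_b <- sum(g); n_a <- 2 * n - n_b
  obs_het <- sum(g == 1)
  exp_het <- 2 * n * (n_a / (2 * n)) * (n_b / (2 * n))
  m <- min(n_a, n_b)
  hs <- seq(m %% 2, m, by = 2)              # parity fixed by allele counts
  logw <- vapply(hs, function(h) {
    lgamma(n + 1) + h * log(2) -
      lgamma((n_a - h) / 2 + 1) - lgamma(h + 1) - lgamma((n_b - h) / 2 + 1)
  }, numeric(1))
  w <- exp(logw - max(logw)); w <- w / sum(w)
  sum(w[abs(hs - exp_het) >= abs(obs_het - exp_het) - 1e-9])
}

# Brute-force Benjamini-Hochberg by its definition adj_(i) = min_{j>=i} p_(j) m / j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m); out[o] <- adj
  out
}

# Weir-Cockerham FST estimator (two alleles, r populations, ratio of sums)
wc_fst <- function(freq_list, n_list, het_list) {
  r <- length(freq_list)
  n_snp <- length(freq_list[[1]])
  num <- den <- 0
  for (j in seq_len(n_snp)) {
    n_i <- vapply(n_list, `[`, numeric(1), j)
    p_i <- vapply(freq_list, `[`, numeric(1), j)
    h_i <- vapply(het_list, `[`, numeric(1), j)
    nbar <- mean(n_i)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r -
                               hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    if (is.finite(a + b + cc)) { num <- num + a; den <- den + a + b + cc }
  }
  num / den
}

# exhaustive van der Voet p on m <= 20 cells: all 2^m sign assignments
vdv_exhaustive <- function(res_cand, res_ref) {
  d <- as.vector(as.matrix(res_cand)^2 - as.matrix(res_ref)^2)
  m <- length(d)
  stopifnot(m <= 20)
  obs <- sum(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
  mean(signs %*% d >= obs - 1e-12)
}

# genotype/expression toy blocks with a planted linear effect;
# beta acts on the standardized dose of the first SNP
make_pair <- function(n, s, t, beta = 0, sigma = 1, maf = 0.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * s, 2, maf), n, s,
              dimnames = list(sprintf("i%03d", 1:n), paste0("snp", 1:s)))
  while (sd(X[, 1]) == 0) X[, 1] <- rbinom(n, 2, maf)
  dose <- as.vector(scale(X[, 1]))
  Y <- matrix(beta * dose + rnorm(n * t, 0, sigma), n, t,
              dimnames = list(rownames(X), paste0("p", 1:t)))
  list(X = X, Y = Y)
}

# small on-disk dataset (6 genes x 3 SNPs, 3 expressed genes x 2 probes,
# two 12-sample populations, one planted cis pair) for pipeline tests
write_mini_dataset <- function(dir, seed = 1) {
  cfg <- sim_config(populations = c(P1 = 14, P2 = 14), n_genes = 6,
                    snps_per_gene = 3, probes_per_gene = 2,
                    n_expressed_genes = 3,
                    fst = c(neutral = 0.02, aim = 0.3), aim_fraction = 0.2,
                    effects = local({
                      e <- data.frame(s_gene = "gene001",
                                      t_gene = "gene001",
                                      stringsAsFactors = FALSE)
                      e$beta <- list(rep(1.5, 3))
                      e
                    }),
                    sigma = 1, missing_rate = 0.02, seed = seed)
  gs <- simulate_genotypes(cfg)
  es <- simulate_expression(gs, cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gall <- do.call(rbind, lapply(gs$genotypes, function(g) g$values))
  eall <- do.call(rbind, lapply(es$expression, function(e) e$values))
  f <- c(genotypes = file.path(dir, "genotypes.tsv"),
         expression = file.path(dir, "expression.tsv"),
         genes = file.path(dir, "genes.tsv"),
         snps = file.path(dir, "snps.tsv"),
         probes = file.path(dir, "probes.tsv"),
         populations = file.path(dir, "populations.tsv"),
         pharma = file.path(dir, "pharma.tsv"))
  write_matrix_tsv(gall, f["genotypes"])
  write_matrix_tsv(eall, f["expression"])
  wt <- function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(gs$annotation, f["genes"])
  wt(gs$genotypes[[1]]$snp_meta, f["snps"])
  wt(es$expression[[1]]$probe_meta, f["probes"])
  wt(data.frame(sample_id = rownames(gall),
                population = rep(names(cfg$populations), each = 14)),
     f["populations"])
  wt(data.frame(rsid = c("gene001_snp01", "rs9999999"),
                category = c("ADR", "FX"),
                drugs = c("drugA", "drugB")), f["pharma"])
  f
}
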