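test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))                     # hand computation
  expect_equal(bh_adjust(0.2), 0.2)              # m = 1
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p))
    expect_true(all(adj <= 1))
    # monotone in the sorted order
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("HWE permutation test matches the exact enumeration oracle", {
  # strong heterozygote excess: exact p astronomically small,
  # permutation p at its floor
  g_het <- rep(1, 50)
  p <- hwe_permutation_test(g_het, n_perm = 9999, seed = 4)
  expect_lt(p, 0.001)
  expect_lt(hwe_exact_p(g_het), 1e-10)

  # genotype counts at exact HWE proportions: statistic at the null mode
  g_hwe <- rep(c(0, 1, 2), c(25, 50, 25))
  expect_gte(hwe_permutation_test(g_hwe, n_perm = 999, seed = 1), 0.5)

  # agreement with enumeration within Monte Carlo error
  g_mid <- rep(c(0, 1, 2), c(10, 10, 10))
  p_perm <- hwe_permutation_test(g_mid, n_perm = 9999, seed = 2)
  expect_lt(abs(p_perm - hwe_exact_p(g_mid)), 0.02)

  expect_warning(p1 <- hwe_permutation_test(rep(0, 30)), "monomorphic")
  expect_equal(p1, 1)
})

test_that("HWE permutation p-values control type-I error under HWE", {
  set.seed(31)
  n_rep <- 1000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    p_freq <- runif(1, 0.2, 0.8)
    g <- rbinom(60, 2, p_freq)
    if (sum(g) %in% c(0, 120)) { rej[i] <- FALSE; next }
    rej[i] <- hwe_permutation_test(g, n_perm = 199, seed = i) <= 0.05
  }
  mc_se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(mean(rej), 0.05 + 2 * mc_se)
})

test_that("SNP QC removes markers in the documented order", {
  set.seed(5)
  n <- 45
  vals <- cbind(
    good   = rbinom(n, 2, 0.4),
    lowcr  = c(rbinom(n - 5, 2, 0.4), rep(NA, 5)),     # call rate 40/45
    rare   = rep(0, n),                                 # non-polymorphic
    hwebad = rep(1, n),                                 # all heterozygous
    nonaut = rbinom(n, 2, 0.4),
    interg = rbinom(n, 2, 0.4))
  vals[, "good"][1] <- 1                                # ensure polymorphic
  rownames(vals) <- sprintf("i%02d", 1:n)
  meta <- data.frame(
    snp_id = colnames(vals),
    chrom = c("1", "1", "1", "1", "X", "1"),
    pos = c(150L, 160L, 170L, 180L, 190L, 5000L))
  g <- genotype_matrix(vals, meta)
  ann <- data.frame(gene_id = "A", symbol = "A", chrom = "1",
                    start = 100, end = 200)
  map <- build_gene_map(ann, g)
  res <- qc_snps(g, map, hwe_perms = 4999, seed = 9)
  expect_equal(colnames(res$genotypes$values), "good")
  st <- res$report$per_snp
  expect_equal(st$status[st$snp_id == "nonaut"], "non_autosomal")
  expect_equal(st$status[st$snp_id == "lowcr"], "low_call_rate")
  expect_equal(st$status[st$snp_id == "rare"], "low_maf")
  expect_equal(st$status[st$snp_id == "hwebad"], "hwe_violated")
  expect_equal(st$status[st$snp_id == "interg"], "inter_gene")
  # documented example values
  expect_equal(st$call_rate[st$snp_id == "lowcr"], 40 / 45)
  expect_equal(st$maf[st$snp_id == "rare"], 0)
  # bookkeeping: removals + retained = input
  expect_equal(sum(res$report$removed) + res$report$n_retained,
               res$report$n_input)
  # reproducible with the same seed
  res2 <- qc_snps(g, map, hwe_perms = 4999, seed = 9)
  expect_identical(res$report$per_snp, res2$report$per_snp)

  # a 60-sample marker with 59 AA + 1 Aa: MAF 1/120 falls below 0.01
  v60 <- cbind(rare60 = c(rep(0, 59), 1), good = rbinom(60, 2, 0.4))
  rownames(v60) <- sprintf("j%02d", 1:60)
  g60 <- genotype_matrix(v60, data.frame(snp_id = colnames(v60),
                                         chrom = "1", pos = c(150L, 160L)))
  r60 <- qc_snps(g60, NULL, hwe_perms = 200, seed = 1)
  s60 <- r60$report$per_snp
  expect_equal(s60$maf[s60$snp_id == "rare60"], 1 / 120)
  expect_equal(s60$status[s60$snp_id == "rare60"], "low_maf")
})

test_that("probe selection combines variability and rank-difference lists", {
  # 10 probes, 2 populations; top-3 sets share exactly 2 probes
  probes <- paste0("p", 1:10)
  v1 <- c(10, 9, 8, 1, 2, 3, 4, 5, 6, 7)
  v2 <- c(10, 9, 1, 8, 2, 3, 4, 5, 6, 7)
  meta <- data.frame(probe_id = probes, gene_id = probes,
                     chrom = "1", source = "RefSeq")
  # deterministic columns with per-probe variance exactly v
  det <- function(v) {
    base <- scale(seq_len(8))[, 1]
    vals <- vapply(v, function(s) base * sqrt(s), numeric(8))
    dimnames(vals) <- list(paste0("i", 1:8), probes)
    vals
  }
  e1 <- expression_matrix(det(v1), meta)
  e2 <- expression_matrix(det(v2), meta)
  res <- select_probes(list(A = e1, B = e2), top_k = 3,
                       rank_diff_frac = 0.1)
  expect_setequal(res$report$set_a, c("p1", "p2"))     # |A| = 2
  expect_equal(res$report$n_a, 2L)
  # rank difference is largest for p3 and p4 (swap of ranks 3 and 8)
  expect_true(all(c("p3", "p4") %in% res$report$set_b))
  # invariant to population order
  res_rev <- select_probes(list(B = e2, A = e1), top_k = 3,
                           rank_diff_frac = 0.1)
  expect_setequal(res$selected, res_rev$selected)
  # |A u B| consistency
  expect_equal(res$report$n_union,
               length(union(res$report$set_a, res$report$set_b)))

  # source filter removes non-RefSeq probes from the final union
  meta2 <- e1$probe_meta; meta2$source[meta2$probe_id == "p1"] <- "Gnomon"
  e1g <- expression_matrix(e1$values, meta2)
  e2g <- expression_matrix(e2$values, meta2)
  resg <- select_probes(list(A = e1g, B = e2g), top_k = 3,
                        rank_diff_frac = 0.1)
  expect_false("p1" %in% resg$selected)
  expect_true("p1" %in% resg$report$set_a)

  # identical variances: every rank difference 0, A is the (tied) top set
  e3 <- expression_matrix(det(v1), e1$probe_meta)
  res_tie <- select_probes(list(A = e1, B = e3), top_k = 3,
                           rank_diff_frac = 0.1)
  expect_setequal(res_tie$report$set_a, c("p1", "p2", "p3"))

  expect_warning(select_probes(list(A = e1, B = e2), top_k = 99),
                 "capped")
})
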