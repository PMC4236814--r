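test_that("2x2 exact test equals hand hypergeometric sums", {
  # table (3,1 / 1,3): P(a) over a = 0..4 is (1,16,36,16,1)/70
  expect_equal(fisher_exact_2xk(rbind(c(3, 1), c(1, 3))), 34 / 70,
               tolerance = 1e-12)
  # proportional columns: the observed table is modal
  expect_equal(fisher_exact_2xk(rbind(c(5, 5), c(5, 5))), 1.0)
  # agreement with the network-algorithm implementation on random tables
  set.seed(14)
  for (i in 1:15) {
    tab <- matrix(rpois(6, 8) + 1, 2, 3)
    expect_equal(fisher_exact_2xk(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("enumeration probabilities are complete and Monte Carlo agrees", {
  set.seed(15)
  for (i in 1:5) {
    tab <- matrix(rpois(6, 10) + 1, 2, 3)
    p_en <- fisher_exact_2xk(tab, method = "enumerate")
    p_mc <- fisher_exact_2xk(tab, method = "monte_carlo", mc_reps = 20000,
                             seed = i)
    se <- sqrt(max(p_en * (1 - p_en), 1e-6) / 20000)
    expect_lt(abs(p_mc - p_en), 3 * se + 2e-4)
  }
  # the conditional probabilities over all tables sum to one
  tab <- rbind(c(6, 3, 2), c(2, 5, 7))
  cs <- colSums(tab); r1 <- sum(tab[1, ]); N <- sum(tab)
  g <- expand.grid(a = 0:cs[1], b = 0:cs[2])
  last <- r1 - g$a - g$b
  ok <- last >= 0 & last <= cs[3]
  lp <- lchoose(cs[1], g$a[ok]) + lchoose(cs[2], g$b[ok]) +
    lchoose(cs[3], last[ok]) - lchoose(N, r1)
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-9)
  # budget overrun falls back to Monte Carlo with a warning
  big <- rbind(c(300, 300, 300), c(300, 300, 300))
  expect_warning(fisher_exact_2xk(big, method = "enumerate", budget = 100),
                 "Monte Carlo")
})

test_that("ancestry flags follow the FDR rule and degenerate cases", {
  mkpop <- function(vals, ids) {
    genotype_matrix(matrix(vals, ncol = length(vals) / length(ids),
                           dimnames = list(ids, paste0("s", seq_len(
                             length(vals) / length(ids))))),
                    data.frame(snp_id = paste0("s", seq_len(
                      length(vals) / length(ids))), chrom = "1",
                      pos = seq_len(length(vals) / length(ids))))
  }
  ids1 <- sprintf("a%02d", 1:45); ids2 <- sprintf("b%02d", 1:45)
  # fixed opposite alleles: complete separation
  p1 <- mkpop(rep(0, 45), ids1); p2 <- mkpop(rep(2, 45), ids2)
  res <- ancestry_informative_eqtl("s1", list(A = p1, B = p2))
  expect_true(res$informative)
  expect_lt(res$adj_p, 1e-20)
  # identical allele counts: p = 1
  g <- c(rep(0, 20), rep(1, 15), rep(2, 10))
  q1 <- mkpop(g, ids1); q2 <- mkpop(g, ids2)
  res2 <- ancestry_informative_eqtl("s1", list(A = q1, B = q2))
  expect_equal(res2$p, 1)
  expect_false(res2$informative)
  # monomorphic everywhere: p = 1, non-informative
  m1 <- mkpop(rep(0, 45), ids1); m2 <- mkpop(rep(0, 45), ids2)
  res3 <- ancestry_informative_eqtl("s1", list(A = m1, B = m2))
  expect_equal(res3$p, 1)
  # lowering the FDR threshold never adds informative markers
  set.seed(16)
  vals1 <- rbinom(45 * 20, 2, 0.5); vals2 <- rbinom(45 * 20, 2, 0.7)
  r1 <- mkpop(vals1, ids1); r2 <- mkpop(vals2, ids2)
  snps <- paste0("s", 1:20)
  f05 <- ancestry_informative_eqtl(snps, list(A = r1, B = r2),
                                   fdr_alpha = 0.05)
  f01 <- ancestry_informative_eqtl(snps, list(A = r1, B = r2),
                                   fdr_alpha = 0.01)
  expect_true(all(f01$snp_id[f01$informative] %in%
                    f05$snp_id[f05$informative]))
})

test_that("rank-score test reduces to Kruskal-Wallis for one response", {
  res <- mnm_test(matrix(1:6, ncol = 1), rep(c("a", "b"), each = 3))
  H <- kruskal.test(1:6, rep(c("a", "b"), each = 3))$statistic
  expect_equal(res$statistic, unname(H), tolerance = 1e-9)
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-9)   # 3.857
  expect_equal(res$df, 1)
  # with ties, the mid-rank statistic still matches kruskal.test scaled
  # by its tie correction only through the covariance; check equality on
  # tie-free data across group counts
  set.seed(17)
  y <- rnorm(15)
  lab <- rep(c("a", "b", "c"), each = 5)
  expect_equal(mnm_test(matrix(y, ncol = 1), lab)$statistic,
               unname(kruskal.test(y, factor(lab))$statistic),
               tolerance = 1e-9)
})

test_that("rank-score test is invariant to monotone transforms and has power", {
  set.seed(18)
  Y <- matrix(rnorm(60 * 3), 60, 3)
  lab <- rep(c("a", "b"), each = 30)
  r0 <- mnm_test(Y, lab)
  Y2 <- Y; Y2[, 2] <- exp(Y2[, 2]); Y2[, 3] <- Y2[, 3]^3
  r2 <- mnm_test(Y2, lab)
  expect_equal(r0$statistic, r2$statistic, tolerance = 1e-10)
  # large mean shift in every probe: overwhelming evidence
  Ys <- matrix(rnorm(90 * 3), 90, 3)
  Ys[46:90, ] <- Ys[46:90, ] + 3
  rs <- mnm_test(Ys, rep(c("a", "b"), c(45, 45)))
  expect_lt(rs$p_value, 1e-6)
  # permutation mode agrees with the asymptotic p at moderate n
  rp <- mnm_test(Ys, rep(c("a", "b"), c(45, 45)), mode = "permutation",
                 n_perm = 499, seed = 2)
  expect_lt(rp$p_value, 0.01)
  expect_error(mnm_test(Y, rep("a", 60)), "2 groups")
})

test_that("pharma intersection joins by rsID and tracks missing panel SNPs", {
  inf <- data.frame(snp_id = c("rs1", "rs2"), p = c(1e-6, 1e-4),
                    adj_p = c(2e-6, 2e-4), informative = TRUE)
  ph <- data.frame(rsid = c("rs2", "rs2", "rs7"),
                   category = c("ADR", "ADR", "FX"),
                   drugs = c("d1", "d1", "d2"))
  rec <- data.frame(population = c("CHB", "JPT"), s_gene = "gA",
                    snp_ids = "rs2", t_gene = c("gB", "gC"),
                    probe_ids = "p", n_factors = 1L, cancor = 0.9,
                    explained_s = 0.4, explained_t = 0.4, class = "trans")
  expect_warning(
    out <- intersect_pharma(inf, ph, records = rec,
                            panel_snps = c("rs1", "rs2")),
    "duplicate")
  expect_equal(out$matched$snp_id, "rs2")
  expect_equal(out$matched$category, "ADR")
  expect_equal(out$matched$t_genes_by_pop, "CHB=1;JPT=1")
  expect_equal(out$not_interrogated, "rs7")
  # empty intersection is a clean empty table
  out2 <- intersect_pharma(inf[inf$snp_id == "rs1", , drop = FALSE],
                           unique(ph))
  expect_equal(nrow(out2$matched), 0L)
})
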