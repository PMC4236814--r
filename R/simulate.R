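#' Simulation configuration
#'
#' Describes a multi-population genotype/expression simulation with planted
#' eQTL structure. Population allele frequencies follow the Balding-Nichols
#' model: an ancestral frequency `p ~ Uniform(0.1, 0.9)` per SNP and, for
#' divergence `F > 0`, per-population frequencies
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`; with `F = 0` the populations
#' share `p`. Genotypes are drawn `Binomial(2, p_pop)` (Hardy-Weinberg
#' within population), then missing calls are inserted uniformly at random.
#'
#' @param populations named integer vector of sample sizes (each >= 2).
#' @param n_genes number of genes laid out along the autosomes.
#' @param snps_per_gene SNPs simulated within every gene.
#' @param probes_per_gene transcript probes per expressed gene.
#' @param n_expressed_genes how many of the first genes carry probes
#'   (default all).
#' @param fst Balding-Nichols divergence per SNP class, named vector with
#'   entries `neutral` and `aim` (each in \[0, 1)).
#' @param aim_fraction fraction of SNPs simulated at the `aim` divergence
#'   (default 0).
#' @param effects planted linear effects: data frame with columns `s_gene`,
#'   `t_gene`, `beta`; `beta` acts on the first SNP of the S-gene (use a
#'   list column of vectors for per-SNP effects).
#' @param mu baseline expression level (default 8).
#' @param sigma expression noise standard deviation (default 1).
#' @param missing_rate genotype missing-call rate (default 0).
#' @param freq_matrix optional SNPs x populations matrix of fixed allele
#'   frequencies overriding the Balding-Nichols draw.
#' @param noise `"gaussian"` (default) or `"t5"` (heavier-tailed, 5 df).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(populations = c(POP1 = 45, POP2 = 45),
                       n_genes = 10, snps_per_gene = 4, probes_per_gene = 3,
                       n_expressed_genes = n_genes,
                       fst = c(neutral = 0.01, aim = 0.2),
                       aim_fraction = 0, effects = NULL, mu = 8, sigma = 1,
                       missing_rate = 0, freq_matrix = NULL,
                       noise = c("gaussian", "t5"), seed = 1) {
  noise <- match.arg(noise)
  if (any(populations < 2)) stop("population sizes must be >= 2")
  if (is.null(names(populations)))
    names(populations) <- paste0("POP", seq_along(populations))
  if (any(fst < 0 | fst >= 1)) stop("F must lie in [0, 1)")
  if (sigma <= 0) stop("sigma must be positive")
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid missing_rate")
  if (!is.null(effects)) {
    gene_ids <- sprintf("gene%03d", seq_len(n_genes))
    bad <- setdiff(c(effects$s_gene, effects$t_gene), gene_ids)
    if (length(bad)) stop("effects reference unknown genes: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(populations = populations, n_genes = n_genes,
                 snps_per_gene = snps_per_gene,
                 probes_per_gene = probes_per_gene,
                 n_expressed_genes = n_expressed_genes, fst = fst,
                 aim_fraction = aim_fraction, effects = effects, mu = mu,
                 sigma = sigma, missing_rate = missing_rate,
                 freq_matrix = freq_matrix, noise = noise, seed = seed),
            class = "sim_config")
}

# deterministic gene layout: genes dealt across the 22 autosomes, SNPs
# spaced 100 bp inside the gene body
sim_gene_layout <- function(cfg) {
  g <- seq_len(cfg$n_genes)
  chrom <- as.character(((g - 1L) %% 22L) + 1L)
  slot <- (g - 1L) %/% 22L
  gene_len <- 100L * cfg$snps_per_gene + 100L
  start <- 10000L + slot * (gene_len + 10000L)
  data.frame(gene_id = sprintf("gene%03d", g),
             symbol = sprintf("GENE%03d", g), chrom = chrom,
             start = start, end = start + gene_len - 1L,
             stringsAsFactors = FALSE)
}

#' Simulate multi-population genotypes
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (named list of [genotype_matrix()], one per
#'   population), `annotation` (the gene table), and `truth` (per-SNP
#'   ancestral and per-population allele frequencies plus SNP class).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- set_local_seed(config$seed)
  on.exit(restore_seed(old))
  ann <- sim_gene_layout(config)
  n_snp <- config$n_genes * config$snps_per_gene
  snp_gene <- rep(ann$gene_id, each = config$snps_per_gene)
  within <- rep(seq_len(config$snps_per_gene), config$n_genes)
  snp_id <- sprintf("%s_snp%02d", snp_gene, within)
  meta <- data.frame(snp_id = snp_id,
                     chrom = rep(ann$chrom, each = config$snps_per_gene),
                     pos = rep(ann$start, each = config$snps_per_gene) +
                       100L * (within - 1L) + 50L,
                     alleleA = "A", alleleB = "B", stringsAsFactors = FALSE)
  pops <- names(config$populations)
  p_anc <- stats::runif(n_snp, 0.1, 0.9)
  is_aim <- stats::runif(n_snp) < config$aim_fraction
  fst <- ifelse(is_aim, config$fst[["aim"]], config$fst[["neutral"]])
  freq <- matrix(NA_real_, n_snp, length(pops),
                 dimnames = list(snp_id, pops))
  for (k in seq_along(pops)) {
    f <- fst
    freq[, k] <- ifelse(
      f > 0,
      stats::rbeta(n_snp, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f),
      p_anc)
  }
  if (!is.null(config$freq_matrix)) {
    fm <- config$freq_matrix
    freq[seq_len(nrow(fm)), ] <- fm
  }
  genos <- list()
  for (k in seq_along(pops)) {
    n <- config$populations[[k]]
    vals <- vapply(seq_len(n_snp), function(j)
      stats::rbinom(n, 2, freq[j, k]), numeric(n))
    if (n == 1) vals <- matrix(vals, nrow = 1)
    if (config$missing_rate > 0)
      vals[stats::runif(length(vals)) < config$missing_rate] <- NA
    rownames(vals) <- sprintf("%s_%03d", pops[k], seq_len(n))
    colnames(vals) <- snp_id
    genos[[pops[k]]] <- genotype_matrix(vals, meta)
  }
  truth <- data.frame(snp_id = snp_id, gene_id = snp_gene,
                      class = ifelse(is_aim, "aim", "neutral"),
                      p_ancestral = p_anc, stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(freq)[,
    , drop = FALSE])
  names(truth)[-(1:4)] <- paste0("freq_", pops)
  list(genotypes = genos, annotation = ann, truth = truth)
}

#' Simulate expression with planted cis/trans eQTL effects
#'
#' Each probe of an expressed gene is `mu + sum_j beta_j g_j + eps` where
#' the genotype terms come from the planted effects targeting that gene
#' (missing genotype codes enter via their column mean) and `eps` is i.i.d.
#' noise; probes of genes with no planted effect are baseline plus noise.
#'
#' @param genotypes the list returned by [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return list with `expression` (named list of [expression_matrix()]) and
#'   `truth` (the planted (S-gene, T-gene) pairs with cis flags).
#' @export
simulate_expression <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  old <- set_local_seed(config$seed + 104729L)
  on.exit(restore_seed(old))
  ann <- genotypes$annotation
  ng_expr <- min(config$n_expressed_genes, config$n_genes)
  t_genes <- ann$gene_id[seq_len(ng_expr)]
  probe_id <- as.vector(vapply(t_genes, function(g)
    sprintf("%s_p%d", g, seq_len(config$probes_per_gene)),
    character(config$probes_per_gene)))
  pmeta <- data.frame(probe_id = probe_id,
                      gene_id = rep(t_genes, each = config$probes_per_gene),
                      chrom = rep(ann$chrom[match(t_genes, ann$gene_id)],
                                  each = config$probes_per_gene),
                      source = "RefSeq", stringsAsFactors = FALSE)
  eff <- config$effects
  rnoise <- function(n) {
    if (config$noise == "gaussian") stats::rnorm(n, 0, config$sigma)
    else config$sigma * stats::rt(n, df = 5) / sqrt(5 / 3)
  }
  exprs <- list()
  for (pop in names(genotypes$genotypes)) {
    g <- genotypes$genotypes[[pop]]
    n <- nrow(g$values)
    vals <- matrix(config$mu + rnoise(n * length(probe_id)), n,
                   length(probe_id),
                   dimnames = list(rownames(g$values), probe_id))
    if (!is.null(eff)) for (i in seq_len(nrow(eff))) {
      snps <- g$snp_meta$snp_id[g$snp_meta$snp_id %in%
        sprintf("%s_snp%02d", eff$s_gene[i],
                seq_len(config$snps_per_gene))]
      beta <- eff$beta[[i]]
      use <- snps[seq_len(min(length(beta), length(snps)))]
      dose <- impute_missing(g$values[, use, drop = FALSE])
      signal <- drop(dose %*% beta[seq_along(use)])
      target <- pmeta$probe_id[pmeta$gene_id == eff$t_gene[i]]
      vals[, target] <- vals[, target] + signal
    }
    exprs[[pop]] <- expression_matrix(vals, pmeta)
  }
  truth <- if (is.null(eff)) {
    data.frame(s_gene = character(0), t_gene = character(0),
               cis = logical(0))
  } else {
    data.frame(s_gene = eff$s_gene, t_gene = eff$t_gene,
               cis = eff$s_gene == eff$t_gene, stringsAsFactors = FALSE)
  }
  list(expression = exprs, truth = truth)
}

#' Write a self-contained fixture dataset to disk
#'
#' Profiles: `tiny` is a compact worked-example shape — 45 samples
#' (split 23 + 22 into two subpopulations so every pipeline stage can run),
#' 43 S-genes x 28 SNPs (1,204 SNP columns) and 7 T-genes x 4 transcript
#' probes — with two planted cis effects and one trans effect.
#' `paper_like` emulates the four-population design (60, 60, 45, 45
#' samples) at a reduced gene count.
#'
#' Files written: `genotypes.tsv`, `expression.tsv`, `genes.tsv`,
#' `snps.tsv` (SNP positions), `probes.tsv`, `populations.tsv`,
#' `pharma.tsv`, `truth_effects.tsv`, `truth_snps.tsv`.
#'
#' @param profile `"tiny"` or `"paper_like"`.
#' @param dir output directory.
#' @param seed integer seed.
#' @param force overwrite an existing non-empty directory (default FALSE:
#'   refusal).
#' @return named character vector of the files written, invisibly.
#' @export
make_fixture_dataset <- function(profile = c("tiny", "paper_like"), dir,
                                 seed = 1, force = FALSE) {
  profile <- match.arg(profile)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("directory ", dir, " exists and is not empty; use force = TRUE")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- if (profile == "tiny") {
    sim_config(populations = c(POP1 = 23, POP2 = 22), n_genes = 43,
               snps_per_gene = 28, probes_per_gene = 4,
               n_expressed_genes = 7,
               fst = c(neutral = 0.02, aim = 0.3), aim_fraction = 0.1,
               effects = local({
                 e <- data.frame(
                   s_gene = c("gene001", "gene002", "gene010"),
                   t_gene = c("gene001", "gene002", "gene003"),
                   stringsAsFactors = FALSE)
                 # effect spread over the first 6 SNPs of the S-gene, as a
                 # regulatory block rather than a lone marker
                 e$beta <- rep(list(rep(1.2, 6)), 3)
                 e
               }),
               sigma = 1, missing_rate = 0.02, seed = seed)
  } else {
    sim_config(populations = c(YRI = 60, CEU = 60, CHB = 45, JPT = 45),
               n_genes = 30, snps_per_gene = 6, probes_per_gene = 3,
               n_expressed_genes = 15,
               fst = c(neutral = 0.02, aim = 0.15), aim_fraction = 0.2,
               effects = local({
                 e <- data.frame(
                   s_gene = c("gene001", "gene002", "gene005", "gene020"),
                   t_gene = c("gene001", "gene002", "gene005", "gene004"),
                   stringsAsFactors = FALSE)
                 e$beta <- rep(list(rep(1.2, 3)), 4)
                 e
               }),
               sigma = 1, missing_rate = 0.02, seed = seed)
  }
  gsim <- simulate_genotypes(cfg)
  esim <- simulate_expression(gsim, cfg)
  gall <- do.call(rbind, lapply(gsim$genotypes, function(g) g$values))
  eall <- do.call(rbind, lapply(esim$expression, function(e) e$values))
  pops <- data.frame(
    sample_id = rownames(gall),
    population = rep(names(cfg$populations),
                     vapply(gsim$genotypes, function(g) nrow(g$values),
                            integer(1))),
    stringsAsFactors = FALSE)
  # pharma list: two SNPs inside planted S-genes plus one absent from panel
  pharma <- data.frame(
    rsid = c(paste0(cfg$effects$s_gene[1], "_snp01"),
             paste0(cfg$effects$s_gene[2], "_snp01"), "rs0000001"),
    category = c("ADR", "FX", "both"),
    drugs = c("drugA", "drugB", "drugC"), stringsAsFactors = FALSE)
  files <- c(genotypes = file.path(dir, "genotypes.tsv"),
             expression = file.path(dir, "expression.tsv"),
             genes = file.path(dir, "genes.tsv"),
             snps = file.path(dir, "snps.tsv"),
             probes = file.path(dir, "probes.tsv"),
             populations = file.path(dir, "populations.tsv"),
             pharma = file.path(dir, "pharma.tsv"),
             truth_effects = file.path(dir, "truth_effects.tsv"),
             truth_snps = file.path(dir, "truth_snps.tsv"))
  write_matrix_tsv(gall, files["genotypes"])
  write_matrix_tsv(eall, files["expression"])
  wt <- function(x, f) utils::write.table(x, f, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(gsim$annotation, files["genes"])
  wt(gsim$genotypes[[1]]$snp_meta, files["snps"])
  wt(esim$expression[[1]]$probe_meta, files["probes"])
  wt(pops, files["populations"])
  wt(pharma, files["pharma"])
  wt(esim$truth, files["truth_effects"])
  wt(gsim$truth, files["truth_snps"])
  invisible(files)
}
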