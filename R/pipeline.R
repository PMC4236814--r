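#' Run configuration for the end-to-end pipeline
#'
#' Validates and assembles every input path and threshold of
#' [run_pipeline()]. Thresholds default to the standard workflow values:
#' call rate 0.9, MAF 0.01, HWE alpha 0.001, FDR 0.05, van der Voet alpha
#' 0.10, forward-selection stop 0.001, 7 CV folds for factor selection and
#' 10 for classification.
#'
#' @param genotypes,expression,annotation,probe_map,populations input file
#'   paths (TSV; see [read_matrix_tsv()], [read_gene_annotation()],
#'   [read_probe_map()]); `populations` maps `sample_id` to `population`.
#' @param snp_meta path of the SNP metadata TSV (`snp_id`, `chrom`, `pos`),
#'   required for gene assignment and the autosome filter.
#' @param pharma optional pharmacogenetic SNP list path.
#' @param out_dir output directory.
#' @param call_rate_min,maf_min,hwe_alpha,hwe_perms SNP QC settings.
#' @param top_k,rank_diff_frac probe-selection settings (`top_k = NULL`
#'   keeps all probes through list A).
#' @param fdr_alpha FDR threshold for the ancestry tests.
#' @param vdv_alpha van der Voet significance level.
#' @param n_randomizations van der Voet randomizations.
#' @param stop_delta forward-selection stopping increment.
#' @param k_folds_press,k_folds_classify fold counts.
#' @param scan_mode `"gene_based"` or `"snp_based"`.
#' @param pair_filter passed to [genome_scan()].
#' @param classify_set candidate set rule for the AIM step
#'   (`"union"`, `"intersection"`, `"specific"`).
#' @param seed master seed.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(genotypes, expression, annotation, probe_map,
                       populations, snp_meta, pharma = NULL,
                       out_dir = "geqtl_out",
                       call_rate_min = 0.9, maf_min = 0.01,
                       hwe_alpha = 0.001, hwe_perms = 2000, top_k = NULL,
                       rank_diff_frac = 0.01, fdr_alpha = 0.05,
                       vdv_alpha = 0.10, n_randomizations = 2000,
                       stop_delta = 0.001, k_folds_press = 7,
                       k_folds_classify = 10,
                       scan_mode = "gene_based", pair_filter = "all",
                       classify_set = "union", seed = 1) {
  chk01 <- function(x, nm) if (!is.numeric(x) || x < 0 || x > 1)
    stop(nm, " must lie in [0, 1]")
  chk01(call_rate_min, "call_rate_min"); chk01(maf_min, "maf_min")
  chk01(hwe_alpha, "hwe_alpha"); chk01(fdr_alpha, "fdr_alpha")
  chk01(vdv_alpha, "vdv_alpha"); chk01(rank_diff_frac, "rank_diff_frac")
  if (k_folds_press < 2 || k_folds_classify < 2) stop("need >= 2 folds")
  for (f in c(genotypes, expression, annotation, probe_map, populations,
              snp_meta, pharma))
    if (!file.exists(f)) stop("input file not found: ", f)
  structure(list(genotypes = genotypes, expression = expression,
                 annotation = annotation, probe_map = probe_map,
                 populations = populations, snp_meta = snp_meta,
                 pharma = pharma,
                 out_dir = out_dir, call_rate_min = call_rate_min,
                 maf_min = maf_min, hwe_alpha = hwe_alpha,
                 hwe_perms = hwe_perms, top_k = top_k,
                 rank_diff_frac = rank_diff_frac, fdr_alpha = fdr_alpha,
                 vdv_alpha = vdv_alpha,
                 n_randomizations = n_randomizations,
                 stop_delta = stop_delta, k_folds_press = k_folds_press,
                 k_folds_classify = k_folds_classify,
                 scan_mode = scan_mode, pair_filter = pair_filter,
                 classify_set = classify_set, seed = seed),
            class = "run_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of `key = value` (# comments allowed); keys are the arguments of
#' [run_config()]. Values are coerced to numeric where possible.
#'
#' @param path configuration file path.
#' @param ... overrides applied after the file is read.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- stats::setNames(
    lapply(kv, function(p) {
      v <- p[2]
      nv <- suppressWarnings(as.numeric(v))
      if (!is.na(nv)) nv else v
    }),
    vapply(kv, `[[`, character(1), 1))
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}

# hash of the analytic configuration; the output location is excluded so
# reruns into different directories compare equal
config_hash <- function(config) {
  config <- config[setdiff(names(config), "out_dir")]
  flat <- paste(names(config),
                vapply(config, function(v) paste(format(v), collapse = ","),
                       character(1)),
                sep = "=", collapse = ";")
  sprintf("%08x", str_hash(flat))
}

#' Run the full gene-based eQTL workflow
#'
#' Executes the six stages on one dataset: (1) per-population SNP QC;
#' (2) probe selection; (3) per-population eQTL scan; (4) ancestry tests on
#' the scanned eQTL (exact allelic homogeneity, FDR-flagged) plus
#' rank-score tests of the T-gene blocks; (5) pharmacogenetic intersection;
#' (6) ancestry-predictive panel selection for the closest population pair
#' (the two smallest populations when K > 2). Every stage writes its table
#' under `out_dir` and the run ends with a JSON manifest carrying the
#' config, its hash, seed and per-stage status.
#'
#' @param config a [run_config()] (or a path accepted by
#'   [read_run_config()]).
#' @return the manifest, invisibly (list).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("geqtl")),
                   seed = config$seed, config = unclass(config),
                   config_hash = config_hash(config), stages = list())
  stage <- function(name, expr) {
    out <- tryCatch(list(ok = TRUE, value = force(expr)),
                    error = function(e) list(ok = FALSE,
                                             error = conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      status = if (out$ok) "complete" else "failed",
      error = if (out$ok) NULL else out$error)
    if (!out$ok) stop("stage '", name, "' failed: ", out$error)
    out$value
  }
  wt <- function(x, f) utils::write.table(
    x, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)

  pops <- utils::read.delim(config$populations, stringsAsFactors = FALSE)
  ann <- read_gene_annotation(config$annotation)
  probe_map <- read_probe_map(config$probe_map)
  smeta <- utils::read.delim(config$snp_meta, stringsAsFactors = FALSE)
  gen_all0 <- read_matrix_tsv(config$genotypes, "genotype")
  gen_all <- genotype_matrix(
    gen_all0$values,
    smeta[match(colnames(gen_all0$values), smeta$snp_id), , drop = FALSE])
  expr_all0 <- read_matrix_tsv(config$expression, "expression")
  if (!all(rownames(gen_all$values) %in% pops$sample_id))
    stop("populations file does not cover all genotyped samples")
  pm <- probe_map[match(colnames(expr_all0$values), probe_map$probe_id), ]
  expr_all <- expression_matrix(expr_all0$values, pm)
  pop_of <- stats::setNames(pops$population, pops$sample_id)
  pop_levels <- sort(unique(pops$population))
  split_pop <- function(mat_obj) {
    lapply(stats::setNames(pop_levels, pop_levels), function(p) {
      ids <- rownames(mat_obj$values)[pop_of[rownames(mat_obj$values)] == p]
      if (inherits(mat_obj, "genotype_matrix"))
        genotype_matrix(mat_obj$values[ids, , drop = FALSE],
                        mat_obj$snp_meta)
      else expression_matrix(mat_obj$values[ids, , drop = FALSE],
                             mat_obj$probe_meta)
    })
  }
  gen_by_pop <- split_pop(gen_all)
  expr_by_pop <- split_pop(expr_all)
  map_full <- build_gene_map(ann, gen_all, expr_all)

  qc <- stage("snp_qc", {
    out <- lapply(pop_levels, function(p)
      qc_snps(gen_by_pop[[p]], map_full,
              call_rate_min = config$call_rate_min,
              maf_min = config$maf_min, hwe_alpha = config$hwe_alpha,
              hwe_perms = config$hwe_perms,
              seed = config$seed + str_hash(p) %% 1000L))
    names(out) <- pop_levels
    rep_all <- do.call(rbind, lapply(pop_levels, function(p)
      cbind(population = p, out[[p]]$report$per_snp)))
    wt(rep_all, "qc_report.tsv")
    out
  })

  probes_sel <- stage("probe_selection", {
    sel <- select_probes(expr_by_pop,
                         top_k = config$top_k %||%
                           ncol(expr_all$values),
                         rank_diff_frac = config$rank_diff_frac)
    wt(data.frame(probe_id = sel$selected), "probes_selected.tsv")
    sel
  })

  scans <- stage("eqtl_scan", {
    out <- lapply(pop_levels, function(p) {
      g <- qc[[p]]$genotypes
      keep <- intersect(probes_sel$selected, colnames(expr_all$values))
      e <- expr_by_pop[[p]]
      e <- expression_matrix(e$values[, keep, drop = FALSE],
                             e$probe_meta[match(keep, e$probe_meta$probe_id), ])
      map_p <- build_gene_map(ann, g, e)
      sc <- genome_scan(g, e, map_p, mode = config$scan_mode,
                        pair_filter = config$pair_filter,
                        config = eqtl_config(
                          k_folds = config$k_folds_press,
                          n_randomizations = config$n_randomizations,
                          alpha = config$vdv_alpha, seed = config$seed),
                        population = p)
      wt(sc$records, paste0("scan_", p, ".tsv"))
      sc
    })
    names(out) <- pop_levels
    records <- do.call(rbind, lapply(out, `[[`, "records"))
    write_eqtl_archive(records, file.path(config$out_dir, "archive"))
    out
  })
  records <- do.call(rbind, lapply(scans, `[[`, "records"))

  ancestry <- stage("ancestry_tests", {
    eqtl_snps <- sort(unique(unlist(strsplit(records$snp_ids, ","))))
    anc <- if (length(eqtl_snps) && length(pop_levels) >= 2) {
      ancestry_informative_eqtl(
        eqtl_snps, lapply(gen_by_pop, identity),
        fdr_alpha = config$fdr_alpha, seed = config$seed)
    } else {
      data.frame(snp_id = character(0), p = numeric(0),
                 adj_p = numeric(0), informative = logical(0))
    }
    wt(anc, "ancestry_tests.tsv")
    # rank-score test per T-gene block on the pooled samples
    t_genes <- sort(unique(expr_all$probe_meta$gene_id[
      expr_all$probe_meta$probe_id %in% probes_sel$selected]))
    mnm <- if (length(pop_levels) >= 2 && length(t_genes)) {
      p <- vapply(t_genes, function(tg) {
        pr <- expr_all$probe_meta$probe_id[
          expr_all$probe_meta$gene_id == tg &
            expr_all$probe_meta$probe_id %in% probes_sel$selected]
        mnm_test(expr_all$values[, pr, drop = FALSE],
                 pop_of[rownames(expr_all$values)])$p_value
      }, numeric(1))
      data.frame(t_gene = t_genes, p = p, adj_p = bh_adjust(p),
                 stringsAsFactors = FALSE)
    } else data.frame(t_gene = character(0), p = numeric(0),
                      adj_p = numeric(0))
    wt(mnm, "mnm_tests.tsv")
    list(eqtl = anc, transcripts = mnm)
  })

  stage("pharma_intersect", {
    if (is.null(config$pharma)) return(NULL)
    pharma <- read_pharma_list(config$pharma)
    res <- intersect_pharma(ancestry$eqtl, pharma, records = records,
                            panel_snps = colnames(gen_all$values))
    wt(res$matched, "pharma_intersect.tsv")
    wt(data.frame(rsid = res$not_interrogated),
       "pharma_not_interrogated.tsv")
    res
  })

  stage("aim_classification", {
    if (length(pop_levels) < 2) return(NULL)
    two <- names(sort(vapply(gen_by_pop, function(g) nrow(g$values),
                             integer(1))))[1:2]
    snps_by_pop <- lapply(stats::setNames(two, two), function(p) {
      r <- records[records$population == p, , drop = FALSE]
      unique(unlist(strsplit(r$snp_ids, ",")))
    })
    cand <- eqtl_candidate_set(snps_by_pop, set = config$classify_set)
    cand <- intersect(cand, colnames(gen_all$values))
    if (length(cand) == 0) return(NULL)
    ids <- pops$sample_id[pops$population %in% two]
    X <- impute_missing(gen_all$values[ids, cand, drop = FALSE])
    keep <- apply(X, 2, stats::sd) > 1e-12
    if (!any(keep)) return(NULL)
    panel <- nested_cv_classify(X[, keep, drop = FALSE], pop_of[ids],
                                k = config$k_folds_classify,
                                seed = config$seed,
                                stop_delta = config$stop_delta)
    jsonlite::write_json(
      list(populations = two, panel = panel$panel,
           test_accuracy = panel$test_accuracy,
           fold_results = panel$fold_results),
      file.path(config$out_dir, "aim_panel.json"),
      auto_unbox = TRUE, digits = NA)
    wt(panel$fold_results, "aim_accuracy.tsv")
    panel
  })

  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
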