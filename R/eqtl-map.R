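#' Scan configuration
#'
#' Collects the tunable settings of the eQTL scan.
#'
#' @param k_folds cross-validation folds (default 7).
#' @param fold_scheme fold assignment, `"interleaved"` or `"seeded_random"`.
#' @param n_randomizations van der Voet randomizations (default 2000).
#' @param alpha van der Voet significance level (default 0.10).
#' @param epsilon minimum explained-variation proportion for a call
#'   (default 1e-8).
#' @param max_factors cap on extracted factors (`NULL` = rank-based default).
#' @param seed base seed; each pair derives its own seed from it and the
#'   pair's ids, so results do not depend on scan order.
#' @return a list of class `eqtl_config`.
#' @export
eqtl_config <- function(k_folds = 7, fold_scheme = "interleaved",
                        n_randomizations = 2000, alpha = 0.10,
                        epsilon = 1e-8, max_factors = NULL, seed = 1) {
  stopifnot(k_folds >= 2, alpha > 0, alpha < 1, epsilon >= 0)
  structure(list(k_folds = k_folds, fold_scheme = fold_scheme,
                 n_randomizations = n_randomizations, alpha = alpha,
                 epsilon = epsilon, max_factors = max_factors, seed = seed),
            class = "eqtl_config")
}

pair_seed <- function(config, s_id, t_id) {
  (abs(config$seed) + str_hash(paste(s_id, t_id, sep = "|"))) %%
    2147483647L
}

empty_records <- function() {
  data.frame(population = character(0), s_gene = character(0),
             snp_ids = character(0), t_gene = character(0),
             probe_ids = character(0), n_factors = integer(0),
             cancor = numeric(0), explained_s = numeric(0),
             explained_t = numeric(0), class = character(0),
             stringsAsFactors = FALSE)
}

#' Test one S-gene/T-gene pair for a gene-based eQTL
#'
#' Selects the number of genetic factors by cross-validated PRESS and the
#' van der Voet test, refits on all samples at the selected count, and emits
#' a record if and only if the selected count is >= 1 and both blocks'
#' explained variation exceeds `config$epsilon`. The pair is cis if the two
#' gene ids are equal, trans otherwise.
#'
#' @param S_gene_block n x s genotype block (missing values are
#'   mean-imputed here).
#' @param T_gene_block n x t expression block.
#' @param s_gene,t_gene gene ids.
#' @param population population label carried into the record.
#' @param config an [eqtl_config()].
#' @return a one-row data frame (the eQTL record) or `NULL` when no eQTL is
#'   called. Degenerate (all-constant) blocks return `NULL` with a warning.
#' @export
call_pair <- function(S_gene_block, T_gene_block, s_gene, t_gene,
                      population = "pop", config = eqtl_config()) {
  X <- as.matrix(S_gene_block); Y <- as.matrix(T_gene_block)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  fully_missing <- apply(X, 2, function(v) all(is.na(v)))
  X <- X[, !fully_missing, drop = FALSE]
  if (ncol(X) == 0L) { warning("S-block fully missing"); return(NULL) }
  X <- impute_missing(X)
  if (all(apply(X, 2, stats::sd) < 1e-12)) {
    warning(sprintf("degenerate S-block for %s: all columns constant",
                    s_gene))
    return(NULL)
  }
  if (all(apply(Y, 2, stats::sd) < 1e-12)) {
    warning(sprintf("degenerate T-block for %s: all columns constant",
                    t_gene))
    return(NULL)
  }
  sd_seed <- pair_seed(config, s_gene, t_gene)
  curve <- suppressWarnings(
    cv_press(X, Y, max_factors = config$max_factors,
             k_folds = config$k_folds, fold_scheme = config$fold_scheme,
             seed = sd_seed, n_randomizations = config$n_randomizations,
             alpha = config$alpha))
  r_sel <- curve$selected
  if (r_sel < 1L) return(NULL)
  fit <- suppressWarnings(gbpls(X, Y, max_factors = r_sel))
  r_sel <- min(r_sel, fit$n_factors)
  if (r_sel < 1L) return(NULL)
  es <- sum(fit$explained_s[seq_len(r_sel)])
  et <- sum(fit$explained_t[seq_len(r_sel)])
  if (min(es, et) <= config$epsilon) return(NULL)
  data.frame(population = population, s_gene = s_gene,
             snp_ids = paste(fit$x_names, collapse = ","),
             t_gene = t_gene,
             probe_ids = paste(colnames(Y), collapse = ","),
             n_factors = r_sel, cancor = fit$cancor[1],
             explained_s = es, explained_t = et,
             class = if (identical(s_gene, t_gene)) "cis" else "trans",
             stringsAsFactors = FALSE)
}

#' Test a single SNP against a T-gene block (SNP-based eQTL)
#'
#' The SNP-based scan is the `s = 1` special case of [call_pair()]. The
#' record is cis when the T-gene is among the genes containing the SNP.
#'
#' @param snp_column length-n genotype vector (or n x 1 matrix).
#' @param T_gene_block n x t expression block.
#' @param snp_id SNP id.
#' @param snp_genes gene ids containing the SNP (for the cis call).
#' @param t_gene T-gene id.
#' @param population population label.
#' @param config an [eqtl_config()].
#' @return a one-row record data frame or `NULL`.
#' @export
call_seqtl <- function(snp_column, T_gene_block, snp_id, snp_genes,
                       t_gene, population = "pop", config = eqtl_config()) {
  X <- matrix(as.numeric(unlist(snp_column)), ncol = 1,
              dimnames = list(rownames(as.matrix(T_gene_block)), snp_id))
  s_gene <- if (t_gene %in% snp_genes) t_gene else
    (snp_genes[1] %||% NA_character_)
  if (length(snp_genes) == 0 || all(is.na(snp_genes)))
    s_gene <- snp_id
  rec <- call_pair(X, T_gene_block, s_gene = s_gene, t_gene = t_gene,
                   population = population, config = config)
  if (is.null(rec)) return(NULL)
  rec$snp_ids <- snp_id
  rec$class <- if (t_gene %in% snp_genes) "cis" else "trans"
  rec
}

#' Genome scan over S-gene x T-gene (or SNP x T-gene) pairs
#'
#' Iterates [call_pair()] (`mode = "gene_based"`) or [call_seqtl()]
#' (`mode = "snp_based"`) over the pairs admitted by `pair_filter`, in
#' deterministic (S id, T id) order. At genome scale an explicit filter is
#' required: an unfiltered all-pairs scan is refused above `max_pairs`
#' pairs.
#'
#' @param genotypes a [genotype_matrix()] (one population).
#' @param expression an [expression_matrix()] of the same samples.
#' @param map a `gene_map` from [build_gene_map()].
#' @param mode `"gene_based"` or `"snp_based"`.
#' @param pair_filter `"all"`, `"cis_only"`, a character vector of
#'   chromosome names (restricts S-side genes/SNPs to those chromosomes),
#'   or a data frame with columns `s_id`, `t_id` of explicit pairs.
#' @param config an [eqtl_config()].
#' @param population population label for the records.
#' @param checkpoint optional path of a checkpoint TSV; completed pairs are
#'   appended as the scan runs, and a rerun with the same path skips them
#'   and reuses their records.
#' @param max_pairs guardrail for unfiltered scans (default 10000).
#' @return list with `records` (data frame, possibly empty), `n_pairs`
#'   attempted, and `press_log` (per-pair selected counts and minimum root
#'   mean PRESS).
#' @export
genome_scan <- function(genotypes, expression, map,
                        mode = c("gene_based", "snp_based"),
                        pair_filter = "all", config = eqtl_config(),
                        population = "pop", checkpoint = NULL,
                        max_pairs = 10000) {
  mode <- match.arg(mode)
  gs <- rownames(genotypes$values); es <- rownames(expression$values)
  if (!identical(sort(gs), sort(es)))
    stop("sample sets differ between genotypes and expression: ",
         paste(union(setdiff(gs, es), setdiff(es, gs)), collapse = ", "))
  expr_vals <- expression$values[gs, , drop = FALSE]

  # T-gene blocks: probes grouped by mapped target gene
  p2g <- map$probe_to_gene[names(map$probe_to_gene) %in%
                             colnames(expr_vals)]
  t_blocks <- split(names(p2g), p2g)
  # S-side units
  if (mode == "gene_based") {
    g2s <- list()
    for (snp in names(map$snp_to_genes))
      for (gene in map$snp_to_genes[[snp]])
        g2s[[gene]] <- c(g2s[[gene]], snp)
    g2s <- lapply(g2s, function(v) v[v %in% colnames(genotypes$values)])
    g2s <- g2s[lengths(g2s) > 0]
    s_units <- data.frame(s_id = names(g2s), stringsAsFactors = FALSE)
  } else {
    snps <- intersect(names(map$snp_to_genes), colnames(genotypes$values))
    s_units <- data.frame(s_id = snps, stringsAsFactors = FALSE)
  }

  pairs <- expand.grid(s_id = s_units$s_id, t_id = names(t_blocks),
                       stringsAsFactors = FALSE)
  if (is.data.frame(pair_filter)) {
    if (!all(c("s_id", "t_id") %in% names(pair_filter)))
      stop("explicit pair list needs columns s_id, t_id")
    pairs <- merge(pairs, pair_filter[, c("s_id", "t_id")])
  } else if (identical(pair_filter, "cis_only")) {
    if (mode == "gene_based") {
      pairs <- pairs[pairs$s_id == pairs$t_id, , drop = FALSE]
    } else {
      keep <- vapply(seq_len(nrow(pairs)), function(i)
        pairs$t_id[i] %in% map$snp_to_genes[[pairs$s_id[i]]], logical(1))
      pairs <- pairs[keep, , drop = FALSE]
    }
  } else if (!identical(pair_filter, "all")) {
    chroms <- norm_chrom(pair_filter)
    if (mode == "gene_based") {
      on_chr <- map$genes$gene_id[map$genes$chrom %in% chroms]
      pairs <- pairs[pairs$s_id %in% on_chr, , drop = FALSE]
    } else {
      sm <- genotypes$snp_meta
      on_chr <- sm$snp_id[sm$chrom %in% chroms]
      pairs <- pairs[pairs$s_id %in% on_chr, , drop = FALSE]
    }
  } else if (nrow(pairs) > max_pairs) {
    stop(sprintf(paste0("unfiltered scan of %d pairs exceeds max_pairs=%d;",
                        " supply a pair_filter"), nrow(pairs), max_pairs))
  }
  pairs <- pairs[order(pairs$s_id, pairs$t_id), , drop = FALSE]

  done <- character(0); cached <- empty_records()
  if (!is.null(checkpoint) && file.exists(checkpoint) &&
      length(readLines(checkpoint)) > 1) {
    ck <- utils::read.delim(checkpoint, stringsAsFactors = FALSE)
    done <- paste(ck$s_id, ck$t_id, sep = "|")
    cached <- ck[ck$called == 1,
                 intersect(names(ck), names(empty_records())),
                 drop = FALSE]
  } else if (!is.null(checkpoint)) {
    utils::write.table(
      data.frame(s_id = character(0), t_id = character(0),
                 called = integer(0), population = character(0),
                 s_gene = character(0), snp_ids = character(0),
                 t_gene = character(0), probe_ids = character(0),
                 n_factors = integer(0), cancor = numeric(0),
                 explained_s = numeric(0), explained_t = numeric(0),
                 class = character(0)),
      checkpoint, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  rec_list <- list(); log_list <- list()
  for (i in seq_len(nrow(pairs))) {
    s_id <- pairs$s_id[i]; t_id <- pairs$t_id[i]
    if (paste(s_id, t_id, sep = "|") %in% done) next
    Y <- expr_vals[, t_blocks[[t_id]], drop = FALSE]
    rec <- if (mode == "gene_based") {
      Xb <- genotypes$values[gs, g2s[[s_id]], drop = FALSE]
      suppressWarnings(call_pair(Xb, Y, s_gene = s_id, t_gene = t_id,
                                 population = population, config = config))
    } else {
      suppressWarnings(call_seqtl(
        genotypes$values[gs, s_id, drop = FALSE], Y, snp_id = s_id,
        snp_genes = map$snp_to_genes[[s_id]], t_gene = t_id,
        population = population, config = config))
    }
    log_list[[i]] <- data.frame(s_id = s_id, t_id = t_id,
                                called = as.integer(!is.null(rec)),
                                stringsAsFactors = FALSE)
    if (!is.null(rec)) rec_list[[length(rec_list) + 1L]] <- rec
    if (!is.null(checkpoint)) {
      row <- cbind(log_list[[i]],
                   if (is.null(rec)) empty_records()[NA_integer_, ] else rec)
      suppressWarnings(utils::write.table(
        row, checkpoint, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE, append = TRUE))
    }
  }
  records <- rbind(cached,
                   if (length(rec_list)) do.call(rbind, rec_list)
                   else empty_records())
  records <- records[order(records$s_gene, records$t_gene), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, n_pairs = nrow(pairs),
       press_log = if (length(log_list)) do.call(rbind, log_list)
       else data.frame(s_id = character(0), t_id = character(0),
                       called = integer(0)))
}
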