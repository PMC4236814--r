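#' Read genotypes from a VCF file
#'
#' Converts biallelic records with GT fields to additive ALT-allele counts
#' (0/1/2); missing calls become `NA`. Multi-allelic records and records
#' without a GT field are skipped with a warning.
#'
#' @param path path to a VCF (v4.x) file.
#' @return a [genotype_matrix()]; the number of skipped records is attached
#'   as attribute `n_skipped`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no variant records in ", path)
  has_gt <- "GT" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID ||
    any(grepl("GT", v@gt[, 1]))
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  gt_ok <- grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"])
  keep <- !multi & gt_ok
  n_skip <- sum(!keep)
  if (n_skip > 0)
    warning(sprintf("skipped %d record(s): multi-allelic or no GT field",
                    n_skip))
  if (!any(keep)) stop("no usable biallelic GT records in ", path)
  gt <- vcfR::extract.gt(v[keep, ], element = "GT")
  # gt: variants x samples, entries like "0/0", "0|1", ".", "./."
  alt_count <- function(x) {
    al <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    vapply(al, function(a) {
      if (length(a) == 0 || any(a == "." ) || any(is.na(a))) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
  }
  vals <- apply(gt, 2, alt_count)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(NULL, colnames(gt)))
  vals <- t(vals)  # samples x SNPs
  fixk <- fix[keep, , drop = FALSE]
  ids <- ifelse(is.na(fixk$ID) | fixk$ID == ".",
                paste0(fixk$CHROM, ":", fixk$POS), fixk$ID)
  colnames(vals) <- ids
  meta <- data.frame(snp_id = ids, chrom = norm_chrom(fixk$CHROM),
                     pos = as.integer(fixk$POS),
                     alleleA = fixk$REF, alleleB = fixk$ALT,
                     stringsAsFactors = FALSE)
  out <- genotype_matrix(vals, meta)
  attr(out, "n_skipped") <- n_skip
  out
}

#' Read a sample-by-marker TSV matrix
#'
#' Expects a header row of marker ids, a first column of sample ids, and one
#' row per sample; missing values are written as "NA". Genotype matrices are
#' validated to codes \{0, 1, 2, NA\}.
#'
#' @param path path to a tab-delimited file.
#' @param kind `"genotype"` or `"expression"`.
#' @param meta optional SNP/probe metadata data frame passed to the container.
#' @return a [genotype_matrix()] or [expression_matrix()].
#' @export
read_matrix_tsv <- function(path, kind = c("genotype", "expression"),
                            meta = NULL) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_h <- length(parts[[1]])
  width <- lengths(parts[-1])
  if (any(width != ncol_h)) {
    bad <- which(width != ncol_h)[1] + 1L
    stop(sprintf("ragged row at line %d of %s (%d fields, expected %d)",
                 bad, path, width[bad - 1L], ncol_h))
  }
  header <- parts[[1]][-1]
  samples <- vapply(parts[-1], `[[`, character(1), 1)
  cells <- t(vapply(parts[-1], function(p) p[-1], character(ncol_h - 1L)))
  if (ncol_h == 2L) cells <- matrix(cells, ncol = 1L)
  suppressWarnings(num <- matrix(as.numeric(ifelse(cells == "NA", NA, cells)),
                                 nrow = nrow(cells)))
  bad <- is.na(num) & cells != "NA"
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                 cells[idx[1], idx[2]], samples[idx[1]], header[idx[2]], path))
  }
  dimnames(num) <- list(samples, header)
  if (kind == "genotype") {
    out_of_range <- !is.na(num) & !(num %in% c(0, 1, 2))
    if (any(out_of_range)) {
      idx <- which(out_of_range, arr.ind = TRUE)[1, ]
      stop(sprintf("invalid genotype code '%s' at row '%s', column '%s'",
                   format(num[idx[1], idx[2]]), samples[idx[1]],
                   header[idx[2]]))
    }
    genotype_matrix(num, meta)
  } else {
    expression_matrix(num, meta)
  }
}

#' Write a sample-by-marker matrix as TSV
#'
#' Inverse of [read_matrix_tsv()]: header of marker ids, first column
#' `sample_id`, missing values as "NA".
#'
#' @param x a [genotype_matrix()], [expression_matrix()] or plain matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  vals <- if (is.matrix(x)) x else x$values
  df <- data.frame(sample_id = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation TSV
#'
#' Columns: `gene_id`, `symbol`, `chrom`, `start`, `end` (1-based inclusive).
#' @param path path to the annotation file.
#' @return data frame of gene records.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns gene_id, chrom, start, end")
  if (is.null(ann$symbol)) ann$symbol <- ann$gene_id
  if (any(ann$start > ann$end)) stop("gene start > end in annotation")
  ann$chrom <- norm_chrom(ann$chrom)
  ann
}

#' Read a probe-to-gene map TSV
#'
#' Columns: `probe_id`, `gene_id`, optional `chrom` and `source`.
#' @param path path to the probe map file.
#' @return data frame of probe records (one row per probe; duplicate probe
#'   ids are reduced to their first listed gene with a warning).
#' @export
read_probe_map <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(pm)))
    stop("probe map must have columns probe_id, gene_id")
  if (anyDuplicated(pm$probe_id)) {
    warning("probe map lists some probes more than once; keeping the first ",
            "target gene per probe")
    pm <- pm[!duplicated(pm$probe_id), , drop = FALSE]
  }
  if (is.null(pm$chrom)) pm$chrom <- NA_character_
  if (is.null(pm$source)) pm$source <- NA_character_
  pm$chrom <- norm_chrom(pm$chrom)
  pm
}

#' Read a pharmacogenetic SNP list
#'
#' Columns: `rsid`, `category` (ADR, FX or both), optional `drugs` free text.
#' @param path path to the TSV.
#' @return data frame; duplicate rsids deduplicated with a warning.
#' @export
read_pharma_list <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("rsid", "category") %in% names(ph)))
    stop("pharma list must have columns rsid, category")
  if (is.null(ph$drugs)) ph$drugs <- NA_character_
  if (anyDuplicated(ph$rsid)) {
    warning("duplicate rsIDs in pharma list; deduplicated")
    ph <- ph[!duplicated(ph$rsid), , drop = FALSE]
  }
  ph
}

#' Build the gene map linking SNPs and probes to genes
#'
#' A SNP is assigned to every gene whose interval (optionally widened by
#' `window` bp on each side) contains its position on the same chromosome;
#' a SNP overlapping several genes is assigned to all of them. SNPs mapping
#' to no gene are flagged inter-gene. Probes are mapped by their annotated
#' target gene; probes citing an unknown gene id are flagged unmapped.
#'
#' @param annotation gene table (`gene_id`, `symbol`, `chrom`, `start`,
#'   `end`), e.g. from [read_gene_annotation()].
#' @param genotypes a [genotype_matrix()] (or `NULL` to skip SNP mapping).
#' @param expression an [expression_matrix()] whose `probe_meta$gene_id`
#'   defines the probe targets (or `NULL`).
#' @param window flanking window in bp added to both gene ends (default 0,
#'   i.e. strict overlap).
#' @return an object of class `gene_map`: list with `genes`, `snp_to_genes`
#'   (named list of gene-id vectors), `intergenic_snps`, `probe_to_gene`
#'   (named character vector) and `unmapped_probes`.
#' @export
build_gene_map <- function(annotation, genotypes = NULL, expression = NULL,
                           window = 0) {
  ann <- annotation
  if (any(ann$start > ann$end)) stop("gene start > end in annotation")
  ann$chrom <- norm_chrom(ann$chrom)
  snp_to_genes <- list(); intergenic <- character(0)
  if (!is.null(genotypes)) {
    sm <- genotypes$snp_meta
    snp_to_genes <- lapply(seq_len(nrow(sm)), function(i) {
      hit <- ann$chrom == sm$chrom[i] &
        ann$start - window <= sm$pos[i] & sm$pos[i] <= ann$end + window
      hit[is.na(hit)] <- FALSE
      ann$gene_id[hit]
    })
    names(snp_to_genes) <- sm$snp_id
    intergenic <- sm$snp_id[lengths(snp_to_genes) == 0L]
  }
  probe_to_gene <- character(0); unmapped <- character(0)
  if (!is.null(expression)) {
    pm <- expression$probe_meta
    probe_to_gene <- stats::setNames(as.character(pm$gene_id), pm$probe_id)
    known <- probe_to_gene %in% ann$gene_id
    unmapped <- names(probe_to_gene)[!known]
    probe_to_gene <- probe_to_gene[known]
  }
  structure(list(genes = ann, snp_to_genes = snp_to_genes,
                 intergenic_snps = intergenic,
                 probe_to_gene = probe_to_gene,
                 unmapped_probes = unmapped),
            class = "gene_map")
}

#' @export
print.gene_map <- function(x, ...) {
  cat(sprintf("gene_map: %d genes, %d SNPs (%d inter-gene), %d probes (%d unmapped)\n",
              nrow(x$genes), length(x$snp_to_genes),
              length(x$intergenic_snps), length(x$probe_to_gene),
              length(x$unmapped_probes)))
  invisible(x)
}

#' Write eQTL scan results as the three-table archive
#'
#' Writes, per population, a T-gene-oriented table (cis flag plus the
#' comma-separated trans regulator list), the symmetric S-gene-oriented
#' table, and a per-SNP table. Availability and cis flags use "1"/"NA".
#'
#' @param records data frame of eQTL records as produced by [genome_scan()].
#' @param dir output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
write_eqtl_archive <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cols <- c("population", "s_gene", "t_gene", "snp_ids", "class")
  if (nrow(records) > 0 && !all(cols %in% names(records)))
    stop("records must carry columns ", paste(cols, collapse = ", "))
  pops <- if (nrow(records)) sort(unique(records$population)) else "all"
  files <- character(0)
  for (pop in pops) {
    r <- records[records$population == pop, , drop = FALSE]
    joinlist <- function(v) paste(sort(unique(v)), collapse = ",")
    tg <- sort(unique(r$t_gene))
    tgt <- data.frame(
      t_gene = tg, available = rep("1", length(tg)),
      cis = vapply(tg, function(g)
        if (any(r$t_gene == g & r$class == "cis")) "1" else "NA",
        character(1)),
      trans_s_genes = vapply(tg, function(g)
        joinlist(r$s_gene[r$t_gene == g & r$class == "trans"]), character(1)),
      stringsAsFactors = FALSE)
    sg <- sort(unique(r$s_gene))
    sgt <- data.frame(
      s_gene = sg, available = rep("1", length(sg)),
      snp_ids = vapply(sg, function(g)
        joinlist(unlist(strsplit(r$snp_ids[r$s_gene == g], ","))),
        character(1)),
      cis = vapply(sg, function(g)
        if (any(r$s_gene == g & r$class == "cis")) "1" else "NA",
        character(1)),
      trans_t_genes = vapply(sg, function(g)
        joinlist(r$t_gene[r$s_gene == g & r$class == "trans"]), character(1)),
      stringsAsFactors = FALSE)
    snp_rows <- do.call(rbind, lapply(seq_len(nrow(r)), function(i) {
      data.frame(snp_id = unlist(strsplit(r$snp_ids[i], ",")),
                 s_gene = r$s_gene[i], t_gene = r$t_gene[i],
                 cis = if (r$class[i] == "cis") "1" else "NA",
                 stringsAsFactors = FALSE)
    }))
    if (is.null(snp_rows))
      snp_rows <- data.frame(snp_id = character(0), s_gene = character(0),
                             t_gene = character(0), cis = character(0))
    f <- file.path(dir, paste0(c("tgene_", "sgene_", "snp_"), pop, ".tsv"))
    utils::write.table(tgt, f[1], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sgt, f[2], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(snp_rows, f[3], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
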