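#' Genotype matrix container
#'
#' Holds additively coded genotypes (count of the B/ALT allele: 0, 1, 2, or
#' `NA` for a missing call) for `n` samples by `s` SNPs, together with SNP
#' metadata used for gene assignment and quality control.
#'
#' @param values numeric matrix, samples in rows, SNPs in columns. Row names
#'   are sample ids, column names SNP ids. Entries must be 0, 1, 2 or `NA`.
#' @param snp_meta data frame with one row per SNP: columns `snp_id`,
#'   `chrom`, `pos` (1-based), and optionally `alleleA`, `alleleB`. If
#'   `NULL`, a skeleton with unknown positions is created.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, snp_meta = NULL) {
  values <- as.matrix(values)
  if (ncol(values) == 0L) colnames(values) <- character(0)
  if (is.null(colnames(values)))
    stop("genotype values must have SNP ids as column names")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample", seq_len(nrow(values)))
  storage.mode(values) <- "double"
  bad <- !is.na(values) & !(values %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("genotype code outside {0,1,2,NA} at sample '%s', SNP '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(snp_id = colnames(values),
                           chrom = NA_character_, pos = NA_integer_,
                           alleleA = NA_character_, alleleB = NA_character_,
                           stringsAsFactors = FALSE)
  }
  snp_meta <- as.data.frame(snp_meta)
  if (!all(c("snp_id", "chrom", "pos") %in% names(snp_meta)))
    stop("snp_meta needs columns snp_id, chrom, pos")
  if (!identical(as.character(snp_meta$snp_id), colnames(values)))
    stop("snp_meta rows must match genotype columns in order")
  if (any(!is.na(snp_meta$pos) & snp_meta$pos < 1))
    stop("SNP positions must be >= 1")
  snp_meta$chrom <- norm_chrom(snp_meta$chrom)
  structure(list(values = values, snp_meta = snp_meta),
            class = "genotype_matrix")
}

#' Expression matrix container
#'
#' Holds real-valued expression of `n` samples by `t` transcript probes with
#' probe metadata (target gene, chromosome, annotation source database).
#'
#' @param values numeric matrix, samples in rows, probes in columns.
#' @param probe_meta data frame with columns `probe_id`, `gene_id`, `chrom`,
#'   `source` (e.g. "RefSeq", "UniGene", "Gnomon"); `NULL` for a skeleton.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probe_meta = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("expression values must have probe ids as column names")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample", seq_len(nrow(values)))
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (is.null(probe_meta)) {
    probe_meta <- data.frame(probe_id = colnames(values),
                             gene_id = NA_character_, chrom = NA_character_,
                             source = NA_character_, stringsAsFactors = FALSE)
  }
  probe_meta <- as.data.frame(probe_meta)
  if (!all(c("probe_id", "gene_id") %in% names(probe_meta)))
    stop("probe_meta needs columns probe_id, gene_id")
  if (is.null(probe_meta$chrom)) probe_meta$chrom <- NA_character_
  if (is.null(probe_meta$source)) probe_meta$source <- NA_character_
  if (!identical(as.character(probe_meta$probe_id), colnames(values)))
    stop("probe_meta rows must match expression columns in order")
  probe_meta$chrom <- norm_chrom(probe_meta$chrom)
  structure(list(values = values, probe_meta = probe_meta),
            class = "expression_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d probes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# chromosome naming: strip a leading "chr" so annotation dialects agree
norm_chrom <- function(ch) {
  ch <- as.character(ch)
  sub("^chr", "", ch, ignore.case = TRUE)
}

#' Subset a genotype matrix by SNP ids (keeps metadata in step)
#' @param g a [genotype_matrix()]
#' @param snp_ids SNP ids to keep, in the given order
#' @return a `genotype_matrix`
#' @export
subset_snps <- function(g, snp_ids) {
  stopifnot(inherits(g, "genotype_matrix"))
  keep <- match(snp_ids, colnames(g$values))
  if (anyNA(keep)) stop("unknown SNP id(s): ",
                        paste(snp_ids[is.na(keep)], collapse = ", "))
  genotype_matrix(g$values[, keep, drop = FALSE],
                  g$snp_meta[keep, , drop = FALSE])
}
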