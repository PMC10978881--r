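# File interfaces: VCF (GT-coded) and a TSV dosage dialect for genotypes,
# TSV matrices for phenotypes/covariates, JSON for simulation truth.

#' Write a genotype set as a GT-coded VCF
#'
#' Hard dosages 0/1/2 become GT `0/0`, `0/1`, `1/1`; `NA` becomes `./.`.
#'
#' @param genos A [genotype_set()].
#' @param path Output path (plain text `.vcf`).
#' @export
write_vcf <- function(genos, path) {
  v <- genos$variants
  d <- genos$dosage
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    s <- ifelse(is.na(g), "./.", gt[as.integer(round(g)) + 1L])
    paste(c(v$chrom[j], v$pos[j], v$snp[j], v$ref[j], v$alt[j], ".",
            "PASS", sprintf("AF=%.6g;INFO=%.4g", v$af[j], v$info[j]),
            "GT", s), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info score\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a GT-coded VCF into a genotype set
#'
#' Uses VariantAnnotation for parsing; counts alternate alleles in the GT
#' field to recover dosages.
#'
#' @param path Path to a VCF file.
#' @return A [genotype_set()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  dos <- matrix(NA_real_, nrow(gt), ncol(gt))
  dos[gt == "0/0" | gt == "0|0"] <- 0
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  dos[gt == "1/1" | gt == "1|1"] <- 2
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  af <- if ("AF" %in% names(info)) as.numeric(unlist(info$AF)) else
    colMeans(t(dos), na.rm = TRUE) / 2
  inf <- if ("INFO" %in% names(info)) as.numeric(info$INFO) else 1.0
  variants <- data.frame(
    snp = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a)[1], character(1)),
    af = af, info = inf)
  genotype_set(t(dos), variants)
}

#' Write/read the TSV dosage dialect
#'
#' Rows are SNPs (columns `snp`, `chrom`, `pos`, `ref`, `alt`, `af`,
#' `info`, then one column per individual); values are dosages in
#' `{0, 1, 2}` or `NA`.
#'
#' @param genos A [genotype_set()].
#' @param path Output path.
#' @export
write_dosage_tsv <- function(genos, path) {
  dt <- data.table::as.data.table(genos$variants)
  dt <- cbind(dt, data.table::as.data.table(t(genos$dosage)))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @return `read_dosage_tsv`: a [genotype_set()].
#' @export
read_dosage_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  meta <- c("snp", "chrom", "pos", "ref", "alt", "af", "info")
  variants <- as.data.frame(dt[, meta, with = FALSE])
  variants$chrom <- as.character(variants$chrom)
  dos <- t(as.matrix(dt[, -meta, with = FALSE]))
  genotype_set(dos, variants)
}

#' Write a numeric matrix as TSV with a row-name column
#'
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @param rowname_col Name for the row-id column.
#' @export
write_matrix_tsv <- function(m, path, rowname_col = "id") {
  dt <- data.table::as.data.table(m, keep.rownames = rowname_col)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, rowname_col = "id") {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -rowname_col, with = FALSE])
  rownames(m) <- dt[[rowname_col]]
  m
}

#' Persist simulation truth as JSON
#'
#' @param truth A [sim_truth()].
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(probes = truth$probes, rho_b = truth$rho_b,
         noise_sd = truth$noise_sd, gamma = as.list(truth$gamma),
         window = truth$window),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gamma <- unlist(x$gamma)
  structure(list(probes = as.data.frame(x$probes), rho_b = x$rho_b,
                 noise_sd = x$noise_sd,
                 gamma = if (length(gamma)) gamma else NULL,
                 window = x$window),
            class = "sim_truth")
}
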