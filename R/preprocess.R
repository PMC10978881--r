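# Genotype QC and methylation pre-correction.

#' QC thresholds for genotype filtering
#'
#' Defaults follow the standard imputation-QC protocol: exclude SNPs with
#' missing call rate > 5%, Hardy-Weinberg exact p < 1e-6, minor allele
#' frequency < 1%, or imputation info score < 0.8.
#'
#' @param max_missing_rate,hwe_p_min,maf_min,info_min Numeric thresholds in
#'   (0, 1).
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_missing_rate = 0.05, hwe_p_min = 1e-6,
                          maf_min = 0.01, info_min = 0.8) {
  x <- list(max_missing_rate = max_missing_rate, hwe_p_min = hwe_p_min,
            maf_min = maf_min, info_min = info_min)
  if (any(unlist(x) <= 0) || any(unlist(x) >= 1))
    stop("all thresholds must lie in (0, 1)")
  structure(x, class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on genotype counts: the p-value is the sum of the
#' probabilities of all heterozygote counts (conditional on allele counts)
#' no more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  n_rare <- 2L * min(n_AA, n_aa) + n_Aa
  if (n_rare == 0L) return(1)  # monomorphic
  # heterozygote counts share parity with n_rare
  hets <- seq(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  # unnormalized log-probabilities of each heterozygote count
  rare_hom <- (n_rare - hets) / 2L
  com_hom <- n - hets - rare_hom
  logp <- hets * log(2) - lfactorial(hets) - lfactorial(rare_hom) -
    lfactorial(com_hom)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs + 1e-12]))
}

#' Filter SNPs by QC thresholds
#'
#' Applies, in order, the missingness, info-score, Hardy-Weinberg and minor
#' allele frequency filters; a SNP is excluded with the first reason that
#' applies. The relative order of surviving SNPs is preserved.
#'
#' @param genos A [genotype_set()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `genos` (filtered [genotype_set()]) and `log`
#'   (`data.frame` snp, reason for each excluded SNP).
#' @export
qc_genotypes <- function(genos, thresholds = qc_thresholds()) {
  d <- genos$dosage
  n <- nrow(d)
  miss <- colMeans(is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  hard <- round(d)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    g <- hard[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  info <- genos$variants$info
  reason <- rep(NA_character_, ncol(d))
  reason[maf < thresholds$maf_min] <- "maf"
  reason[hwe_p < thresholds$hwe_p_min] <- "hwe"
  reason[info < thresholds$info_min] <- "info"
  reason[miss > thresholds$max_missing_rate] <- "missing"
  keep <- is.na(reason)
  if (!any(keep)) warning("no SNPs pass QC")
  log <- data.frame(snp = genos$variants$snp[!keep],
                    reason = reason[!keep])
  out <- genotype_set(d[, keep, drop = FALSE],
                      genos$variants[keep, , drop = FALSE])
  list(genos = out, log = log)
}

#' Residualize methylation on covariates
#'
#' Per-probe least squares: each probe's values are regressed on an
#' intercept, the numeric covariates (sex, age, age squared, cell
#' proportions, ...) and indicator columns for any factor/character
#' covariates (batch), and replaced by the residuals. Collinear design
#' columns are dropped with a warning.
#'
#' @param values Probe x individual matrix.
#' @param covariates `data.frame` with one row per individual. An `age`
#'   column automatically contributes `age^2` as well.
#' @return Residual matrix of the same shape.
#' @export
adjust_methylation <- function(values, covariates) {
  if (ncol(values) != nrow(covariates))
    stop("covariate rows must match individuals (matrix columns)")
  if (anyNA(covariates)) stop("missing covariates are not allowed")
  cv <- as.data.frame(covariates)
  if ("age" %in% names(cv)) cv$age2 <- cv$age^2
  X <- stats::model.matrix(~ ., data = cv)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    warning("dropping collinear design columns: ",
            paste(drop, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  res <- t(qr.resid(qx, t(values)))
  dimnames(res) <- dimnames(values)
  res
}

#' Rank-based inverse normal transformation
#'
#' Blom variant: `qnorm((rank - 3/8) / (n + 1/4))`, ties sharing averaged
#' ranks.
#'
#' @param x Numeric vector, length >= 3, not constant.
#' @return Transformed vector with mean ~0 and SD ~1.
#' @export
rank_int <- function(x) {
  if (length(x) < 3) stop("need at least 3 values")
  if (stats::sd(x) == 0) stop("constant vector cannot be rank-transformed")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}
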