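# Cis-window association scans, lead-SNP extraction, IVW meta-analysis and
# allele harmonization.

#' SNPs within a cis window of a probe
#'
#' Closed interval `[probe_pos - window, probe_pos + window]` on the
#' probe's chromosome.
#'
#' @param probe_pos Probe position (1-based bp).
#' @param variants Variant table with columns `pos` and, when `chrom` is
#'   given, `chrom`.
#' @param window Half-window in bp (default 1 Mb).
#' @param chrom Optional probe chromosome; when supplied only variants on
#'   the same chromosome are eligible.
#' @return Integer indices into `variants` (possibly empty).
#' @export
cis_window <- function(probe_pos, variants, window = 1e6, chrom = NULL) {
  if (window < 0) stop("window must be non-negative")
  ok <- abs(variants$pos - probe_pos) <= window
  if (!is.null(chrom)) ok <- ok & variants$chrom == chrom
  which(ok)
}

#' Per-SNP simple regression scan
#'
#' Ordinary least squares of a phenotype on each SNP dosage separately
#' (with intercept). Missing dosages are mean-imputed per SNP; SNPs with
#' zero dosage variance are dropped with a warning. Two-sided p-values come
#' from the t distribution with n - 2 degrees of freedom.
#'
#' @param y Numeric phenotype vector (typically INT residuals), aligned
#'   with the genotype rows.
#' @param genos A [genotype_set()].
#' @param snp_idx Integer indices of SNPs to test (default: all).
#' @param probe Probe id recorded in the output.
#' @param probe_pos Optional probe position, carried into the output for
#'   lead-SNP tie-breaking.
#' @return `data.table` with columns probe, snp, chrom, pos,
#'   effect_allele, other_allele, af, beta, se, p, n (and probe_pos when
#'   given). The effect allele is the ALT allele.
#' @export
assoc_scan <- function(y, genos, snp_idx = NULL, probe = "probe",
                       probe_pos = NULL) {
  d <- genos$dosage
  if (length(y) != nrow(d)) stop("y and genotypes must align on individuals")
  if (is.null(snp_idx)) snp_idx <- seq_len(ncol(d))
  G <- d[, snp_idx, drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2L]]
  }
  n <- length(y)
  gc_ <- sweep(G, 2L, colMeans(G))
  yc <- y - mean(y)
  sxx <- colSums(gc_^2)
  keep <- sxx > 0
  if (!all(keep)) {
    warning(sum(!keep), " SNP(s) with zero dosage variance dropped")
    G <- G[, keep, drop = FALSE]
    gc_ <- gc_[, keep, drop = FALSE]
    sxx <- sxx[keep]
    snp_idx <- snp_idx[keep]
  }
  sxy <- as.numeric(crossprod(gc_, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  tstat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  v <- genos$variants[snp_idx, , drop = FALSE]
  out <- data.table::data.table(
    probe = probe, snp = v$snp, chrom = v$chrom, pos = v$pos,
    effect_allele = v$alt, other_allele = v$ref,
    af = colMeans(G) / 2, beta = beta, se = se, p = p, n = n)
  if (!is.null(probe_pos)) out$probe_pos <- probe_pos
  out[]
}

#' Scan every probe's cis window
#'
#' Convenience wrapper: for each probe, runs [assoc_scan()] on the SNPs
#' returned by [cis_window()]; probes with an empty window are skipped.
#'
#' @param meth Probe x individual matrix (already adjusted/transformed).
#' @param genos A [genotype_set()].
#' @param probes `data.frame` with columns probe, chrom, pos.
#' @param window Cis half-window in bp.
#' @return `data.table` of stacked [assoc_scan()] records.
#' @export
scan_cis <- function(meth, genos, probes, window = 1e6) {
  res <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    idx <- cis_window(probes$pos[i], genos$variants, window,
                      chrom = probes$chrom[i])
    if (!length(idx)) next
    res[[i]] <- assoc_scan(meth[probes$probe[i], ], genos, idx,
                           probe = probes$probe[i],
                           probe_pos = probes$pos[i])
  }
  data.table::rbindlist(res)
}

#' Lead SNP for one probe
#'
#' Minimum p-value with a deterministic tie-break: larger `|beta/se|`, then
#' smaller distance to the probe (when `probe_pos` is available), then
#' smaller position.
#'
#' @param records [assoc_scan()] records for a single probe.
#' @return One-row `data.table` (the lead record).
#' @export
lead_snp <- function(records) {
  if (!nrow(records)) stop("no records")
  r <- data.table::as.data.table(records)
  dist <- if ("probe_pos" %in% names(r)) abs(r$pos - r$probe_pos) else
    rep(0, nrow(r))
  ord <- order(r$p, -abs(r$beta / r$se), dist, r$pos)
  r[ord[1L]]
}

#' Lead SNPs for all probes
#'
#' @param records Stacked [assoc_scan()] records.
#' @return `data.table` with one lead record per probe.
#' @export
lead_snps <- function(records) {
  r <- data.table::as.data.table(records)
  r[, lead_snp(.SD), by = "probe"]
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' `w_i = 1/se_i^2`; pooled beta is the weighted mean, pooled
#' `se = (sum w)^(-1/2)`, p from the normal z statistic.
#'
#' @param beta,se Aligned per-cohort effect and standard-error vectors.
#' @return List with `beta`, `se`, `p`.
#' @export
ivw_meta <- function(beta, se) {
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  list(beta = b, se = s, p = 2 * stats::pnorm(-abs(b / s)))
}

#' Meta-analyse cohort summary statistics
#'
#' Groups records by (probe, snp) across cohorts — alleles are assumed
#' harmonized (see [harmonize_alleles()]) — and applies [ivw_meta()].
#' Sample sizes are summed and allele frequencies n-weighted.
#'
#' @param stats_list List of per-cohort [assoc_scan()] record tables.
#' @return `data.table` of meta records (probe, snp, chrom, pos, alleles,
#'   af, beta, se, p, n, k_cohorts).
#' @export
meta_cohorts <- function(stats_list) {
  all <- data.table::rbindlist(stats_list, use.names = TRUE, fill = TRUE)
  if (any(all$se <= 0)) stop("all standard errors must be positive")
  all[, {
    w <- 1 / se^2
    b <- sum(w * beta) / sum(w)
    s <- 1 / sqrt(sum(w))
    list(chrom = chrom[1L], pos = pos[1L],
         effect_allele = effect_allele[1L], other_allele = other_allele[1L],
         af = sum(af * n) / sum(n), beta = b, se = s,
         p = 2 * stats::pnorm(-abs(b / s)), n = sum(n),
         k_cohorts = .N,
         probe_pos = if ("probe_pos" %in% names(.SD)) probe_pos[1L] else
           NA_real_)
  }, by = c("probe", "snp")]
}

#' Harmonize effect alleles across datasets
#'
#' Aligns records to a reference allele table. Records whose effect/other
#' alleles are swapped relative to the reference are sign-flipped (beta and
#' af). Strand-ambiguous SNPs (A/T or C/G) are resolved by allele frequency
#' when unambiguous (reference MAF < 0.4 and frequencies consistent under
#' one orientation), otherwise dropped with a warning; records whose
#' alleles cannot be reconciled by a flip or swap are dropped with a
#' warning.
#'
#' @param records Summary-statistic records with columns snp,
#'   effect_allele, other_allele, af, beta.
#' @param reference `data.frame` with columns snp, effect_allele,
#'   other_allele and optionally af.
#' @return Harmonized records (possibly fewer rows).
#' @export
harmonize_alleles <- function(records, reference) {
  r <- data.table::as.data.table(records)
  ref <- data.table::as.data.table(reference)
  m <- match(r$snp, ref$snp)
  keep <- !is.na(m)
  if (!all(keep)) warning(sum(!keep), " record(s) absent from reference dropped")
  r <- r[keep]; m <- m[keep]
  rea <- ref$effect_allele[m]; roa <- ref$other_allele[m]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ambiguous <- rea == comp[roa]
  same <- r$effect_allele == rea & r$other_allele == roa
  swapped <- r$effect_allele == roa & r$other_allele == rea
  flip_strand <- comp[r$effect_allele] == rea & comp[r$other_allele] == roa
  drop <- !(same | swapped | flip_strand)
  if ("af" %in% names(ref)) {
    raf <- ref$af[m]
    bad_amb <- ambiguous & pmin(raf, 1 - raf) >= 0.4
    drop <- drop | bad_amb
    # ambiguous but resolvable by AF: orient so frequencies agree
    res_amb <- ambiguous & !bad_amb & !drop
    disagree <- res_amb & (abs(r$af - raf) > abs((1 - r$af) - raf))
    swapped <- swapped | (disagree & !swapped)
  } else {
    drop <- drop | ambiguous
  }
  if (any(drop))
    warning(sum(drop), " record(s) dropped during allele harmonization")
  r <- r[!drop]
  sw <- swapped[!drop]
  r[sw, `:=`(beta = -beta, af = 1 - af)]
  r[, `:=`(effect_allele = rea[!drop], other_allele = roa[!drop])]
  r[]
}
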