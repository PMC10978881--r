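# Summary-based Mendelian randomization and the HEIDI heterogeneity test.

#' SMR test at a single instrument
#'
#' With exposure (methylation) association `b_zx, se_zx` and outcome
#' (trait) association `b_zy, se_zy` at the instrument SNP:
#' `T_SMR = z_zx^2 z_zy^2 / (z_zx^2 + z_zy^2)` is compared to a 1-df
#' chi-square; the mediated effect is `b_xy = b_zy / b_zx` with
#' delta-method standard error.
#'
#' @param b_zx,se_zx SNP effect on the exposure and its SE.
#' @param b_zy,se_zy SNP effect on the outcome and its SE.
#' @return List with `b_xy`, `se_xy`, `t_smr`, `p_smr`. A warning is
#'   emitted for weak instruments (`z_zx^2 < 10`).
#' @export
smr_test <- function(b_zx, se_zx, b_zy, se_zy) {
  if (se_zx <= 0 || se_zy <= 0) stop("standard errors must be positive")
  z_zx <- b_zx / se_zx
  z_zy <- b_zy / se_zy
  if (z_zx^2 < 10) warning("weak instrument: z_zx^2 < 10")
  t_smr <- if (z_zy == 0) 0 else
    z_zx^2 * z_zy^2 / (z_zx^2 + z_zy^2)
  b_xy <- b_zy / b_zx
  se_xy <- sqrt(b_xy^2 * (se_zy^2 / b_zy^2 + se_zx^2 / b_zx^2))
  if (b_zy == 0) se_xy <- se_zy / abs(b_zx)
  list(b_xy = b_xy, se_xy = se_xy, t_smr = t_smr,
       p_smr = stats::pchisq(t_smr, df = 1, lower.tail = FALSE))
}

#' HEIDI heterogeneity test
#'
#' Distinguishes a single shared causal variant (the SMR model) from
#' distinct variants in linkage. For each eligible cis SNP `i` (reference
#' r-squared with the top instrument within `r2_bounds`, exposure
#' association below `p_zx_max`, capped at `max_snps` strongest), the
#' deviation `d_i = b_xy(i) - b_xy(top)` should be zero under a shared
#' causal variant. The statistic sums squared standardized deviations; the
#' null distribution of the correlated sum is approximated by two-moment
#' (Satterthwaite) matching using the delta-method covariance of the
#' `d_i`, with cross-SNP correlation taken from the reference LD matrix.
#'
#' @param stats_zx Exposure cis records (snp, beta, se).
#' @param stats_zy Outcome records at the same SNPs (snp, beta, se).
#' @param R Reference LD correlation matrix covering the SNPs.
#' @param top Instrument SNP id (the mQTL lead).
#' @param r2_bounds Eligibility r-squared interval with the top SNP
#'   (default 0.05–0.9, open at both ends).
#' @param max_snps Cap on eligible SNPs (default 20).
#' @param p_zx_max Exposure p-value ceiling for eligibility (default
#'   1.57e-3, i.e. |z| > 3.16).
#' @return List with `p_heidi` (NA with `reason` when < 3 eligible SNPs)
#'   and `n_snps`.
#' @export
heidi_test <- function(stats_zx, stats_zy, R, top,
                       r2_bounds = c(0.05, 0.9), max_snps = 20L,
                       p_zx_max = 1.57e-3) {
  zx <- data.table::as.data.table(stats_zx)
  zy <- data.table::as.data.table(stats_zy)
  m <- merge(zx[, list(snp, b_zx = beta, se_zx = se)],
             zy[, list(snp, b_zy = beta, se_zy = se)], by = "snp")
  m <- m[snp %in% rownames(R)]
  if (!(top %in% m$snp))
    return(list(p_heidi = NA_real_, n_snps = 0L,
                reason = "top SNP missing from merged stats"))
  r_top <- R[m$snp, top]
  p_zx <- 2 * stats::pnorm(-abs(m$b_zx / m$se_zx))
  elig <- m$snp != top & r_top^2 > r2_bounds[1] & r_top^2 < r2_bounds[2] &
    p_zx < p_zx_max
  cand <- m[elig]
  if (nrow(cand) > max_snps)
    cand <- cand[order(2 * stats::pnorm(-abs(b_zx / se_zx)))][seq_len(max_snps)]
  if (nrow(cand) < 3)
    return(list(p_heidi = NA_real_, n_snps = nrow(cand),
                reason = "fewer than 3 eligible SNPs"))
  tt <- m[snp == top]
  bxy_top <- tt$b_zy / tt$b_zx
  bxy <- cand$b_zy / cand$b_zx
  d <- bxy - bxy_top
  # delta-method covariance of b_xy across SNPs; exposure and outcome
  # samples are independent, cross-SNP correlation ~ reference LD r
  snps <- c(tt$snp, cand$snp)
  r <- R[snps, snps]
  b_zx_all <- c(tt$b_zx, cand$b_zx)
  b_zy_all <- c(tt$b_zy, cand$b_zy)
  se_zx_all <- c(tt$se_zx, cand$se_zx)
  se_zy_all <- c(tt$se_zy, cand$se_zy)
  k <- length(snps)
  Vb <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    Vb[i, j] <- r[i, j] *
      (se_zy_all[i] * se_zy_all[j] / (b_zx_all[i] * b_zx_all[j]) +
         b_zy_all[i] * b_zy_all[j] * se_zx_all[i] * se_zx_all[j] /
           (b_zx_all[i]^2 * b_zx_all[j]^2))
  }
  # covariance of d_i = b_xy(i) - b_xy(top); index 1 is the top SNP
  idx <- 2:k
  Vd <- Vb[idx, idx] - outer(Vb[idx, 1], rep(1, k - 1)) -
    outer(rep(1, k - 1), Vb[1, idx]) + Vb[1, 1]
  sd_d <- sqrt(diag(Vd))
  zd <- d / sd_d
  Corr <- Vd / outer(sd_d, sd_d)
  t_heidi <- sum(zd^2)
  # Satterthwaite: match mean and variance of the correlated chi-square sum
  mu <- k - 1
  v <- 2 * sum(Corr^2)
  a <- v / (2 * mu)
  nu <- 2 * mu^2 / v
  list(p_heidi = stats::pchisq(t_heidi / a, df = nu, lower.tail = FALSE),
       n_snps = nrow(cand))
}

#' SMR + HEIDI over ancestry-specific mQTLs
#'
#' For each ancestry-specific probe, the instrument is its lead SNP in the
#' significant ancestry; the SNP's effect is looked up in that ancestry's
#' GWAS. Probes with any genome-wide-significant GWAS signal
#' (`p < gwas_sig`) inside the cis window of the *alternate* ancestry's
#' GWAS are excluded, so surviving signals are genuinely
#' ancestry-specific. HEIDI is run with the same ancestry's cis stats and
#' reference panel.
#'
#' @param sets Output of [define_sets()] (only specific labels used).
#' @param meta_stats Named list ("EUR", "EAS") of meta summary tables.
#' @param gwas Named list ("EUR", "EAS") of GWAS tables (snp, beta, se, p;
#'   optionally chrom, pos).
#' @param panels Named list of reference [genotype_set()]s.
#' @param probes Probe table (probe, chrom, pos) for window lookups.
#' @param window Cis half-window (default 1 Mb).
#' @param p_smr_sig SMR significance threshold (default 1e-7; the
#'   Bonferroni level for the probe count tested; 1e-6 is the common
#'   alternative preset).
#' @param p_heidi_min HEIDI retention threshold (default 0.01).
#' @param gwas_sig GWAS significance for the alternate-ancestry exclusion
#'   (default 5e-8).
#' @return `data.table`: probe, ancestry, snp, b_xy, se_xy, p_smr,
#'   p_heidi, n_heidi_snps, significant, excluded_alt_gwas, reason.
#' @export
ancestry_specific_smr <- function(sets, meta_stats, gwas, panels, probes,
                                  window = 1e6, p_smr_sig = 1e-7,
                                  p_heidi_min = 0.01, gwas_sig = 5e-8) {
  s <- data.table::as.data.table(sets)
  s <- s[label %in% c("EUR_SPECIFIC", "EAS_SPECIFIC")]
  pr <- data.table::as.data.table(probes)
  out <- list()
  for (i in seq_len(nrow(s))) {
    anc <- if (s$label[i] == "EUR_SPECIFIC") "EUR" else "EAS"
    alt <- setdiff(c("EUR", "EAS"), anc)
    p_ <- s$probe[i]
    lead <- if (anc == "EUR") s$lead_eur[i] else s$lead_eas[i]
    row <- data.table::data.table(
      probe = p_, ancestry = anc, snp = lead, b_xy = NA_real_,
      se_xy = NA_real_, p_smr = NA_real_, p_heidi = NA_real_,
      n_heidi_snps = 0L, significant = FALSE, excluded_alt_gwas = FALSE,
      reason = NA_character_)
    ppos <- pr[probe == p_]
    cis <- data.table::as.data.table(meta_stats[[anc]])[probe == p_]
    # alternate-ancestry GWAS signal inside the cis window -> exclude
    galt <- data.table::as.data.table(gwas[[alt]])
    if (nrow(ppos) && all(c("chrom", "pos") %in% names(galt))) {
      hit <- galt[chrom == ppos$chrom & abs(pos - ppos$pos) <= window &
                    p < gwas_sig]
      if (nrow(hit)) {
        row$excluded_alt_gwas <- TRUE
        row$reason <- "GWAS signal in alternate ancestry cis window"
        out[[length(out) + 1L]] <- row
        next
      }
    }
    ganc <- data.table::as.data.table(gwas[[anc]])
    gy <- ganc[snp == lead]
    if (!nrow(gy)) {
      row$reason <- "instrument SNP absent from GWAS"
      out[[length(out) + 1L]] <- row
      next
    }
    zx <- cis[snp == lead]
    if (!nrow(zx)) {
      row$reason <- "instrument SNP absent from cis stats"
      out[[length(out) + 1L]] <- row
      next
    }
    sm <- suppressWarnings(smr_test(zx$beta, zx$se, gy$beta, gy$se))
    row$b_xy <- sm$b_xy; row$se_xy <- sm$se_xy; row$p_smr <- sm$p_smr
    shared <- intersect(cis$snp, ganc$snp)
    if (length(shared) >= 3 && lead %in% shared &&
        all(shared %in% panels[[anc]]$variants$snp)) {
      R <- ld_matrix(panels[[anc]], shared)
      hd <- heidi_test(cis[snp %in% shared], ganc[snp %in% shared], R, lead)
      row$p_heidi <- hd$p_heidi
      row$n_heidi_snps <- hd$n_snps
    }
    row$significant <- !is.na(row$p_smr) && row$p_smr < p_smr_sig &&
      (is.na(row$p_heidi) || row$p_heidi > p_heidi_min)
    out[[length(out) + 1L]] <- row
  }
  data.table::rbindlist(out)
}
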