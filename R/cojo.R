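# Stepwise approximate conditional analysis from summary statistics.

#' Conditional z-score given a selected SNP set
#'
#' Standardized-genotype formulation: with marginal z-scores `z` and a
#' reference LD correlation matrix `R`,
#' `z_cond(t | C) = (z_t - R_tC R_CC^-1 z_C) / sqrt(1 - R_tC R_CC^-1 R_Ct)`.
#' `R_CC` is ridge-stabilized by adding 1e-6 to its diagonal. Targets whose
#' conditional variance falls below `1e-4` (near-collinear with the
#' selected set) are flagged and skipped.
#'
#' @param z Named marginal z-score vector over the window SNPs.
#' @param R LD correlation matrix with matching dimnames.
#' @param selected Character vector of conditioned SNP ids (may be empty).
#' @param targets SNP ids to evaluate (default: all non-selected).
#' @return `data.table`: snp, z_cond, ok (FALSE where skipped as
#'   collinear).
#' @export
conditional_z <- function(z, R, selected = character(), targets = NULL) {
  snps <- names(z)
  if (is.null(targets)) targets <- setdiff(snps, selected)
  if (!length(selected)) {
    return(data.table::data.table(snp = targets, z_cond = z[targets],
                                  ok = TRUE))
  }
  Rcc <- R[selected, selected, drop = FALSE]
  diag(Rcc) <- diag(Rcc) + 1e-6
  Rinv <- solve(Rcc)
  Rtc <- R[targets, selected, drop = FALSE]
  num <- z[targets] - as.numeric(Rtc %*% (Rinv %*% z[selected]))
  denom2 <- 1 - rowSums((Rtc %*% Rinv) * Rtc)
  ok <- denom2 > 1e-4
  zc <- rep(NA_real_, length(targets))
  zc[ok] <- num[ok] / sqrt(denom2[ok])
  data.table::data.table(snp = targets, z_cond = zc, ok = ok)
}

#' Stepwise selection of conditionally independent SNPs
#'
#' Starts from the lead SNP, then repeatedly adds the SNP with the
#' smallest conditional p-value, provided it stays below `p_thresh` and
#' its maximum reference r-squared with the already-selected set stays
#' below `r2_cap`. Deterministic: p ties are broken by SNP id. Joint
#' statistics for the selected set come from the multiple-regression
#' transform of the z-scores (`z_joint = R^-1 z / sqrt(diag(R^-1))`).
#'
#' @param stats Summary records for one probe (columns snp, beta, se, p).
#' @param R Reference LD correlation matrix (dimnames = SNP ids).
#' @param p_thresh Conditional significance threshold (default 1e-10).
#' @param r2_cap Collinearity cap on reference r-squared (default 0.9).
#' @param max_steps Safety cap on selected signals.
#' @param panel_n Optional reference-panel sample size; a warning is
#'   emitted when it falls below 20x the selected-set size (unstable
#'   conditional estimates).
#' @return List of class `conditional_result`: `probe`, `selected`
#'   (`data.table`: snp, order, cond_p, joint_beta, joint_se, joint_p),
#'   `reason` (why selection stopped).
#' @export
stepwise_select <- function(stats, R, p_thresh = 1e-10, r2_cap = 0.9,
                            max_steps = 10L, panel_n = NULL) {
  s <- data.table::as.data.table(stats)
  probe <- if ("probe" %in% names(s)) s$probe[1L] else NA_character_
  s <- s[snp %in% rownames(R)]
  if (!nrow(s) || min(s$p) >= p_thresh) {
    return(structure(list(probe = probe,
                          selected = data.table::data.table(),
                          reason = "no SNP below threshold"),
                     class = "conditional_result"))
  }
  z <- stats::setNames(s$beta / s$se, s$snp)
  se_map <- stats::setNames(s$se, s$snp)
  n_map <- if ("n" %in% names(s)) stats::setNames(s$n, s$snp) else NULL
  lead <- s$snp[order(s$p, s$snp)][1L]
  selected <- lead
  cond_p <- stats::setNames(s$p[match(lead, s$snp)], lead)
  reason <- "threshold"
  while (length(selected) < max_steps) {
    cand <- setdiff(s$snp, selected)
    if (!length(cand)) { reason <- "exhausted"; break }
    r2max <- apply(R[cand, selected, drop = FALSE]^2, 1L, max)
    cand <- cand[r2max < r2_cap]
    if (!length(cand)) { reason <- "collinearity"; break }
    cz <- conditional_z(z, R, selected, cand)
    cz <- cz[ok == TRUE]
    if (!nrow(cz)) { reason <- "collinearity"; break }
    cz[, p := 2 * stats::pnorm(-abs(z_cond))]
    cz <- cz[order(p, snp)]
    if (cz$p[1L] >= p_thresh) break
    selected <- c(selected, cz$snp[1L])
    cond_p[cz$snp[1L]] <- cz$p[1L]
  }
  # joint statistics over the final selected set
  Rss <- R[selected, selected, drop = FALSE]
  diag(Rss) <- diag(Rss) + 1e-6
  Rinv <- solve(Rss)
  zj <- as.numeric(Rinv %*% z[selected]) / sqrt(diag(Rinv))
  joint_beta <- zj * se_map[selected]
  sel <- data.table::data.table(
    snp = selected, order = seq_along(selected),
    cond_p = as.numeric(cond_p[selected]),
    joint_beta = joint_beta, joint_se = se_map[selected],
    joint_p = 2 * stats::pnorm(-abs(zj)))
  if (!is.null(panel_n) && panel_n < 20L * length(selected))
    warning("reference panel (n = ", panel_n,
            ") is small for a selected set of ", length(selected), " SNPs")
  structure(list(probe = probe, selected = sel, reason = reason),
            class = "conditional_result")
}

#' LD correlation matrix from a reference panel
#'
#' @param ref A [genotype_set()].
#' @param snps SNP ids (default all).
#' @return Correlation matrix of dosages with SNP-id dimnames; monomorphic
#'   SNPs get zero off-diagonal correlation.
#' @export
ld_matrix <- function(ref, snps = NULL) {
  if (is.null(snps)) snps <- ref$variants$snp
  G <- ref$dosage[, snps, drop = FALSE]
  sds <- apply(G, 2L, stats::sd)
  R <- suppressWarnings(stats::cor(G))
  R[is.na(R)] <- 0
  diag(R) <- 1
  dimnames(R) <- list(snps, snps)
  R
}
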