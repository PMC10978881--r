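# Error-aware correlation of QTL effect sizes between datasets.

#' Correlation of effect sizes corrected for estimation error
#'
#' Naive Pearson correlation of estimated effects is attenuated by sampling
#' noise. The method-of-moments estimator used here subtracts the mean
#' squared standard error from each dataset's observed effect variance:
#' `r_b = cov(b1, b2) / sqrt((var(b1) - mean(se1^2)) *
#' (var(b2) - mean(se2^2)))`. For sample-independent datasets the
#' covariance needs no error correction. The standard error of `r_b` is a
#' delete-one jackknife.
#'
#' @param b1,se1 Effects and standard errors in the first dataset (lead
#'   SNPs ascertained there).
#' @param b2,se2 Effects at the same SNPs in the second dataset.
#' @return List with `rb`, `se` (jackknife), `n` (pairs used). `rb` is
#'   clipped to `[-1, 1]` with a warning when the correction overshoots.
#' @export
estimate_rb <- function(b1, se1, b2, se2) {
  n <- length(b1)
  if (n < 10) stop("need at least 10 effect pairs")
  if (any(se1 <= 0) || any(se2 <= 0)) stop("standard errors must be positive")
  rb_stat <- function(i) {
    v1 <- stats::var(b1[i]) - mean(se1[i]^2)
    v2 <- stats::var(b2[i]) - mean(se2[i]^2)
    if (v1 <= 0 || v2 <= 0) return(NA_real_)
    stats::cov(b1[i], b2[i]) / sqrt(v1 * v2)
  }
  full <- rb_stat(seq_len(n))
  if (is.na(full))
    stop("corrected variance non-positive: effects indistinguishable from noise")
  jack <- vapply(seq_len(n), function(k) rb_stat(seq_len(n)[-k]), numeric(1))
  jack <- jack[!is.na(jack)]
  se_jack <- sqrt((length(jack) - 1) / length(jack) *
                    sum((jack - mean(jack))^2))
  rb <- full
  if (abs(rb) > 1) {
    warning("r_b estimate ", format(rb, digits = 4), " clipped to [-1, 1]")
    rb <- max(-1, min(1, rb))
  }
  list(rb = rb, se = se_jack, n = n)
}

#' Pairwise r_b matrix across cohorts
#'
#' For every ordered (discovery, replication) pair of datasets, lead SNPs
#' are ascertained in the discovery dataset only (to avoid winner's-curse
#' bias from joint ascertainment), their effects looked up in the
#' replication dataset, and [estimate_rb()] applied. Pairs where the lead
#' SNP is absent from the replication dataset are dropped and counted.
#'
#' @param stats_list Named list of per-dataset summary-statistic tables
#'   (columns probe, snp, beta, se, p at minimum).
#' @param leads_list Optional named list of per-dataset lead tables; by
#'   default computed with [lead_snps()].
#' @param min_pairs Minimum overlapping pairs for a cell (default 10).
#' @param p_ascertain Optional p-value cutoff applied to discovery leads.
#' @return `data.table` with discovery, replication, rb, se, n_pairs,
#'   n_dropped. Cells with too few pairs hold `NA` with a warning.
#' @export
rb_matrix <- function(stats_list, leads_list = NULL, min_pairs = 10,
                      p_ascertain = NULL) {
  if (length(stats_list) < 2) stop("need at least two datasets")
  nm <- names(stats_list)
  if (is.null(leads_list))
    leads_list <- lapply(stats_list, lead_snps)
  out <- list()
  for (dis in nm) for (rep_ in nm) {
    if (dis == rep_) next
    ld <- data.table::as.data.table(leads_list[[dis]])
    if (!is.null(p_ascertain)) ld <- ld[p < p_ascertain]
    rs <- data.table::as.data.table(stats_list[[rep_]])
    mm <- merge(ld[, list(probe, snp, b1 = beta, se1 = se)],
                rs[, list(probe, snp, b2 = beta, se2 = se)],
                by = c("probe", "snp"))
    dropped <- nrow(ld) - nrow(mm)
    if (nrow(mm) < min_pairs) {
      warning("fewer than ", min_pairs, " overlapping lead SNPs for ",
              dis, " -> ", rep_)
      cell <- list(rb = NA_real_, se = NA_real_, n = nrow(mm))
    } else {
      cell <- estimate_rb(mm$b1, mm$se1, mm$b2, mm$se2)
    }
    out[[length(out) + 1L]] <- data.table::data.table(
      discovery = dis, replication = rep_, rb = cell$rb, se = cell$se,
      n_pairs = cell$n, n_dropped = dropped)
  }
  data.table::rbindlist(out)
}
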