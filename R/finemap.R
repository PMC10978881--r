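# Single-causal-variant fine mapping: Wakefield approximate Bayes factors,
# PIPs, 95% credible sets, outlier filtering, sample-size experiment.

#' Default prior effect-variance grid
#'
#' Grid of prior variances `W` for the causal effect on the standardized
#' phenotype scale; Bayes factors are averaged over the grid.
#'
#' @param W Positive numeric vector.
#' @return Validated grid.
#' @export
prior_spec <- function(W = c(0.01, 0.05, 0.1, 0.2, 0.4)) {
  if (any(W <= 0)) stop("all prior variances must be positive")
  W
}

#' Log approximate Bayes factor (Wakefield)
#'
#' `log ABF = 0.5 log(se^2 / (se^2 + W)) + z^2 W / (2 (se^2 + W))`,
#' `z = beta/se` — the normal-normal marginal likelihood ratio of a causal
#' model with prior effect variance `W` against the null.
#'
#' @param beta,se Effect estimate and standard error (se > 0). Vectorized.
#' @param W Prior effect variance (> 0).
#' @return Log Bayes factor(s).
#' @export
log_abf <- function(beta, se, W) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(W <= 0)) stop("W must be positive")
  v <- se^2
  z2 <- (beta / se)^2
  0.5 * log(v / (v + W)) + z2 * W / (2 * (v + W))
}

# log of mean(exp(x)) along rows of a matrix, stable
log_row_mean_exp <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowMeans(exp(M - mx)))
}

#' Single-ancestry posterior inclusion probabilities
#'
#' Under a single-causal-variant model with a uniform prior over the
#' window, each SNP's Bayes factor (averaged over the prior grid) is
#' normalized to a posterior inclusion probability.
#'
#' @param stats Window records (columns snp, beta, se).
#' @param prior Prior variance grid ([prior_spec()]).
#' @return Named PIP vector (sums to 1) in window order.
#' @export
pips_single <- function(stats, prior = prior_spec()) {
  s <- data.table::as.data.table(stats)
  if (!nrow(s)) stop("empty window")
  labf <- vapply(prior, function(w) log_abf(s$beta, s$se, w),
                 numeric(nrow(s)))
  lb <- log_row_mean_exp(matrix(labf, nrow = nrow(s)))
  lb <- lb - max(lb)
  pip <- exp(lb) / sum(exp(lb))
  stats::setNames(pip, s$snp)
}

#' Cross-ancestry posterior inclusion probabilities
#'
#' Joint single-causal model over the union of the two populations' window
#' SNPs: the samples are independent, the causal position is shared, and
#' effect sizes are population-specific, so the joint Bayes factor is the
#' product of per-population grid-averaged Bayes factors. A SNP missing
#' (monomorphic or filtered) in one population contributes `BF = 1` for
#' that population; SNPs missing in both are excluded.
#'
#' @param stats_eur,stats_eas Window records per population (columns snp,
#'   beta, se); either may lack some SNPs.
#' @param prior Prior variance grid.
#' @return Named PIP vector over the union window.
#' @export
pips_cross <- function(stats_eur, stats_eas, prior = prior_spec()) {
  se_ <- data.table::as.data.table(stats_eur)
  sa <- data.table::as.data.table(stats_eas)
  snps <- union(se_$snp, sa$snp)
  if (!length(snps)) stop("empty window")
  lb_pop <- function(s) {
    out <- stats::setNames(rep(0, length(snps)), snps)
    if (nrow(s)) {
      labf <- vapply(prior, function(w) log_abf(s$beta, s$se, w),
                     numeric(nrow(s)))
      out[s$snp] <- log_row_mean_exp(matrix(labf, nrow = nrow(s)))
    }
    out
  }
  lb <- lb_pop(se_) + lb_pop(sa)
  lb <- lb - max(lb)
  exp(lb) / sum(exp(lb))
}

#' 95% credible set from PIPs
#'
#' SNPs sorted by descending PIP (position, when supplied, breaks exact
#' ties deterministically); the set is the smallest prefix whose
#' cumulative PIP reaches the coverage target.
#'
#' @param pips Named, normalized PIP vector.
#' @param coverage Coverage target (default 0.95).
#' @param pos Optional position vector aligned with `pips` for
#'   tie-breaking.
#' @param probe,mode Metadata carried on the result.
#' @return List of class `credible_set`: `probe`, `mode`, `members`
#'   (`data.table`: snp, pip), `size`, `coverage`.
#' @export
credible_set <- function(pips, coverage = 0.95, pos = NULL,
                         probe = NA_character_, mode = NA_character_) {
  if (abs(sum(pips) - 1) > 1e-8) stop("PIPs must be normalized")
  tie <- if (is.null(pos)) seq_along(pips) else pos
  ord <- order(-pips, tie)
  cum <- unname(cumsum(pips[ord]))
  k <- which(cum >= coverage - 1e-12)[1L]
  if (is.na(k)) k <- length(pips)
  sel <- ord[seq_len(k)]
  structure(list(probe = probe, mode = mode,
                 members = data.table::data.table(snp = names(pips)[sel],
                                                  pip = as.numeric(pips[sel])),
                 size = k, coverage = as.numeric(cum[k])),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat("credible_set [", x$mode, "] probe", x$probe, "- size", x$size,
      "(coverage", round(x$coverage, 3), ")\n")
  invisible(x)
}

#' Filter grossly oversized credible sets
#'
#' A probe is excluded when, in at least one mode, its credible-set size
#' exceeds `mean + 3 IQR` of that mode's sizes (strict inequality, so a
#' degenerate IQR of zero retains sizes equal to the mean).
#'
#' @param sizes `data.frame` with columns probe, mode, size (>= 4 rows per
#'   mode).
#' @return List with `keep` (probes retained), `excluded` (`data.table`:
#'   probe, mode, size, cutoff).
#' @export
filter_outlier_sets <- function(sizes) {
  s <- data.table::as.data.table(sizes)
  if (any(s[, .N, by = "mode"]$N < 4)) stop("need at least 4 sets per mode")
  s[, cutoff := mean(size) + 3 * stats::IQR(size), by = "mode"]
  excluded <- s[size > cutoff]
  list(keep = setdiff(unique(s$probe), unique(excluded$probe)),
       excluded = excluded[, list(probe, mode, size, cutoff)])
}

#' Deduplicate probes sharing a lead SNP
#'
#' Where several probes have the same lead SNP, keep only the one with the
#' smallest p-value; optionally drop probes inside masked regions (BED,
#' 0-based half-open), the MHC being the canonical mask.
#'
#' @param leads Lead table (probe, snp, p, chrom, pos).
#' @param mask Optional `data.frame` with columns chrom, start, end.
#' @return Filtered lead table.
#' @export
dedupe_leads <- function(leads, mask = NULL) {
  l <- data.table::as.data.table(leads)
  if (!is.null(mask) && nrow(mask)) {
    drop <- rep(FALSE, nrow(l))
    for (i in seq_len(nrow(mask)))
      drop <- drop | (l$chrom == mask$chrom[i] & l$pos > mask$start[i] &
                        l$pos <= mask$end[i])
    l <- l[!drop]
  }
  l[order(p, probe)][!duplicated(snp)][order(probe)]
}

#' Sample-size versus credible-set-size experiment
#'
#' For each sample size in `n_grid`, simulates a fresh EUR cohort, one
#' phenotype per probe with the probe's causal SNP as the causal variant
#' (effect from the truth object), scans the cis window, fine-maps under
#' the single-causal model, and records credible-set sizes. When
#' `n_eas > 0`, an EAS cohort of that size is additionally simulated at
#' each grid point and a cross-ancestry set computed, quantifying what an
#' extra EAS cohort buys relative to the same number of extra EUR samples.
#'
#' @param model A [population_model()].
#' @param afs Output of [sample_population_afs()].
#' @param truth A [sim_truth()].
#' @param n_grid Ascending EUR sample sizes (each >= 50).
#' @param n_eas EAS cohort size for the cross mode (0 = single-ancestry
#'   only).
#' @param seed Integer seed.
#' @param coverage Credible-set coverage target.
#' @param prior Prior variance grid.
#' @return `data.table`: mode ("EUR"/"CROSS"), n (EUR size), n_eas,
#'   mean_size, median_size, n_probes.
#' @export
sample_size_experiment <- function(model, afs, truth, n_grid, n_eas = 0L,
                                   seed = 1L, coverage = 0.95,
                                   prior = prior_spec()) {
  if (is.unsorted(n_grid)) stop("n_grid must be ascending")
  if (any(n_grid < 50)) stop("sample sizes below 50 are refused")
  pr <- truth$probes
  res <- list()
  for (gi in seq_along(n_grid)) {
    n <- n_grid[gi]
    g_eur <- simulate_genotypes(model, afs$f_eur, n, seed + 100L * gi, "EUR")
    meth <- simulate_methylation(g_eur, truth, pop = "EUR",
                                 seed = seed + 100L * gi + 1L)
    meth <- t(apply(meth, 1L, rank_int))
    st_eur <- scan_cis(meth, g_eur, pr, window = truth$window)
    sizes_eur <- numeric(0)
    sizes_cross <- numeric(0)
    if (n_eas > 0) {
      g_eas <- simulate_genotypes(model, afs$f_eas, n_eas,
                                  seed + 100L * gi + 2L, "EAS")
      meth_a <- simulate_methylation(g_eas, truth, pop = "EUR",
                                     seed = seed + 100L * gi + 3L)
      meth_a <- t(apply(meth_a, 1L, rank_int))
      st_eas <- scan_cis(meth_a, g_eas, pr, window = truth$window)
    }
    for (pb in pr$probe) {
      se_ <- st_eur[probe == pb]
      if (!nrow(se_)) next
      cs <- credible_set(pips_single(se_, prior), coverage, pos = se_$pos,
                         probe = pb, mode = "EUR")
      sizes_eur <- c(sizes_eur, cs$size)
      if (n_eas > 0) {
        sa <- st_eas[probe == pb]
        pip <- pips_cross(se_, sa, prior)
        u <- union(se_$snp, sa$snp)
        upos <- se_$pos[match(u, se_$snp)]
        upos[is.na(upos)] <- sa$pos[match(u[is.na(upos)], sa$snp)]
        csx <- credible_set(pip, coverage, pos = upos, probe = pb,
                            mode = "CROSS")
        sizes_cross <- c(sizes_cross, csx$size)
      }
    }
    res[[length(res) + 1L]] <- data.table::data.table(
      mode = "EUR", n = n, n_eas = 0L, mean_size = mean(sizes_eur),
      median_size = stats::median(sizes_eur), n_probes = length(sizes_eur))
    if (n_eas > 0)
      res[[length(res) + 1L]] <- data.table::data.table(
        mode = "CROSS", n = n, n_eas = as.integer(n_eas),
        mean_size = mean(sizes_cross),
        median_size = stats::median(sizes_cross),
        n_probes = length(sizes_cross))
  }
  data.table::rbindlist(res)
}
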