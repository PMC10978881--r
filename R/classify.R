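# Stringent / ancestry-specific set construction, the hierarchical sharing
# classification, tallies, and allele-frequency heterogeneity.

SHARING_LEVELS <- c("SAME_LEAD_SAME_DIRECTION", "STRONG_LD", "BLOCK_OVERLAP",
                    "COJO_SAME_SNP", "COJO_BLOCK_OVERLAP", "UNEXPLAINED")

#' Assign probes to the stringent and ancestry-specific sets
#'
#' Per probe, using each ancestry's own meta-analysis lead SNP p-value:
#' `STRINGENT` when both ancestries reach `p < p_sig`; `EUR_SPECIFIC` /
#' `EAS_SPECIFIC` when one ancestry reaches `p < p_sig` and the other stays
#' above `p_rep`; `OTHER` otherwise (including the between-thresholds gap).
#' Ancestry-specific probes are excluded (relabelled `OTHER`, flags kept)
#' when the two ancestries share the same lead SNP, or when the probe's
#' mQTL is stringently significant in an individual cohort of the alternate
#' ancestry — both symptoms of a power artefact rather than true
#' specificity.
#'
#' @param lead_eur,lead_eas Per-probe lead tables (columns probe, snp, p)
#'   from each ancestry's meta-analysis.
#' @param cohort_stats Optional named list of per-cohort record tables; the
#'   parallel `cohort_pops` gives each cohort's ancestry.
#' @param cohort_pops Character vector ("EUR"/"EAS") aligned with
#'   `cohort_stats`.
#' @param p_sig Stringent threshold (default 1e-10).
#' @param p_rep Replication threshold (default 1e-6).
#' @return `data.table`: probe, label, p_eur, p_eas, lead_eur, lead_eas,
#'   excl_same_lead, excl_alt_cohort.
#' @export
define_sets <- function(lead_eur, lead_eas, cohort_stats = NULL,
                        cohort_pops = NULL, p_sig = 1e-10, p_rep = 1e-6) {
  le <- data.table::as.data.table(lead_eur)[, list(
    probe, lead_eur = snp, p_eur = p)]
  la <- data.table::as.data.table(lead_eas)[, list(
    probe, lead_eas = snp, p_eas = p)]
  x <- merge(le, la, by = "probe", all = TRUE)
  x[, label := "OTHER"]
  x[!is.na(p_eur) & !is.na(p_eas) & p_eur < p_sig & p_eas < p_sig,
    label := "STRINGENT"]
  x[!is.na(p_eur) & p_eur < p_sig & (is.na(p_eas) | p_eas > p_rep),
    label := "EUR_SPECIFIC"]
  x[!is.na(p_eas) & p_eas < p_sig & (is.na(p_eur) | p_eur > p_rep),
    label := "EAS_SPECIFIC"]
  x[, excl_same_lead := label %in% c("EUR_SPECIFIC", "EAS_SPECIFIC") &
      !is.na(lead_eur) & !is.na(lead_eas) & lead_eur == lead_eas]
  x[, excl_alt_cohort := FALSE]
  if (!is.null(cohort_stats) && length(cohort_stats)) {
    if (is.null(cohort_pops) || length(cohort_pops) != length(cohort_stats))
      stop("cohort_pops must label every cohort_stats entry")
    minp <- data.table::rbindlist(lapply(seq_along(cohort_stats), function(i)
      data.table::as.data.table(cohort_stats[[i]])[, list(
        minp = min(p), pop = cohort_pops[i]), by = "probe"]))
    alt_eur <- minp[pop == "EAS" & minp < p_sig, unique(probe)]
    alt_eas <- minp[pop == "EUR" & minp < p_sig, unique(probe)]
    x[label == "EUR_SPECIFIC" & probe %in% alt_eur, excl_alt_cohort := TRUE]
    x[label == "EAS_SPECIFIC" & probe %in% alt_eas, excl_alt_cohort := TRUE]
  }
  x[(excl_same_lead | excl_alt_cohort), label := "OTHER"]
  x[]
}

#' Hierarchical sharing category for one stringent-set probe
#'
#' First matching rule wins: (1) identical lead SNP with matching
#' harmonized effect direction; (2) lead-lead r-squared above `r2_strong`
#' in either reference panel; (3) the leads' LD blocks (each built in its
#' own ancestry panel) intersect; (4) the EAS lead SNP is among the EUR
#' conditionally independent signals; (5) the EAS lead's block intersects
#' the block of any conditional signal; otherwise `UNEXPLAINED`. Panels in
#' which a lead is monomorphic contribute nothing to the LD rules.
#'
#' @param lead_eur,lead_eas One-row lead records (snp, beta) per ancestry,
#'   alleles harmonized.
#' @param panels Named list of [genotype_set()]s: `EUR`, `EAS`.
#' @param cojo_snps Character vector of EUR conditionally independent SNP
#'   ids for this probe (may be empty).
#' @param candidates Candidate SNP ids for block construction (typically
#'   the probe's cis-window SNPs).
#' @param r2_strong Strong-LD threshold (default 0.8).
#' @return A factor level from the sharing hierarchy.
#' @export
classify_shared_mqtl <- function(lead_eur, lead_eas, panels,
                                 cojo_snps = character(),
                                 candidates = NULL, r2_strong = 0.8) {
  se_ <- lead_eur$snp; sa <- lead_eas$snp
  if (se_ == sa && sign(lead_eur$beta) == sign(lead_eas$beta))
    return(factor("SAME_LEAD_SAME_DIRECTION", levels = SHARING_LEVELS))
  lead_r2 <- suppressWarnings(vapply(panels, function(p) {
    if (!all(c(se_, sa) %in% p$variants$snp)) return(NA_real_)
    ld_r2(p, se_, sa)
  }, numeric(1)))
  if (any(!is.na(lead_r2) & lead_r2 > r2_strong))
    return(factor("STRONG_LD", levels = SHARING_LEVELS))
  block_of <- function(snp, pop) {
    p <- panels[[pop]]
    if (!(snp %in% p$variants$snp)) return(NULL)
    if (stats::sd(p$dosage[, snp]) == 0) return(NULL)
    ld_block(p, snp, candidates = candidates, r2_min = r2_strong,
             panel = pop)
  }
  b_eur <- block_of(se_, "EUR")
  b_eas <- block_of(sa, "EAS")
  if (!is.null(b_eur) && !is.null(b_eas) && blocks_overlap(b_eur, b_eas))
    return(factor("BLOCK_OVERLAP", levels = SHARING_LEVELS))
  if (length(cojo_snps)) {
    if (sa %in% cojo_snps)
      return(factor("COJO_SAME_SNP", levels = SHARING_LEVELS))
    if (!is.null(b_eas)) {
      for (cs in cojo_snps) {
        b_c <- block_of(cs, "EUR")
        if (!is.null(b_c) && blocks_overlap(b_eas, b_c))
          return(factor("COJO_BLOCK_OVERLAP", levels = SHARING_LEVELS))
      }
    }
  }
  factor("UNEXPLAINED", levels = SHARING_LEVELS)
}

#' Tally sharing categories
#'
#' Counts per category with percentages of the stringent-set size rounded
#' to one decimal; "putative shared" totals everything except
#' `UNEXPLAINED`.
#'
#' @param categories Factor/character vector of per-probe categories, or a
#'   named count vector (names from the sharing hierarchy).
#' @param total Stringent-set size (default: length/sum of input).
#' @return List with `table` (`data.table`: category, n, pct), `shared_n`,
#'   `shared_pct`, `total`.
#' @export
tally_categories <- function(categories, total = NULL) {
  if (is.numeric(categories) && !is.null(names(categories))) {
    counts <- categories
  } else {
    counts <- table(factor(categories, levels = SHARING_LEVELS))
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  lev <- intersect(SHARING_LEVELS, names(counts))
  counts <- counts[lev]
  if (is.null(total)) total <- sum(counts)
  pct <- round(100 * counts / total, 1)
  shared <- sum(counts[setdiff(lev, "UNEXPLAINED")])
  list(table = data.table::data.table(category = lev, n = as.numeric(counts),
                                      pct = as.numeric(pct)),
       shared_n = shared,
       shared_pct = round(100 * shared / total, 1),
       total = total)
}

#' Headline set-report percentages
#'
#' Percentages (one decimal) describing the split of probes with a
#' significant mQTL into shared and ancestry-specific sets.
#'
#' @param n_any Probes significant in at least one ancestry.
#' @param n_stringent Probes stringently significant in both.
#' @param n_eur_specific,n_eas_specific Ancestry-specific set sizes.
#' @return Named list: pct_stringent, pct_specific, pct_eur_of_specific,
#'   pct_eas_of_specific, n_specific.
#' @export
set_report <- function(n_any, n_stringent, n_eur_specific, n_eas_specific) {
  n_spec <- n_eur_specific + n_eas_specific
  list(pct_stringent = round(100 * n_stringent / n_any, 1),
       pct_specific = round(100 * n_spec / n_any, 1),
       pct_eur_of_specific = round(100 * n_eur_specific / n_spec, 1),
       pct_eas_of_specific = round(100 * n_eas_specific / n_spec, 1),
       n_specific = n_spec)
}

#' Allele-frequency heterogeneity of ancestry-specific mQTLs
#'
#' For each ancestry-specific probe: the lead SNP's minor allele frequency
#' in the alternate-ancestry panel (rare flag below `rare_af`), and the
#' lead-vs-lead r-squared bucket — `incalculable` when the lead is
#' monomorphic or absent in the alternate-ancestry panel, else `weak`
#' (< r2_weak), `intermediate`, or `strong` (> r2_strong) using the larger
#' of the two panel values.
#'
#' @param sets Output of [define_sets()].
#' @param panels Named list of [genotype_set()]s: `EUR`, `EAS`.
#' @param rare_af Rare-frequency threshold (default 0.01).
#' @param r2_weak,r2_strong Bucket boundaries (defaults 0.2 / 0.8).
#' @return `data.table`: probe, label, alt_maf, rare, lead_r2, ld_bucket.
#' @export
af_heterogeneity <- function(sets, panels, rare_af = 0.01, r2_weak = 0.2,
                             r2_strong = 0.8) {
  s <- data.table::as.data.table(sets)
  s <- s[label %in% c("EUR_SPECIFIC", "EAS_SPECIFIC")]
  if (!nrow(s)) return(data.table::data.table())
  out <- vector("list", nrow(s))
  for (i in seq_len(nrow(s))) {
    lab <- s$label[i]
    lead <- if (lab == "EUR_SPECIFIC") s$lead_eur[i] else s$lead_eas[i]
    alt_pop <- if (lab == "EUR_SPECIFIC") "EAS" else "EUR"
    panel <- panels[[alt_pop]]
    alt_maf <- NA_real_
    mono_alt <- TRUE
    if (lead %in% panel$variants$snp) {
      af <- mean(panel$dosage[, lead]) / 2
      alt_maf <- min(af, 1 - af)
      mono_alt <- stats::sd(panel$dosage[, lead]) == 0
    }
    other_lead <- if (lab == "EUR_SPECIFIC") s$lead_eas[i] else s$lead_eur[i]
    r2s <- suppressWarnings(vapply(panels, function(p) {
      if (is.na(other_lead) ||
          !all(c(lead, other_lead) %in% p$variants$snp)) return(NA_real_)
      ld_r2(p, lead, other_lead)
    }, numeric(1)))
    # monomorphic in the alternate ancestry -> LD between leads incalculable
    r2 <- if (mono_alt || all(is.na(r2s))) NA_real_ else
      max(r2s, na.rm = TRUE)
    bucket <- if (is.na(r2)) "incalculable"
      else if (r2 < r2_weak) "weak"
      else if (r2 > r2_strong) "strong"
      else "intermediate"
    out[[i]] <- data.table::data.table(
      probe = s$probe[i], label = lab, alt_maf = alt_maf,
      rare = !is.na(alt_maf) & alt_maf < rare_af,
      lead_r2 = r2, ld_bucket = bucket)
  }
  data.table::rbindlist(out)
}
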