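# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

fix_cached <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

# medium one-chromosome model: 600 SNPs in 10-SNP blocks
fix_model <- function() {
  fix_cached("model", function()
    population_model(600, rep(10L, 60), rho_eur = 0.9, rho_eas = 0.9,
                     fst = 0.1, eas_block_shift = 5L, seed = 41L))
}

fix_afs <- function() {
  fix_cached("afs", function() sample_population_afs(fix_model()))
}

fix_panel <- function(pop = "EUR", n = 1000L, seed = 42L) {
  key <- paste0("panel_", pop, "_", n, "_", seed)
  fix_cached(key, function() {
    f <- if (pop == "EUR") fix_afs()$f_eur else fix_afs()$f_eas
    simulate_genotypes(fix_model(), f, n, seed, pop)
  })
}

# small complete study: 2 EUR + 1 EAS cohorts, 40 probes
fix_study <- function() {
  fix_cached("study", function()
    suppressWarnings(simulate_study(
      fix_model(),
      data.frame(name = c("eur1", "eur2", "eas1"),
                 pop = c("EUR", "EUR", "EAS"),
                 n = c(500L, 500L, 500L)),
      n_probes = 40L, window = 12000, rho_b = 0.9, prop_private = 0.2,
      n_ref = 400L, seed = 7L)))
}

# per-cohort INT-adjusted scans + meta for the small study
fix_scans <- function() {
  fix_cached("scans", function() {
    study <- fix_study()
    stats <- lapply(study$cohorts, function(co) {
      adj <- suppressWarnings(adjust_methylation(co$meth, co$covariates))
      adj <- t(apply(adj, 1L, rank_int))
      suppressWarnings(
        scan_cis(adj, co$genos, study$truth$probes,
                 window = study$truth$window))
    })
    pops <- vapply(study$cohorts, `[[`, "", "pop")
    meta <- list(EUR = meta_cohorts(stats[pops == "EUR"]),
                 EAS = meta_cohorts(stats[pops == "EAS"]))
    list(stats = stats, pops = pops, meta = meta,
         leads = lapply(meta, lead_snps))
  })
}

# genotype_set straight from hard-coded dosages
toy_genos <- function(dosage, pos = NULL, chrom = "1") {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_set(dosage, data.frame(
    snp = sprintf("s%02d", seq_len(m)), chrom = chrom, pos = pos,
    ref = "A", alt = "G", af = colMeans(dosage, na.rm = TRUE) / 2,
    info = 1.0))
}
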