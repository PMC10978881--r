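# SMR and HEIDI.

test_that("smr_test matches closed forms and the chi-square oracle", {
  # z_zx = 10, z_zy = 5 -> T = 100*25/125 = 20
  s <- smr_test(0.5, 0.05, 0.25, 0.05)
  expect_equal(s$t_smr, 20)
  expect_equal(s$p_smr, stats::pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(s$b_xy, 0.5)
  # null outcome: T = 0, p = 1
  s0 <- smr_test(0.5, 0.05, 0, 0.05)
  expect_equal(s0$t_smr, 0)
  expect_equal(s0$p_smr, 1)
  expect_equal(s0$b_xy, 0)
  # equal z: T = z^2 / 2
  se_ <- smr_test(0.4, 0.05, 0.4, 0.05)
  expect_equal(se_$t_smr, (0.4 / 0.05)^2 / 2)
  # unit-rescaling invariance of T
  s1 <- smr_test(0.5, 0.05, 0.25, 0.05)
  s2 <- smr_test(0.5, 0.05, 0.25 * 7, 0.05 * 7)
  expect_equal(s1$t_smr, s2$t_smr, tolerance = 1e-12)
  # sign rule
  sn <- smr_test(-0.5, 0.05, 0.25, 0.05)
  expect_equal(sign(sn$b_xy), -1)
  expect_warning(smr_test(0.05, 0.05, 0.2, 0.05), "weak instrument")
})

test_that("heidi_test eligibility rules and degenerate filters", {
  g <- fix_panel("EUR", 800L, seed = 101)
  v <- g$variants
  R <- ld_matrix(g, v$snp[1:20])
  zx <- data.table::data.table(snp = v$snp[1:20], beta = 0.5, se = 0.05)
  zy <- data.table::data.table(snp = v$snp[1:20], beta = 0.15, se = 0.05)
  # all non-top SNPs in near-perfect LD with top -> excluded by the upper
  # r2 bound -> p missing with reason
  Rp <- matrix(0.99, 5, 5); diag(Rp) <- 1
  dimnames(Rp) <- list(v$snp[1:5], v$snp[1:5])
  h <- heidi_test(zx[1:5], zy[1:5], Rp, v$snp[1])
  expect_true(is.na(h$p_heidi))
  expect_match(h$reason, "eligible")
  # missing top SNP
  h2 <- heidi_test(zx[2:5], zy[2:5], Rp, v$snp[1])
  expect_true(is.na(h2$p_heidi))
})

test_that("HEIDI is calibrated under a shared causal variant and powered "
          , {
  m <- fix_model()
  afs <- fix_afs()
  gx <- fix_panel("EUR", 2000L, seed = 82)
  gy <- simulate_genotypes(m, afs$f_eur, 2000, 102, "EUR", "out")
  gr <- fix_panel("EUR", 1000L, seed = 81)
  v <- gx$variants
  maf <- pmin(v$af, 1 - v$af)
  common <- which(maf >= 0.15)
  common <- common[common > 30 & common < nrow(v) - 30]
  set.seed(103)
  # shared causal variant: fully mediated trait -> rejection <= 3% at 0.01
  rej <- 0; nok <- 0
  for (i in 1:120) {
    ci <- sample(common, 1)
    yx <- gx$dosage[, ci] * 0.5 + rnorm(2000)
    yy <- gy$dosage[, ci] * 0.15 + rnorm(2000)
    idx <- cis_window(v$pos[ci], v, 12000)
    sx <- suppressWarnings(assoc_scan(yx, gx, idx, probe = "x"))
    sy <- suppressWarnings(assoc_scan(yy, gy, idx, probe = "x"))
    shared <- intersect(sx$snp, sy$snp)
    h <- heidi_test(sx[snp %in% shared], sy[snp %in% shared],
                    ld_matrix(gr, shared), lead_snp(sx)$snp)
    if (is.na(h$p_heidi)) next
    nok <- nok + 1
    rej <- rej + (h$p_heidi < 0.01)
  }
  expect_gt(nok, 80)
  expect_lte(rej / nok, 0.03)
  # linkage: distinct causal variants at moderate LD -> rejection >= 50%
  rej2 <- 0; nok2 <- 0
  for (i in 1:80) {
    repeat {
      c1 <- sample(common, 1)
      cand <- setdiff(intersect((c1 - 8):(c1 + 8), common), c1)
      r2s <- suppressWarnings(
        vapply(cand, function(cj) ld_r2(gr, c1, cj), numeric(1)))
      pick <- which(!is.na(r2s) & r2s > 0.2 & r2s < 0.45)
      if (length(pick)) { c2 <- cand[pick[1]]; break }
    }
    yx <- gx$dosage[, c1] * 0.5 + rnorm(2000)
    yy <- gy$dosage[, c2] * 0.3 + rnorm(2000)
    idx <- cis_window(v$pos[c1], v, 12000)
    sx <- suppressWarnings(assoc_scan(yx, gx, idx, probe = "x"))
    sy <- suppressWarnings(assoc_scan(yy, gy, idx, probe = "x"))
    shared <- intersect(sx$snp, sy$snp)
    h <- heidi_test(sx[snp %in% shared], sy[snp %in% shared],
                    ld_matrix(gr, shared), lead_snp(sx)$snp)
    if (is.na(h$p_heidi)) next
    nok2 <- nok2 + 1
    rej2 <- rej2 + (h$p_heidi < 0.01)
  }
  expect_gt(nok2, 50)
  expect_gte(rej2 / nok2, 0.5)
})

test_that("ancestry_specific_smr mediates, excludes, and skips correctly", {
  m <- fix_model()
  afs <- fix_afs()
  gx <- fix_panel("EUR", 2000L, seed = 82)
  gy <- simulate_genotypes(m, afs$f_eur, 4000, 104, "EUR", "gw")
  v <- gx$variants
  maf <- pmin(v$af, 1 - v$af)
  ci <- which(maf >= 0.2)[10]
  set.seed(105)
  b <- 0.5; cc <- 0.4
  yx <- gx$dosage[, ci] * b + rnorm(2000)
  meth_gy <- gy$dosage[, ci] * b + rnorm(4000)   # outcome cohort methylation
  yy <- meth_gy * cc + rnorm(4000)               # trait mediated by DNAm
  probes <- data.frame(probe = "cgX", chrom = "1", pos = v$pos[ci])
  idx <- cis_window(v$pos[ci], v, 12000)
  cis <- suppressWarnings(assoc_scan(yx, gx, idx, probe = "cgX"))
  gwas_eur <- suppressWarnings(assoc_scan(yy, gy, idx, probe = "trait"))
  gwas_eur$probe <- NULL
  gwas_null <- data.table::copy(gwas_eur)
  set.seed(106)
  gwas_null$p <- runif(nrow(gwas_null))  # no signal in the EAS GWAS
  sets <- data.table::data.table(
    probe = "cgX", label = "EUR_SPECIFIC",
    lead_eur = lead_snp(cis)$snp, lead_eas = NA_character_,
    p_eur = 1e-20, p_eas = 0.5,
    excl_same_lead = FALSE, excl_alt_cohort = FALSE)
  panels <- list(EUR = fix_panel("EUR", 1000L, seed = 81),
                 EAS = fix_panel("EAS", 400L, seed = 107))
  res <- suppressWarnings(ancestry_specific_smr(
    sets, meta_stats = list(EUR = cis, EAS = cis[0]),
    gwas = list(EUR = gwas_eur, EAS = gwas_null),
    panels = panels, probes = probes, window = 12000))
  expect_equal(nrow(res), 1)
  expect_false(res$excluded_alt_gwas)
  # mediated effect on the methylation-SD scale recovered within 2 se
  expect_lt(abs(res$b_xy - cc), 2 * res$se_xy)
  expect_lt(res$p_smr, 1e-7)
  # alternate-ancestry GWAS signal in the window -> excluded
  gwas_sig <- data.table::copy(gwas_null)
  gwas_sig$p[1] <- 1e-9
  res2 <- suppressWarnings(ancestry_specific_smr(
    sets, meta_stats = list(EUR = cis, EAS = cis[0]),
    gwas = list(EUR = gwas_eur, EAS = gwas_sig),
    panels = panels, probes = probes, window = 12000))
  expect_true(res2$excluded_alt_gwas)
  expect_false(res2$significant)
  # instrument absent from the GWAS -> skipped with reason
  gwas_miss <- gwas_eur[snp != sets$lead_eur]
  res3 <- suppressWarnings(ancestry_specific_smr(
    sets, meta_stats = list(EUR = cis, EAS = cis[0]),
    gwas = list(EUR = gwas_miss, EAS = gwas_null),
    panels = panels, probes = probes, window = 12000))
  expect_match(res3$reason, "absent")
})

test_that("null traits give approximately uniform SMR p-values", {
  gx <- fix_panel("EUR", 2000L, seed = 82)
  v <- gx$variants
  maf <- pmin(v$af, 1 - v$af)
  common <- which(maf >= 0.15)
  set.seed(108)
  ps <- vapply(1:300, function(i) {
    ci <- sample(common, 1)
    yx <- gx$dosage[, ci] * 0.5 + rnorm(2000)
    yy <- rnorm(2000)                       # trait independent of the locus
    sx <- suppressWarnings(assoc_scan(yx, gx, ci, probe = "x"))
    sy <- suppressWarnings(assoc_scan(yy, gx, ci, probe = "x"))
    suppressWarnings(smr_test(sx$beta, sx$se, sy$beta, sy$se)$p_smr)
  }, numeric(1))
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
})
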