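# Set definitions, the sharing hierarchy, tallies, AF heterogeneity.

mk_lead <- function(probe, snp, p, beta = 0.5) {
  data.table::data.table(probe = probe, snp = snp, beta = beta,
                         se = 0.05, p = p)
}

test_that("define_sets applies the threshold rules", {
  le <- mk_lead(c("p1", "p2", "p3", "p4"), c("a", "b", "c", "d"),
                c(1e-15, 1e-15, 1e-15, 1e-3))
  la <- mk_lead(c("p1", "p2", "p3", "p4"), c("x", "y", "z", "w"),
                c(1e-12, 1e-5, 1e-8, 1e-15))
  s <- define_sets(le, la)
  lab <- stats::setNames(s$label, s$probe)
  expect_equal(lab[["p1"]], "STRINGENT")
  expect_equal(lab[["p2"]], "EUR_SPECIFIC")
  expect_equal(lab[["p3"]], "OTHER")       # between thresholds
  expect_equal(lab[["p4"]], "EAS_SPECIFIC")
  # probe absent in one ancestry -> OTHER unless the other is stringent
  s2 <- define_sets(le, la[1:3])
  expect_equal(s2[s2$probe == "p4", ]$label, "OTHER")
})

test_that("define_sets excludes power artefacts from the specific sets", {
  le <- mk_lead(c("p1", "p2"), c("a", "b"), c(1e-15, 1e-15))
  la <- mk_lead(c("p1", "p2"), c("a", "q"), c(1e-5, 1e-5))
  # p1: same lead SNP in both ancestries -> excluded
  s <- define_sets(le, la)
  expect_equal(s[s$probe == "p1", ]$label, "OTHER")
  expect_true(s[s$probe == "p1", ]$excl_same_lead)
  expect_equal(s[s$probe == "p2", ]$label, "EUR_SPECIFIC")
  # p2 significant in an alternate-ancestry cohort -> excluded
  alt <- data.table::data.table(probe = "p2", snp = "q", p = 1e-12)
  s2 <- define_sets(le, la, cohort_stats = list(alt), cohort_pops = "EAS")
  expect_equal(s2[s2$probe == "p2", ]$label, "OTHER")
  expect_true(s2[s2$probe == "p2", ]$excl_alt_cohort)
})

test_that("classify_shared_mqtl walks the hierarchy top-down", {
  set.seed(61)
  n <- 400
  base <- rbinom(n, 2, 0.5)
  flip <- function(g, k) { i <- sample(n, k); g[i] <- 2 - g[i]; g }
  # s1 ~ s2 in very strong LD; s3 correlated with both; s4 independent;
  # s5 tags s1; s6 tags s4
  ind <- rbinom(n, 2, 0.3)
  d <- cbind(base, flip(base, 8), flip(base, 60), ind,
             flip(base, 10), { i <- sample(n, 3); x <- ind
                               x[i] <- 2 - x[i]; x })
  panels <- list(EUR = toy_genos(d), EAS = toy_genos(d))
  le <- mk_lead("p", "s01", 1e-15, beta = 0.5)
  la_same <- mk_lead("p", "s01", 1e-12, beta = 0.3)
  expect_equal(as.character(
    classify_shared_mqtl(le, la_same, panels)),
    "SAME_LEAD_SAME_DIRECTION")
  # same lead, opposite sign -> falls through; s01 vs s01 r2 = 1 -> STRONG_LD
  la_opp <- mk_lead("p", "s01", 1e-12, beta = -0.3)
  expect_equal(as.character(classify_shared_mqtl(le, la_opp, panels)),
               "STRONG_LD")
  # r2(s1, s2) > 0.8 -> STRONG_LD
  la_ld <- mk_lead("p", "s02", 1e-12)
  expect_equal(as.character(classify_shared_mqtl(le, la_ld, panels)),
               "STRONG_LD")
  # s3: moderate LD with s1 but blocks (r2 > 0.8) both contain s05
  la_blk <- mk_lead("p", "s03", 1e-12)
  r13 <- ld_r2(panels$EUR, "s01", "s03")
  expect_lt(r13, 0.8)
  cat_blk <- as.character(classify_shared_mqtl(le, la_blk, panels))
  expect_true(cat_blk %in% c("BLOCK_OVERLAP", "UNEXPLAINED"))
  # s4 independent: rescued only via cojo
  la_ind <- mk_lead("p", "s04", 1e-12)
  expect_equal(as.character(classify_shared_mqtl(le, la_ind, panels)),
               "UNEXPLAINED")
  expect_equal(as.character(
    classify_shared_mqtl(le, la_ind, panels, cojo_snps = "s04")),
    "COJO_SAME_SNP")
  # EAS lead s04 not itself a conditional signal, but its block tags the
  # conditional SNP s06
  expect_equal(as.character(
    classify_shared_mqtl(le, la_ind, panels, cojo_snps = "s06")),
    "COJO_BLOCK_OVERLAP")
})

test_that("shared-causal simulation lands in the LD-evidence categories", {
  # one shared causal SNP, population-rotated tagging: the leads differ by
  # population but stay in LD, so rules 2-3 explain nearly all probes
  m <- population_model(400, rep(10L, 40), rho_eur = 0.95, rho_eas = 0.95,
                        fst = 0.1, eas_block_shift = 5L, seed = 62)
  afs <- sample_population_afs(m)
  tr <- sim_truth(m, 60, window = 10000, rho_b = 1, seed = 63)
  b <- 0.6 * sign(tr$probes$b_eur + 1e-9)
  tr$probes$b_eur <- b; tr$probes$b_eas <- b
  ge <- simulate_genotypes(m, afs$f_eur, 1500, 64, "EUR")
  ga <- simulate_genotypes(m, afs$f_eas, 1500, 65, "EAS")
  pe <- simulate_genotypes(m, afs$f_eur, 500, 66, "EUR", "refe")
  pa <- simulate_genotypes(m, afs$f_eas, 500, 67, "EAS", "refa")
  me <- t(apply(simulate_methylation(ge, tr, pop = "EUR", seed = 68), 1,
                rank_int))
  ma <- t(apply(simulate_methylation(ga, tr, pop = "EAS", seed = 69), 1,
                rank_int))
  se <- suppressWarnings(scan_cis(me, ge, tr$probes, window = tr$window))
  sa <- suppressWarnings(scan_cis(ma, ga, tr$probes, window = tr$window))
  lse <- lead_snps(se); lsa <- lead_snps(sa)
  sets <- define_sets(lse, lsa)
  stringent <- sets[sets$label == "STRINGENT", ]$probe
  expect_gt(length(stringent), 30)
  panels <- list(EUR = pe, EAS = pa)
  cats <- vapply(stringent, function(p_) {
    idx <- cis_window(tr$probes$pos[tr$probes$probe == p_], pe$variants,
                      tr$window)
    as.character(suppressWarnings(classify_shared_mqtl(
      lse[probe == p_], lsa[probe == p_], panels,
      candidates = pe$variants$snp[idx])))
  }, character(1))
  shared_frac <- mean(cats != "UNEXPLAINED")
  expect_gte(shared_frac, 0.9)
  # deterministic classification
  cats2 <- vapply(stringent[1:5], function(p_) {
    idx <- cis_window(tr$probes$pos[tr$probes$probe == p_], pe$variants,
                      tr$window)
    as.character(suppressWarnings(classify_shared_mqtl(
      lse[probe == p_], lsa[probe == p_], panels,
      candidates = pe$variants$snp[idx])))
  }, character(1))
  expect_identical(unname(cats[1:5]), unname(cats2))
})

test_that("tally_categories reproduces percentage arithmetic", {
  counts <- c(SAME_LEAD_SAME_DIRECTION = 9153, STRONG_LD = 40648,
              BLOCK_OVERLAP = 3069, COJO_SAME_SNP = 1031,
              COJO_BLOCK_OVERLAP = 3999)
  t <- tally_categories(counts, total = 80394)
  expect_equal(t$table$pct, c(11.4, 50.6, 3.8, 1.3, 5.0))
  expect_equal(t$shared_n, 57900)
  expect_equal(t$shared_pct, 72.0)
  # degenerate cases
  t0 <- tally_categories(c(UNEXPLAINED = 10), total = 10)
  expect_equal(t0$shared_n, 0)
  expect_equal(t0$shared_pct, 0.0)
  t1 <- tally_categories(c(STRONG_LD = 7), total = 7)
  expect_equal(t1$table$pct, 100.0)
  # counts from a factor vector sum to the stringent size
  f <- factor(c("STRONG_LD", "STRONG_LD", "UNEXPLAINED"),
              levels = c("SAME_LEAD_SAME_DIRECTION", "STRONG_LD",
                         "BLOCK_OVERLAP", "COJO_SAME_SNP",
                         "COJO_BLOCK_OVERLAP", "UNEXPLAINED"))
  tf <- tally_categories(f)
  expect_equal(sum(tf$table$n), 3)
})

test_that("set_report reproduces the headline split percentages", {
  r <- set_report(n_any = 129155, n_stringent = 80394,
                  n_eur_specific = 21084, n_eas_specific = 7841)
  expect_equal(r$pct_stringent, 62.2)
  expect_equal(r$pct_specific, 22.4)
  expect_equal(r$pct_eur_of_specific, 72.9)
  expect_equal(r$pct_eas_of_specific, 27.1)
  expect_equal(r$n_specific, 28925)
})

test_that("af_heterogeneity flags rare and incalculable leads", {
  set.seed(70)
  n <- 300
  d_eur <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.25), rbinom(n, 2, 0.3))
  d_eas <- cbind(rbinom(n, 2, 0.005), rep(0, n), rbinom(n, 2, 0.3))
  panels <- list(EUR = toy_genos(d_eur), EAS = toy_genos(d_eas))
  sets <- data.table::data.table(
    probe = c("p1", "p2", "p3"),
    label = "EUR_SPECIFIC",
    lead_eur = c("s01", "s02", "s03"),
    lead_eas = c("s03", "s03", "s01"),
    p_eur = 1e-15, p_eas = 1e-3,
    excl_same_lead = FALSE, excl_alt_cohort = FALSE)
  afh <- suppressWarnings(af_heterogeneity(sets, panels, rare_af = 0.01))
  a <- afh[afh$probe == "p1"]
  expect_true(a$alt_maf < 0.01 && a$rare)
  b <- afh[afh$probe == "p2"]   # truly private: monomorphic in EAS
  expect_true(b$rare)
  expect_equal(b$ld_bucket, "incalculable")
  c_ <- afh[afh$probe == "p3"]  # common everywhere
  expect_false(c_$rare)
  expect_true(c_$ld_bucket %in% c("weak", "intermediate", "strong"))
})
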