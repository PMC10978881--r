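# ABF fine mapping, credible sets, outlier filter, sample-size experiment.

test_that("log_abf matches the quadrature oracle and its limits", {
  # oracle: numeric integration of the normal-normal marginal likelihood
  # ratio against the point-null likelihood
  abf_oracle <- function(beta, se, W) {
    num <- stats::integrate(function(b)
      stats::dnorm(beta, b, se) * stats::dnorm(b, 0, sqrt(W)),
      -Inf, Inf, rel.tol = 1e-12)$value
    log(num / stats::dnorm(beta, 0, se))
  }
  cases <- list(c(0.5, 0.05, 0.04), c(0.1, 0.08, 0.2), c(-0.3, 0.02, 0.01))
  for (cs in cases)
    expect_equal(log_abf(cs[1], cs[2], cs[3]),
                 abf_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-8)
  # beta = 0: evidence against the causal model
  expect_lt(log_abf(0, 0.1, 0.05), 0)
  expect_equal(log_abf(0, 0.1, 0.05), 0.5 * log(0.01 / 0.06),
               tolerance = 1e-12)
  # W -> 0 collapses the prior onto the null
  expect_equal(log_abf(0.5, 0.05, 1e-12), 0, tolerance = 1e-6)
  expect_error(log_abf(1, 0, 0.1), "positive")
})

test_that("pips_single normalizes and concentrates on dominant signals", {
  st <- data.table::data.table(
    snp = sprintf("s%02d", 1:10),
    beta = c(1.5, rep(0.001, 9)), se = 0.05)
  p <- pips_single(st)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_gt(p[["s01"]], 0.999)
  # identical stats -> uniform
  stu <- data.table::data.table(snp = sprintf("s%02d", 1:8),
                                beta = 0.2, se = 0.1)
  pu <- pips_single(stu)
  expect_equal(unname(pu), rep(1 / 8, 8), tolerance = 1e-12)
  expect_error(pips_single(stu[0]), "empty")
})

test_that("credible_set takes the smallest sufficient prefix", {
  cs <- credible_set(stats::setNames(c(0.96, 0.04), c("a", "b")))
  expect_equal(cs$size, 1)
  cs2 <- credible_set(stats::setNames(rep(1 / 100, 100),
                                      sprintf("s%03d", 1:100)))
  expect_equal(cs2$size, 95)
  cs3 <- credible_set(stats::setNames(c(0.5, 0.3, 0.15, 0.05),
                                      letters[1:4]))
  expect_equal(cs3$size, 3)
  expect_equal(cs3$members$snp, c("a", "b", "c"))
  # minimality: dropping the last member undercuts the target
  expect_lt(sum(cs3$members$pip[-3]), 0.95)
  expect_error(credible_set(c(0.5, 0.2)), "normalized")
})

test_that("pips_cross reduces to single-ancestry and accumulates evidence", {
  st_e <- data.table::data.table(snp = sprintf("s%02d", 1:6),
                                 beta = c(0.8, 0.1, 0, 0, 0, 0.05),
                                 se = 0.05)
  # uninformative partner (no rows) -> cross equals single
  st_a0 <- st_e[0]
  px <- pips_cross(st_e, st_a0)
  ps <- pips_single(st_e)
  expect_equal(unname(px[names(ps)]), unname(ps), tolerance = 1e-12)
  # concordant strong signal -> PIP at the shared SNP not decreased
  st_a <- data.table::data.table(snp = sprintf("s%02d", 1:6),
                                 beta = c(0.7, 0.05, 0, 0, 0, 0),
                                 se = 0.06)
  px2 <- pips_cross(st_e, st_a)
  expect_gte(px2[["s01"]], ps[["s01"]] - 1e-12)
  # SNP missing in one population contributes BF = 1 there
  st_a_miss <- st_a[snp != "s01"]
  px3 <- pips_cross(st_e, st_a_miss)
  expect_true("s01" %in% names(px3))
  expect_equal(sum(px3), 1, tolerance = 1e-12)
})

test_that("filter_outlier_sets excludes only gross outliers", {
  sz <- data.table::data.table(
    probe = paste0("p", 1:5), mode = "EUR", size = c(2, 2, 2, 2, 50))
  f <- filter_outlier_sets(sz)
  expect_equal(f$excluded$probe, "p5")
  expect_setequal(f$keep, paste0("p", 1:4))
  # degenerate IQR: equal sizes all retained (strict inequality)
  sz2 <- data.table::data.table(probe = paste0("p", 1:6), mode = "EUR",
                                size = 3)
  f2 <- filter_outlier_sets(sz2)
  expect_equal(nrow(f2$excluded), 0)
  expect_error(filter_outlier_sets(sz[1:3]), "at least 4")
})

test_that("dedupe_leads keeps the best probe per lead SNP and masks regions", {
  l <- data.table::data.table(
    probe = c("p1", "p2", "p3"), snp = c("a", "a", "b"),
    p = c(1e-20, 1e-10, 1e-15), chrom = "1", pos = c(100, 100, 5000))
  d <- dedupe_leads(l)
  expect_setequal(d$probe, c("p1", "p3"))
  d2 <- dedupe_leads(l, mask = data.frame(chrom = "1", start = 4000,
                                          end = 6000))
  expect_setequal(d2$probe, "p1")
})

test_that("cross-ancestry sets are smaller than single-ancestry sets "
          , {
  m <- population_model(800, rep(10L, 80), rho_eur = 0.95, rho_eas = 0.95,
                        fst = 0.15, eas_block_shift = 5L, seed = 91)
  afs <- sample_population_afs(m)
  tr <- sim_truth(m, 120, window = 12000, rho_b = 1, seed = 92)
  b <- 0.3 * sign(tr$probes$b_eur + 1e-9)
  tr$probes$b_eur <- b; tr$probes$b_eas <- b
  ge <- simulate_genotypes(m, afs$f_eur, 1000, 93, "EUR")
  ga <- simulate_genotypes(m, afs$f_eas, 1000, 94, "EAS")
  me <- t(apply(simulate_methylation(ge, tr, pop = "EUR", seed = 95), 1,
                rank_int))
  ma <- t(apply(simulate_methylation(ga, tr, pop = "EAS", seed = 96), 1,
                rank_int))
  se <- suppressWarnings(scan_cis(me, ge, tr$probes, window = tr$window))
  sa <- suppressWarnings(scan_cis(ma, ga, tr$probes, window = tr$window))
  sz <- vapply(tr$probes$probe, function(p_) {
    e <- se[probe == p_]; a <- sa[probe == p_]
    c(credible_set(pips_single(e), pos = e$pos)$size,
      credible_set(pips_single(a), pos = a$pos)$size,
      credible_set(pips_cross(e, a))$size)
  }, numeric(3))
  expect_lt(mean(sz[3, ]), mean(sz[1, ]))
  expect_lt(mean(sz[3, ]), mean(sz[2, ]))
})

test_that("sample_size_experiment shrinks sets with n and refuses tiny n", {
  m <- population_model(400, rep(10L, 40), rho_eur = 0.95, rho_eas = 0.95,
                        fst = 0.15, eas_block_shift = 5L, seed = 97)
  afs <- sample_population_afs(m)
  tr <- sim_truth(m, 60, window = 12000, rho_b = 1, seed = 98)
  b <- 0.3 * sign(tr$probes$b_eur + 1e-9)
  tr$probes$b_eur <- b; tr$probes$b_eas <- b
  tab <- suppressWarnings(
    sample_size_experiment(m, afs, tr, n_grid = c(400, 800, 1600),
                           n_eas = 400L, seed = 99))
  eur <- tab[tab$mode == "EUR", ]
  # non-increasing mean size along the grid (1 inversion tolerated)
  expect_lte(sum(diff(eur$mean_size) > 0), 1)
  # an EAS cohort of 400 beats 400 extra EUR samples (rotated LD blocks)
  cross_400 <- tab[tab$mode == "CROSS" & tab$n == 400, ]$mean_size
  eur_800 <- eur[eur$n == 800, ]$mean_size
  expect_lt(cross_400, eur_800)
  expect_error(sample_size_experiment(m, afs, tr, n_grid = c(30, 100)),
               "refused")
  expect_error(sample_size_experiment(m, afs, tr, n_grid = c(800, 400)),
               "ascending")
})
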