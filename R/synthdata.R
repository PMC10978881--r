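#' Two-population genotype/methylation simulator
#'
#' The simulator provides a stated world in which every downstream stage of
#' the cross-ancestry mQTL pipeline can be tested with known ground truth:
#' two populations ("EUR", "EAS") diverge in allele frequency under a
#' Balding-Nichols model, carry population-specific LD-block structure, and
#' share (or not) causal effects on methylation probes.
#'
#' @name synthdata
NULL

#' Construct a two-population genotype model
#'
#' Describes a single synthetic chromosome: SNP count and spacing, LD-block
#' partition, per-population within-block LD decay, and the Balding-Nichols
#' divergence parameter Fst.
#'
#' @param n_snps Number of SNPs.
#' @param block_lengths Integer vector of LD-block lengths; must sum to
#'   `n_snps`. Defaults to blocks of 10 SNPs.
#' @param rho_eur,rho_eas Within-block latent AR(1) correlation per
#'   population, in `[0, 1)`. Adjacent SNPs in a block have latent
#'   correlation `rho`, SNPs `k` apart `rho^k`.
#' @param fst Balding-Nichols divergence parameter, in (0, 1).
#' @param ancestral_af_range Interval within (0,1) from which ancestral
#'   allele frequencies are drawn uniformly.
#' @param spacing_bp Base-pair distance between adjacent SNPs.
#' @param eas_block_shift Number of SNPs by which the EAS block boundaries
#'   are rotated relative to EUR. A non-zero shift creates
#'   population-specific tagging: the same causal SNP sits in different
#'   blocks in the two populations.
#' @param seed Integer seed controlling allele-frequency draws.
#' @return An object of class `population_model`.
#' @export
population_model <- function(n_snps,
                             block_lengths = NULL,
                             rho_eur = 0.9,
                             rho_eas = 0.9,
                             fst = 0.1,
                             ancestral_af_range = c(0.05, 0.95),
                             spacing_bp = 1000L,
                             eas_block_shift = 0L,
                             seed = 1L) {
  n_snps <- as.integer(n_snps)
  if (is.null(block_lengths)) {
    k <- n_snps %/% 10L
    block_lengths <- rep(10L, k)
    if (n_snps %% 10L) block_lengths <- c(block_lengths, n_snps %% 10L)
  }
  block_lengths <- as.integer(block_lengths)
  if (sum(block_lengths) != n_snps)
    stop("sum(block_lengths) must equal n_snps")
  if (rho_eur < 0 || rho_eur >= 1 || rho_eas < 0 || rho_eas >= 1)
    stop("rho parameters must lie in [0, 1)")
  if (fst <= 0 || fst >= 1)
    stop("fst must lie in (0, 1)")
  if (length(ancestral_af_range) != 2 ||
      ancestral_af_range[1] <= 0 || ancestral_af_range[2] >= 1 ||
      ancestral_af_range[1] > ancestral_af_range[2])
    stop("ancestral_af_range must be an interval within (0, 1)")
  structure(
    list(n_snps = n_snps, block_lengths = block_lengths,
         rho_eur = rho_eur, rho_eas = rho_eas, fst = fst,
         ancestral_af_range = ancestral_af_range,
         spacing_bp = as.integer(spacing_bp),
         eas_block_shift = as.integer(eas_block_shift),
         seed = as.integer(seed)),
    class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("population_model:", x$n_snps, "SNPs in", length(x$block_lengths),
      "LD blocks; rho_EUR =", x$rho_eur, "rho_EAS =", x$rho_eas,
      "Fst =", x$fst, "\n")
  invisible(x)
}

#' LD-block membership per SNP
#'
#' EAS block boundaries are the EUR boundaries rotated by
#' `eas_block_shift` SNPs, then relabelled so each contiguous run forms a
#' block.
#'
#' @param model A [population_model()].
#' @param pop `"EUR"` or `"EAS"`.
#' @return Integer block id per SNP.
#' @export
block_ids <- function(model, pop = c("EUR", "EAS")) {
  pop <- match.arg(pop)
  ids <- rep(seq_along(model$block_lengths), model$block_lengths)
  if (pop == "EAS" && model$eas_block_shift != 0L) {
    shift <- model$eas_block_shift %% model$n_snps
    ids <- ids[((seq_len(model$n_snps) - 1L + shift) %% model$n_snps) + 1L]
    # after rotation, relabel runs so each contiguous run is one block
    ids <- cumsum(c(1L, diff(ids) != 0L))
  }
  ids
}

#' Base-pair positions of the model's SNPs
#'
#' @param model A [population_model()].
#' @return Integer position vector.
#' @export
variant_positions <- function(model) seq_len(model$n_snps) * model$spacing_bp

#' Sample diverged population allele frequencies
#'
#' Draws an ancestral frequency `f` uniformly on the model's range and, for
#' each population, an allele frequency from the Balding-Nichols Beta
#' distribution `Beta(f(1-F)/F, (1-f)(1-F)/F)` with `F = fst`, so that
#' `E[f_pop] = f` and `Var[f_pop] = F f(1-f)`.
#'
#' @param model A [population_model()].
#' @return A `data.frame` with columns `f_anc`, `f_eur`, `f_eas`.
#' @export
sample_population_afs <- function(model) {
  if (!inherits(model, "population_model")) stop("need a population_model")
  F <- model$fst
  set.seed(model$seed)
  f <- stats::runif(model$n_snps, model$ancestral_af_range[1],
                    model$ancestral_af_range[2])
  a <- f * (1 - F) / F
  b <- (1 - f) * (1 - F) / F
  data.frame(f_anc = f,
             f_eur = stats::rbeta(model$n_snps, a, b),
             f_eas = stats::rbeta(model$n_snps, a, b))
}

#' A genotype panel with its variant table
#'
#' @param dosage Numeric matrix, individuals in rows, SNPs in columns;
#'   entries in `{0, 1, 2}` or `NA`.
#' @param variants `data.frame` with columns `snp`, `chrom`, `pos`, `ref`,
#'   `alt`, `af`, `info` aligned with the dosage columns.
#' @return An object of class `genotype_set`.
#' @export
genotype_set <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), ncol(dosage) == nrow(variants))
  need <- c("snp", "chrom", "pos", "ref", "alt", "af", "info")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  colnames(dosage) <- variants$snp
  structure(list(dosage = dosage, variants = as.data.frame(variants)),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "SNPs\n")
  invisible(x)
}

#' Simulate genotypes with block-wise LD
#'
#' Haplotypes arise from a latent Gaussian AR(1) process restarted at each
#' LD-block boundary: within a block the latent correlation between SNPs
#' `i` and `j` is `rho^|i-j|`; across blocks it is zero. A haplotype carries
#' the alternate allele at SNP `j` when its latent value falls below the
#' `f_j` quantile, so marginal allele frequencies match `afs` exactly in
#' expectation. Genotype dosage is the sum of two independent haplotypes.
#'
#' @param model A [population_model()].
#' @param afs Per-SNP allele frequency vector (length `n_snps`), typically
#'   one column of [sample_population_afs()].
#' @param n_individuals Number of diploid individuals (>= 2).
#' @param seed Integer seed.
#' @param pop `"EUR"` or `"EAS"`; selects `rho` and block boundaries.
#' @param id_prefix Prefix for individual ids.
#' @return A [genotype_set()].
#' @export
simulate_genotypes <- function(model, afs, n_individuals, seed,
                               pop = c("EUR", "EAS"), id_prefix = NULL) {
  pop <- match.arg(pop)
  if (length(afs) != model$n_snps) stop("afs length must equal n_snps")
  n_individuals <- as.integer(n_individuals)
  if (n_individuals < 2) stop("n_individuals must be >= 2")
  rho <- if (pop == "EUR") model$rho_eur else model$rho_eas
  blocks <- block_ids(model, pop)
  m <- model$n_snps
  nh <- 2L * n_individuals
  set.seed(seed)
  Z <- matrix(0, nh, m)
  new_block <- c(TRUE, diff(blocks) != 0L)
  innov_sd <- sqrt(1 - rho^2)
  for (j in seq_len(m)) {
    e <- stats::rnorm(nh)
    Z[, j] <- if (new_block[j]) e else rho * Z[, j - 1L] + innov_sd * e
  }
  thr <- stats::qnorm(pmin(pmax(afs, 0), 1))
  hap <- sweep(Z, 2L, thr, `<`)
  dos <- hap[seq_len(n_individuals), , drop = FALSE] +
    hap[n_individuals + seq_len(n_individuals), , drop = FALSE]
  storage.mode(dos) <- "double"
  if (is.null(id_prefix)) id_prefix <- tolower(pop)
  rownames(dos) <- sprintf("%s_%04d", id_prefix, seq_len(n_individuals))
  variants <- data.frame(
    snp = sprintf("snp%05d", seq_len(m)),
    chrom = "1",
    pos = variant_positions(model),
    ref = "A", alt = "G",
    af = colMeans(dos) / 2,
    info = 1.0)
  genotype_set(dos, variants)
}

#' Ground-truth causal architecture for simulated probes
#'
#' Places `n_probes` methylation probes evenly along the simulated
#' chromosome, assigns each a causal SNP drawn uniformly from its cis
#' window, and draws per-probe causal effects `(b_EUR, b_EAS)` from a
#' bivariate normal with correlation `rho_b`. A fraction of probes can be
#' made population-private (effect set to zero in one randomly chosen
#' population), emulating ancestry-specific mQTLs.
#'
#' @param model A [population_model()].
#' @param n_probes Number of probes.
#' @param window Cis half-window in bp used to pick the causal SNP.
#' @param rho_b Correlation of causal effects across populations.
#' @param prop_private Fraction of probes with an effect in only one
#'   population.
#' @param b_sd SD of causal effects (phenotype-SD units per allele).
#' @param noise_sd Residual SD of the simulated phenotype.
#' @param gamma Optional named vector of covariate effects.
#' @param seed Integer seed.
#' @return A list of class `sim_truth` with elements `probes`
#'   (`data.frame`: probe, chrom, pos, causal_index, causal_snp, b_eur,
#'   b_eas, private), `rho_b`, `noise_sd`, `gamma`, `window`.
#' @export
sim_truth <- function(model, n_probes, window = 25000, rho_b = 0.9,
                      prop_private = 0, b_sd = 0.5, noise_sd = 1,
                      gamma = NULL, seed = 1L) {
  if (abs(rho_b) > 1) stop("rho_b must lie in [-1, 1]")
  pos <- variant_positions(model)
  span <- range(pos)
  set.seed(seed)
  ppos <- round(seq(span[1] + window, span[2] - window,
                    length.out = n_probes))
  causal_index <- integer(n_probes)
  for (i in seq_len(n_probes)) {
    cand <- which(abs(pos - ppos[i]) <= window)
    causal_index[i] <- if (length(cand) == 1L) cand else
      cand[sample.int(length(cand), 1L)]
  }
  # bivariate normal effect pairs with correlation rho_b
  z1 <- stats::rnorm(n_probes)
  z2 <- rho_b * z1 + sqrt(1 - rho_b^2) * stats::rnorm(n_probes)
  b_eur <- b_sd * z1
  b_eas <- b_sd * z2
  private <- rep(NA_character_, n_probes)
  if (prop_private > 0) {
    idx <- sample.int(n_probes, round(prop_private * n_probes))
    which_pop <- sample(c("EUR", "EAS"), length(idx), replace = TRUE)
    private[idx] <- which_pop
    b_eas[idx[which_pop == "EUR"]] <- 0
    b_eur[idx[which_pop == "EAS"]] <- 0
  }
  probes <- data.frame(
    probe = sprintf("cg%06d", seq_len(n_probes)),
    chrom = "1", pos = ppos,
    causal_index = causal_index,
    causal_snp = sprintf("snp%05d", causal_index),
    b_eur = b_eur, b_eas = b_eas, private = private)
  structure(list(probes = probes, rho_b = rho_b, noise_sd = noise_sd,
                 gamma = gamma, window = window),
            class = "sim_truth")
}

#' Simulate covariates for a cohort
#'
#' Sex, age (with its square available downstream), three cell-type
#' proportions summing to one, and a batch factor.
#'
#' @param n Number of individuals.
#' @param n_batches Number of batch levels.
#' @param seed Integer seed.
#' @return `data.frame` with columns sex, age, cell1..cell3, batch.
#' @export
make_covariates <- function(n, n_batches = 2L, seed = 1L) {
  set.seed(seed)
  g <- matrix(stats::rgamma(3L * n, shape = c(8, 4, 2)), nrow = n,
              byrow = TRUE)
  cells <- g / rowSums(g)
  data.frame(sex = stats::rbinom(n, 1L, 0.5),
             age = round(stats::runif(n, 20, 70), 1),
             cell1 = cells[, 1], cell2 = cells[, 2], cell3 = cells[, 3],
             batch = factor(sample.int(n_batches, n, replace = TRUE)))
}

#' Simulate methylation phenotypes
#'
#' For each probe, `y = dosage[, causal] * b_pop + X gamma + e`,
#' `e ~ N(0, noise_sd^2)`. With `beta_scale = TRUE` values are squashed to
#' the (0, 100) beta-value scale by `100 * plogis(y)`.
#'
#' @param genos A [genotype_set()] for one cohort.
#' @param truth A [sim_truth()].
#' @param covariates Optional `data.frame` (as [make_covariates()]); used
#'   only when `truth$gamma` names a subset of its numeric columns.
#' @param pop `"EUR"` or `"EAS"`: which causal effect column applies.
#' @param seed Integer seed.
#' @param beta_scale Emit (0, 100) beta-values instead of the latent scale.
#' @return Numeric matrix, probes in rows, individuals in columns.
#' @export
simulate_methylation <- function(genos, truth, covariates = NULL,
                                 pop = c("EUR", "EAS"), seed = 1L,
                                 beta_scale = FALSE) {
  pop <- match.arg(pop)
  pr <- truth$probes
  if (any(pr$causal_index > ncol(genos$dosage)))
    stop("causal index outside the genotype panel")
  n <- nrow(genos$dosage)
  b <- if (pop == "EUR") pr$b_eur else pr$b_eas
  set.seed(seed)
  cov_term <- 0
  if (!is.null(truth$gamma) && !is.null(covariates)) {
    cols <- intersect(names(truth$gamma), names(covariates))
    if (length(cols)) {
      X <- as.matrix(covariates[cols])
      if (nrow(X) != n) stop("covariate rows must match individuals")
      cov_term <- as.numeric(X %*% truth$gamma[cols])
    }
  }
  G <- genos$dosage[, pr$causal_index, drop = FALSE]
  E <- matrix(stats::rnorm(nrow(pr) * n, sd = truth$noise_sd), nrow(pr), n)
  Y <- t(G) * b + E + rep(cov_term, each = nrow(pr))
  if (beta_scale) Y <- 100 * stats::plogis(Y)
  rownames(Y) <- pr$probe
  colnames(Y) <- rownames(genos$dosage)
  Y
}

#' Inject missing dosages
#'
#' Sets a fraction of dosage entries to `NA`, to exercise QC filters and
#' mean imputation.
#'
#' @param genos A [genotype_set()].
#' @param rate Missingness rate in `[0, 1)`.
#' @param seed Integer seed.
#' @return The modified [genotype_set()].
#' @export
add_missingness <- function(genos, rate = 0, seed = 1L) {
  if (rate <= 0) return(genos)
  set.seed(seed)
  idx <- which(stats::runif(length(genos$dosage)) < rate)
  genos$dosage[idx] <- NA_real_
  genos
}

#' Simulate a complete two-ancestry study
#'
#' Builds the full stated world used by the pipeline and tests: diverged
#' allele frequencies, per-ancestry reference panels, per-cohort genotype
#' sets and methylation matrices with covariate structure, and the truth
#' object.
#'
#' @param model A [population_model()].
#' @param cohorts `data.frame` with columns `name`, `pop` ("EUR"/"EAS"),
#'   `n`.
#' @param truth A [sim_truth()]; if `NULL` one is generated with
#'   `n_probes`/`window`/`rho_b`/`prop_private`.
#' @param n_probes,window,rho_b,prop_private Passed to [sim_truth()] when
#'   `truth` is NULL.
#' @param n_ref Reference-panel size per ancestry.
#' @param missing_rate Dosage missingness rate per cohort.
#' @param seed Integer master seed; cohort seeds are derived from it.
#' @return List with `model`, `afs`, `truth`, `panels` (EUR/EAS
#'   [genotype_set()]s), `cohorts` (list per cohort: `genos`, `meth`,
#'   `covariates`, `pop`, `name`).
#' @export
simulate_study <- function(model, cohorts, truth = NULL, n_probes = 100L,
                           window = 25000, rho_b = 0.9, prop_private = 0,
                           n_ref = 500L, missing_rate = 0, seed = 1L) {
  model$seed <- as.integer(seed)
  afs <- sample_population_afs(model)
  if (is.null(truth))
    truth <- sim_truth(model, n_probes, window = window, rho_b = rho_b,
                       prop_private = prop_private,
                       gamma = c(age = 0.01, cell1 = 1), seed = seed + 1L)
  panels <- list(
    EUR = simulate_genotypes(model, afs$f_eur, n_ref, seed + 2L, "EUR",
                             id_prefix = "refeur"),
    EAS = simulate_genotypes(model, afs$f_eas, n_ref, seed + 3L, "EAS",
                             id_prefix = "refeas"))
  out <- vector("list", nrow(cohorts))
  names(out) <- cohorts$name
  for (i in seq_len(nrow(cohorts))) {
    pop <- cohorts$pop[i]
    s <- seed + 10L * i
    f <- if (pop == "EUR") afs$f_eur else afs$f_eas
    g <- simulate_genotypes(model, f, cohorts$n[i], s, pop,
                            id_prefix = cohorts$name[i])
    if (missing_rate > 0) g <- add_missingness(g, missing_rate, s + 1L)
    cv <- make_covariates(cohorts$n[i], seed = s + 2L)
    meth <- simulate_methylation(g, truth, covariates = cv, pop = pop,
                                 seed = s + 3L)
    out[[i]] <- list(name = cohorts$name[i], pop = pop, genos = g,
                     meth = meth, covariates = cv)
  }
  list(model = model, afs = afs, truth = truth, panels = panels,
       cohorts = out)
}
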