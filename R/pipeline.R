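# Pipeline orchestration: simulate -> QC -> scan -> meta -> r_b ->
# classify -> cojo -> finemap -> (simsize) -> smr, with a JSON config.

#' Default pipeline configuration
#'
#' All printed analysis thresholds live here, never hard-coded in stage
#' code: stringent significance 1e-10, replication 1e-6, strong/weak LD
#' r-squared 0.8/0.2, rare AF 0.01, credible-set coverage 0.95, cis window
#' 1 Mb (scaled for the synthetic chromosome via `window`).
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function(outdir = tempfile("mqtl_run_"), seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    cohorts = data.frame(name = c("eur1", "eur2", "eas1"),
                         pop = c("EUR", "EUR", "EAS"),
                         n = c(800L, 800L, 800L)),
    sim = list(n_snps = 600L, block_len = 10L, rho_eur = 0.9,
               rho_eas = 0.9, fst = 0.1, eas_block_shift = 5L,
               n_probes = 300L, window = 25000, rho_b = 0.9,
               prop_private = 0.2, n_ref = 400L, missing_rate = 0),
    thresholds = list(p_sig = 1e-10, p_rep = 1e-6, r2_strong = 0.8,
                      r2_weak = 0.2, rare_af = 0.01, coverage = 0.95,
                      cojo_p = 1e-10, cojo_r2_cap = 0.9,
                      p_smr_sig = 1e-7, p_heidi_min = 0.01,
                      gwas_sig = 5e-8),
    stages = list(simulate = TRUE, qc = TRUE, scan = TRUE, meta = TRUE,
                  rb = TRUE, classify = TRUE, cojo = TRUE, finemap = TRUE,
                  simsize = FALSE, smr = FALSE)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Fields present in the file override the defaults.
#'
#' @param path JSON config path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && !is.data.frame(cfg[[k]]) && is.list(user[[k]])) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else cfg[[k]] <- user[[k]]
  }
  cfg$cohorts <- as.data.frame(cfg$cohorts)
  cfg
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  # tiny FNV-1a over the serialized config; enough to fingerprint outputs
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}

write_stage_tsv <- function(x, path, config) {
  hdr <- sprintf("# seed=%d config=%s", config$seed, config_hash(config))
  writeLines(hdr, path)
  suppressWarnings(data.table::fwrite(x, path, sep = "\t", append = TRUE,
                                      col.names = TRUE, quote = FALSE))
  invisible(path)
}

#' Run the full synthetic-study pipeline
#'
#' Executes the enabled stages in order on a freshly simulated
#' two-ancestry study; each stage writes its TSV/JSON outputs under
#' `config$outdir` (every file headed by the seed and a config hash) and a
#' structured log records the counts entering and leaving each filter.
#' Identical config + seed gives byte-identical outputs.
#'
#' @param config A `pipeline_config` ([default_config()]).
#' @return Invisibly, a list with the in-memory stage products (`study`,
#'   `stats`, `meta`, `leads`, `rb`, `sets`, `tally`, `cojo`, `finemap`,
#'   `log`).
#' @export
run_pipeline <- function(config = default_config()) {
  th <- config$thresholds
  sm <- config$sim
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logline <- function(...) {
    msg <- paste0(...)
    message("[mqtlshare] ", msg)
    msg
  }
  log <- character()
  if (!isTRUE(config$stages$simulate))
    stop("pipeline requires the simulate stage (no external inputs configured)")
  model <- population_model(
    n_snps = sm$n_snps,
    block_lengths = rep(sm$block_len, sm$n_snps / sm$block_len),
    rho_eur = sm$rho_eur, rho_eas = sm$rho_eas, fst = sm$fst,
    eas_block_shift = sm$eas_block_shift, seed = config$seed)
  study <- simulate_study(model, config$cohorts, n_probes = sm$n_probes,
                          window = sm$window, rho_b = sm$rho_b,
                          prop_private = sm$prop_private, n_ref = sm$n_ref,
                          missing_rate = sm$missing_rate,
                          seed = config$seed)
  write_truth_json(study$truth, file.path(config$outdir, "truth.json"))
  log <- c(log, logline("simulated ", nrow(config$cohorts), " cohorts, ",
                        sm$n_probes, " probes, ", sm$n_snps, " SNPs"))

  stats <- list()
  for (co in study$cohorts) {
    g <- co$genos
    if (isTRUE(config$stages$qc)) {
      qc <- qc_genotypes(g)
      log <- c(log, logline("qc ", co$name, ": ", ncol(g$dosage), " -> ",
                            ncol(qc$genos$dosage), " SNPs"))
      write_stage_tsv(qc$log,
                      file.path(config$outdir,
                                paste0("qc_", co$name, ".tsv")), config)
      g <- qc$genos
    }
    if (!isTRUE(config$stages$scan))
      stop("downstream stages need the scan stage enabled")
    adj <- adjust_methylation(co$meth, co$covariates)
    adj <- t(apply(adj, 1L, rank_int))
    st <- scan_cis(adj, g, study$truth$probes, window = study$truth$window)
    stats[[co$name]] <- st
    log <- c(log, logline("scan ", co$name, ": ", nrow(st), " records"))
  }

  if (!isTRUE(config$stages$meta))
    stop("downstream stages need the meta stage enabled")
  pops <- vapply(study$cohorts, `[[`, "", "pop")
  meta <- list(
    EUR = meta_cohorts(stats[pops == "EUR"]),
    EAS = meta_cohorts(stats[pops == "EAS"]))
  leads <- lapply(meta, lead_snps)
  for (a in names(meta))
    write_stage_tsv(meta[[a]],
                    file.path(config$outdir, paste0("meta_", a, ".tsv")),
                    config)
  log <- c(log, logline("meta: EUR ", nrow(meta$EUR), " records, EAS ",
                        nrow(meta$EAS), " records"))

  rb <- NULL
  if (isTRUE(config$stages$rb)) {
    rb <- rb_matrix(stats, min_pairs = 10, p_ascertain = th$p_rep)
    write_stage_tsv(rb, file.path(config$outdir, "rb_matrix.tsv"), config)
    log <- c(log, logline("rb matrix over ", length(stats), " cohorts"))
  }

  sets <- NULL; tallied <- NULL; afh <- NULL
  cojo_res <- list(); fm <- NULL
  if (isTRUE(config$stages$classify)) {
    sets <- define_sets(leads$EUR, leads$EAS, cohort_stats = stats,
                        cohort_pops = pops, p_sig = th$p_sig,
                        p_rep = th$p_rep)
    log <- c(log, logline("sets: ",
                          paste(capture_counts(sets$label), collapse = ", ")))
    if (isTRUE(config$stages$cojo)) {
      Rfull <- ld_matrix(study$panels$EUR)
      stringent <- sets[sets$label == "STRINGENT", ]$probe
      for (p_ in stringent) {
        st <- meta$EUR[probe == p_]
        cojo_res[[p_]] <- stepwise_select(st, Rfull[st$snp, st$snp],
                                          p_thresh = th$cojo_p,
                                          r2_cap = th$cojo_r2_cap)
      }
      log <- c(log, logline("cojo on ", length(cojo_res),
                            " stringent probes"))
    }
    cats <- character()
    stringent_probes <- sets[sets$label == "STRINGENT", ]$probe
    for (p_ in stringent_probes) {
      le <- leads$EUR[probe == p_]
      la <- leads$EAS[probe == p_]
      cj <- if (!is.null(cojo_res[[p_]]) &&
                nrow(cojo_res[[p_]]$selected))
        cojo_res[[p_]]$selected$snp else character()
      idx <- cis_window(study$truth$probes$pos[
        study$truth$probes$probe == p_],
        study$panels$EUR$variants, study$truth$window)
      cand <- study$panels$EUR$variants$snp[idx]
      cats[p_] <- as.character(
        classify_shared_mqtl(le, la, study$panels, cojo_snps = cj,
                             candidates = cand,
                             r2_strong = th$r2_strong))
    }
    tallied <- tally_categories(cats)
    jsonlite::write_json(
      list(seed = config$seed, config = config_hash(config),
           table = tallied$table, shared_n = tallied$shared_n,
           shared_pct = tallied$shared_pct, total = tallied$total),
      file.path(config$outdir, "sharing_report.json"),
      auto_unbox = TRUE, digits = NA)
    write_stage_tsv(sets, file.path(config$outdir, "set_labels.tsv"),
                    config)
    afh <- af_heterogeneity(sets, study$panels, rare_af = th$rare_af,
                            r2_weak = th$r2_weak,
                            r2_strong = th$r2_strong)
    if (nrow(afh))
      write_stage_tsv(afh, file.path(config$outdir, "af_heterogeneity.tsv"),
                      config)
    log <- c(log, logline("classified ", length(cats),
                          " stringent probes; shared ", tallied$shared_pct,
                          "%"))
  }

  if (isTRUE(config$stages$finemap)) {
    if (is.null(sets)) stop("finemap stage needs the classify stage")
    sizes <- list()
    same_lead <- sets[sets$label == "STRINGENT" &
                        sets$lead_eur == sets$lead_eas, ]
    keep_leads <- dedupe_leads(merge(
      leads$EUR[, list(probe, snp, p, chrom, pos)],
      same_lead[, list(probe)], by = "probe"))
    for (p_ in keep_leads$probe) {
      se_ <- meta$EUR[probe == p_]
      sa <- meta$EAS[probe == p_]
      pe <- pips_single(se_)
      cs_e <- credible_set(pe, th$coverage, pos = se_$pos, probe = p_,
                           mode = "EUR")
      pa <- pips_single(sa)
      cs_a <- credible_set(pa, th$coverage, pos = sa$pos, probe = p_,
                           mode = "EAS")
      px <- pips_cross(se_, sa)
      cs_x <- credible_set(px, th$coverage,
                           pos = se_$pos[match(names(px), se_$snp)],
                           probe = p_, mode = "CROSS")
      sizes[[p_]] <- data.table::data.table(
        probe = p_, mode = c("EUR", "EAS", "CROSS"),
        size = c(cs_e$size, cs_a$size, cs_x$size))
    }
    fm <- data.table::rbindlist(sizes)
    if (nrow(fm) && length(unique(fm$probe)) >= 4) {
      flt <- filter_outlier_sets(fm)
      fm <- fm[probe %in% flt$keep]
    }
    write_stage_tsv(fm, file.path(config$outdir, "credible_sizes.tsv"),
                    config)
    log <- c(log, logline("finemap: ", length(unique(fm$probe)),
                          " probes, mean sizes ",
                          paste(fm[, round(mean(size), 2), by = "mode"]$V1,
                                collapse = "/")))
  }

  simsize <- NULL
  if (isTRUE(config$stages$simsize)) {
    n0 <- config$cohorts$n[1]
    tr_sub <- study$truth
    keep <- seq_len(min(50L, nrow(tr_sub$probes)))
    tr_sub$probes <- tr_sub$probes[keep, ]
    simsize <- suppressWarnings(sample_size_experiment(
      model, study$afs, tr_sub, n_grid = c(n0, 2L * n0),
      n_eas = n0, seed = config$seed + 900L,
      coverage = th$coverage))
    write_stage_tsv(simsize, file.path(config$outdir, "simsize.tsv"),
                    config)
    log <- c(log, logline("simsize over ", length(keep), " probes"))
  }

  smr_res <- NULL
  if (isTRUE(config$stages$smr)) {
    if (is.null(sets)) stop("smr stage needs the classify stage")
    smr_res <- simulate_smr_stage(study, sets, meta, th, config)
    if (nrow(smr_res))
      write_stage_tsv(smr_res, file.path(config$outdir, "smr.tsv"), config)
    log <- c(log, logline("smr over ", nrow(smr_res),
                          " ancestry-specific probes"))
  }

  writeLines(c(sprintf("# seed=%d config=%s", config$seed,
                       config_hash(config)), log),
             file.path(config$outdir, "pipeline.log"))
  invisible(list(study = study, stats = stats, meta = meta, leads = leads,
                 rb = rb, sets = sets, tally = tallied, afh = afh,
                 cojo = cojo_res, finemap = fm, simsize = simsize,
                 smr = smr_res, log = log))
}

capture_counts <- function(x) {
  tb <- table(x)
  paste0(names(tb), "=", as.integer(tb))
}

# synthetic GWAS per ancestry: traits mediated through methylation at the
# ancestry-specific probes' causal SNPs, then SMR + HEIDI over those probes
simulate_smr_stage <- function(study, sets, meta, th, config,
                               mediation = 0.3) {
  spec <- sets[sets$label %in% c("EUR_SPECIFIC", "EAS_SPECIFIC"), ]
  if (!nrow(spec)) return(data.table::data.table())
  tr <- study$truth
  gwas <- list()
  for (anc in c("EUR", "EAS")) {
    f <- if (anc == "EUR") study$afs$f_eur else study$afs$f_eas
    n_gw <- 4L * config$cohorts$n[1]
    g_out <- simulate_genotypes(study$model, f, n_gw,
                                config$seed + 950L + (anc == "EAS"), anc,
                                id_prefix = paste0("gw", tolower(anc)))
    set.seed(config$seed + 960L + (anc == "EAS"))
    b <- if (anc == "EUR") tr$probes$b_eur else tr$probes$b_eas
    spec_anc <- spec[spec$label == paste0(anc, "_SPECIFIC"), ]$probe
    idx <- match(spec_anc, tr$probes$probe)
    gv <- if (length(idx))
      g_out$dosage[, tr$probes$causal_index[idx], drop = FALSE] %*%
        (b[idx] * mediation) else matrix(0, n_gw, 1)
    trait <- as.numeric(gv) + stats::rnorm(n_gw)
    gw <- suppressWarnings(assoc_scan(trait, g_out, probe = "trait"))
    gw$probe <- NULL
    gwas[[anc]] <- gw
  }
  suppressWarnings(ancestry_specific_smr(
    spec, meta_stats = meta, gwas = gwas, panels = study$panels,
    probes = tr$probes, window = tr$window,
    p_smr_sig = th$p_smr_sig, p_heidi_min = th$p_heidi_min,
    gwas_sig = th$gwas_sig))
}

#' Command-line entry point
#'
#' Verbs: `all` (default) runs every default stage; `simulate`, `qc`,
#' `scan`, `meta`, `rb`, `classify`, `cojo`, `finemap`, `simsize`, `smr`
#' enable the pipeline up to and including the named stage. Options:
#' `--config <json>`, `--out <dir>`, `--seed <int>`.
#'
#' @param args Character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return Invisibly, the [run_pipeline()] result.
#' @export
mqtl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  verbs <- c("simulate", "qc", "scan", "meta", "rb", "classify", "cojo",
             "finemap", "simsize", "smr", "all")
  verb <- if (length(args) && args[1] %in% verbs) args[1] else "all"
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  cfg <- if (!is.null(opt("--config"))) read_config(opt("--config")) else
    default_config()
  if (!is.null(opt("--seed"))) cfg$seed <- as.integer(opt("--seed"))
  if (!is.null(opt("--out"))) cfg$outdir <- opt("--out")
  if (verb != "all") {
    upto <- match(verb, verbs)
    for (v in verbs[-length(verbs)])
      cfg$stages[[v]] <- match(v, verbs) <= upto
  }
  invisible(run_pipeline(cfg))
}
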