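# End-to-end "replay": chains every analysis stage on synthetic inputs and
# assembles one JSON + Markdown report.  Exit status (for the CLI) is clean
# iff every internal balance check passes.

#' Default replay configuration
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param mossbauer_seeds number of noisy-spectrum replicates fitted per
#'   preset (default 5; raise for tighter averages).
#' @param ani_length length of the synthetic genomes used for the ANI
#'   calibration stage (default 2e5 bp).
#' @param out_dir optional directory for the JSON/Markdown report files.
#' @return List of class \code{replay_config}.
#' @export
replay_config <- function(seed = 1L, mossbauer_seeds = 5L,
                          ani_length = 2e5, out_dir = NULL) {
  structure(list(seed = as.integer(seed),
                 mossbauer_seeds = as.integer(mossbauer_seeds),
                 ani_length = ani_length, out_dir = out_dir),
            class = "replay_config")
}

#' Replay every analysis stage on synthetic data
#'
#' Runs: (1) culture simulation and per-phase brutto-equation/partition
#' extraction for the ferrihydrite and glauconite scenarios; (2) simulation
#' and constrained refitting of the glauconite Moessbauer presets with site
#' fractions and ferrous shares; (3) strain-pair generation and the full
#' genome screen (CooA-box scan, operon inference, site-to-operon
#' assignment, heme census, reciprocal-best-hit uniqueness) plus an ANI
#' calibration on mutated copies of a synthetic genome.
#'
#' @param config a \code{\link{replay_config}}.
#' @param progress print stage timers (default TRUE).
#' @return List of class \code{replay_report}; element \code{ok} is TRUE iff
#'   all internal balance checks passed.  When \code{config$out_dir} is set,
#'   \code{report.json} and \code{report.md} are written there.
#' @export
replay <- function(config = replay_config(), progress = TRUE) {
  t_start <- Sys.time()
  say <- function(...) if (progress) message(sprintf(...))
  checks <- list()
  seed <- config$seed

  # --- stage 1: cultures ---------------------------------------------------
  say("[1/3] culture simulation + electron balance")
  cultures <- list()
  for (scen in c("ferrihydrite_CO_lactate", "glauconite_CO_lactate")) {
    ts <- simulate_culture(scen, seed = seed)
    truth <- attr(ts, "truth")
    bp <- if (is.finite(truth$switch_time)) truth$switch_time else numeric(0)
    phases <- partition_from_timeseries(ts, breakpoints = bp)
    resid <- lapply(phases, function(p) max(abs(check_balance(p$equation))))
    checks[[paste0("balance_", scen)]] <- all(unlist(resid) < 1e-6)
    cultures[[scen]] <- list(
      truth = truth,
      phases = lapply(phases, function(p) list(
        phase = p$phase, from = p$from, to = p$to,
        coefficients = as.list(unclass(p$equation)),
        co_to_fe = p$partition$co_to_fe,
        co_to_h2 = p$partition$co_to_h2,
        fraction_fe = p$partition$fraction_fe)))
  }

  # --- stage 2: Moessbauer -------------------------------------------------
  say("[2/3] Moessbauer simulation + refitting")
  mb <- list()
  for (preset in c("glauconite_initial", "glauconite_166h",
                   "glauconite_960h")) {
    model <- spectrum_preset(preset)
    truth_fe2 <- fe2_share(assign_phases(model))
    fits <- lapply(seq_len(config$mossbauer_seeds), function(k) {
      s <- simulate_spectrum(model, baseline = 1e6, noise = TRUE,
                             seed = seed * 1000L + k)
      fit_spectrum(s, n_doublets = nrow(model),
                   constraints = list(shared_fwhm = TRUE))
    })
    fe2 <- vapply(fits, function(f) fe2_share(assign_phases(f)), numeric(1))
    sid <- vapply(fits, function(f) {
      lf <- assign_phases(f)
      100 * sum(lf$doublets$fraction[lf$doublets$label == "siderite"])
    }, numeric(1))
    frac_ok <- vapply(fits, function(f)
      abs(sum(site_fractions(f)) - 1) < 1e-9, logical(1))
    checks[[paste0("fractions_", preset)]] <- all(frac_ok)
    mb[[preset]] <- list(truth_fe2_pct = truth_fe2,
                         fe2_pct_mean = mean(fe2),
                         fe2_pct_sd = stats::sd(fe2),
                         siderite_pct_mean = mean(sid),
                         n_fits = length(fits))
  }

  # --- stage 3: genomes ----------------------------------------------------
  say("[3/3] strain pair + genome screen + ANI")
  pair <- generate_strain_pair(strain_pair_spec(seed = seed))
  gs <- list()
  for (nm in c("strain_a", "strain_b")) {
    s <- pair[[nm]]
    hits <- scan_iupac(s$genome, pair$truth$consensus,
                       contig = s$features$contig[1])
    ops <- infer_operons(s$features)
    hits <- assign_sites_to_operons(hits, ops, s$features)
    census <- find_multihemes(s$proteome)
    gs[[nm]] <- list(n_sites = nrow(hits),
                     co_regulated_operons = unique(stats::na.omit(hits$operon)),
                     n_multiheme = nrow(census),
                     max_hemes = if (nrow(census)) max(census$hemes) else 0L)
  }
  comp <- reciprocal_unique(pair$strain_a$proteome, pair$strain_b$proteome)
  uniq_census <- find_multihemes(pair$strain_b$proteome[comp$unique_to_b],
                                 min_hemes = 1)
  checks$one_exclusive_multiheme <-
    identical(sort(pair$truth$unique_b),
              sort(uniq_census$id[uniq_census$hemes >= 15]))

  g0 <- .random_dna(config$ani_length, gc = 0.49)
  ani_near <- ani(g0, mutate_genome(g0, 0.003, seed + 1L))
  gs$ani <- list(self = ani(g0, g0)$ani, mutated_0.3pct = ani_near$ani)
  checks$ani_self_100 <- abs(gs$ani$self - 100) < 1e-9

  report <- structure(list(
    seed = seed,
    cultures = cultures,
    mossbauer = mb,
    genome_screen = gs,
    strain_comparison = list(n_pairs = nrow(comp$pairs),
                             unique_to_a = comp$unique_to_a,
                             unique_to_b = comp$unique_to_b),
    checks = checks,
    ok = all(unlist(checks)),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "replay_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format_replay_md(report),
               file.path(config$out_dir, "report.md"))
  }
  report
}

#' Render a replay report as Markdown
#' @param report a \code{replay_report}.
#' @return Character vector of Markdown lines.
#' @export
format_replay_md <- function(report) {
  ln <- c("# ferroco replay report", "",
          sprintf("Seed: %d.  All checks passed: %s.", report$seed,
                  report$ok), "", "## CO partition by growth phase", "")
  for (scen in names(report$cultures)) {
    ln <- c(ln, sprintf("### %s", scen))
    for (p in report$cultures[[scen]]$phases)
      ln <- c(ln, sprintf(
        "- %s (%.1f-%.1f h): CO to Fe(III) %.3g, CO to H2 %.3g, fraction %.1f%%",
        p$phase, p$from, p$to, p$co_to_fe, p$co_to_h2,
        100 * p$fraction_fe))
    ln <- c(ln, "")
  }
  ln <- c(ln, "## Moessbauer site fractions", "")
  for (nm in names(report$mossbauer)) {
    m <- report$mossbauer[[nm]]
    ln <- c(ln, sprintf(
      "- %s: Fe2+ share %.2f%% (truth %.2f%%), siderite %.2f%% (mean of %d fits)",
      nm, m$fe2_pct_mean, m$truth_fe2_pct, m$siderite_pct_mean, m$n_fits))
  }
  gs <- report$genome_screen
  ln <- c(ln, "", "## Genome screen", "",
          sprintf("- strain A: %d consensus sites, %d multiheme cytochromes (max %d hemes)",
                  gs$strain_a$n_sites, gs$strain_a$n_multiheme,
                  gs$strain_a$max_hemes),
          sprintf("- strain B: %d consensus sites, %d multiheme cytochromes (max %d hemes)",
                  gs$strain_b$n_sites, gs$strain_b$n_multiheme,
                  gs$strain_b$max_hemes),
          sprintf("- reciprocal pairs: %d; unique to A: %d; unique to B: %d",
                  report$strain_comparison$n_pairs,
                  length(report$strain_comparison$unique_to_a),
                  length(report$strain_comparison$unique_to_b)),
          sprintf("- ANI: self %.2f%%, 0.3%% mutated %.2f%%",
                  gs$ani$self, gs$ani$mutated_0.3pct))
  ln
}

#' @export
print.replay_report <- function(x, ...) {
  cat(format_replay_md(x), sep = "\n")
  invisible(x)
}
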