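# Synthetic culture trajectories for growth on CO + lactate with an Fe(III)
# mineral.  The generator integrates a simple flux model forward in time
# (explicit Euler, 0.5 h step): cell-density-driven Monod uptake of CO and
# lactate, a configurable partition of CO electrons between Fe(III) and
# protons that switches when the medium redox potential falls below a
# threshold, and a redox potential that tracks cumulative Fe(II).  All gas
# and solute pools are expressed as liquid-phase mmol-equivalents so that the
# cumulative electron ledger 4*d(acetate) + 2*d(CO_ox) = d(Fe2) + 2*d(H2)
# holds exactly, step by step, in the noise-free signal.

#' Built-in culture scenarios
#'
#' \describe{
#'   \item{ferrihydrite_CO_lactate}{Two growth phases.  Phase 1 (high Eh,
#'     active Fe(III) reduction): 13/30 of CO electrons go to Fe(III), lactate
#'     is catabolized to acetate at 77\% yield.  When accumulating Fe(II)
#'     drives Eh below -250 mV, the partition switches to 3/270 and the
#'     acetate yield drops.  Totals are tuned so that about 2.3 mM lactate is
#'     consumed and 1.1 mM acetate formed.}
#'   \item{glauconite_CO_lactate}{Structural Fe(III) reduction from a mica
#'     mineral: no acetate at all (lactate is carbon source only), Fe(II)
#'     production driven entirely by CO electrons, ceasing on CO exhaustion
#'     at about 1.42 mM Fe(II); Eh falls to -520 mV.}
#'   \item{lowEh_CO_only}{Pure hydrogenogenic carboxydotrophy at low Eh:
#'     CO + H2O -> CO2 + H2, no iron, no lactate.}
#' }
#'
#' @param name scenario name.
#' @param ... overrides of scenario fields (e.g. \code{noise_sd}, pools,
#'   partitions, \code{seed}).
#' @return List of class \code{culture_scenario}.
#' @export
culture_scenario <- function(name = c("ferrihydrite_CO_lactate",
                                      "glauconite_CO_lactate",
                                      "lowEh_CO_only"), ...) {
  name <- match.arg(name)
  base <- list(
    name = name,
    t_end = 120, dt = 0.5,
    cells0 = 1e7, cell_yield = 5e6,       # cells per mmol-equiv electrons
    cell_cap = 4e8,                       # carrying capacity, cells/ml
    lac_phase2_factor = 0.016,            # phase-2 slowdown of lactate catabolism
    co0 = 150, lactate0 = 3.5, fe3_0 = 90,
    vmax_co = 1.2, k_co = 20,             # mM-equiv / h at unit cell density
    vmax_lac = 0.145, k_lac = 2, k_fe = 10,
    partition_phase1 = 13 / 30, partition_phase2 = 3 / 270,
    acetate_yield_phase1 = 0.77, acetate_yield_phase2 = 0.25,
    eh0 = -90, eh_floor = -360, eh_fe2_scale = 19.5, eh_switch = -250,
    noise_sd = 0, seed = 1L)
  over <- switch(name,
    ferrihydrite_CO_lactate = list(),
    glauconite_CO_lactate = list(
      t_end = 240, co0 = 9.0, lactate0 = 1.0, fe3_0 = 20,
      vmax_co = 1.6, vmax_lac = 0.12, k_lac = 0.5,
      partition_phase1 = 0.079, partition_phase2 = 0.079,
      acetate_yield_phase1 = 0, acetate_yield_phase2 = 0,
      eh_floor = -520, eh_fe2_scale = 1.3, eh_switch = -600),
    lowEh_CO_only = list(
      co0 = 100, lactate0 = 0, fe3_0 = 0,
      partition_phase1 = 0, partition_phase2 = 0,
      acetate_yield_phase1 = 0, acetate_yield_phase2 = 0,
      eh0 = -430, eh_floor = -430, eh_switch = -600))
  sc <- modifyList(modifyList(base, over), list(...))
  if (sc$partition_phase1 < 0 || sc$partition_phase1 > 1 ||
      sc$partition_phase2 < 0 || sc$partition_phase2 > 1)
    stop("partitions must lie in [0, 1]")
  if (any(unlist(sc[c("co0", "lactate0", "fe3_0")]) < 0))
    stop("initial pools must be non-negative")
  class(sc) <- "culture_scenario"
  sc
}

#' Simulate a culture trajectory
#'
#' Forward-Euler integration of the scenario's flux model; see
#' \code{\link{culture_scenario}} for the built-in presets.  Gaussian
#' relative noise (\code{noise_sd}) is applied to the measured columns after
#' integration, so the noise-free signal always satisfies the electron
#' ledger exactly.
#'
#' @param scenario a \code{\link{culture_scenario}} (or a preset name).
#' @param ... when \code{scenario} is a name: overrides passed through.
#' @return A \code{\link{culture_timeseries}} with attributes
#'   \code{scenario} and \code{truth} (list with the configured per-phase CO
#'   partitions and the phase-switch time, NA when never switched).
#' @export
simulate_culture <- function(scenario = "ferrihydrite_CO_lactate", ...) {
  if (is.character(scenario)) scenario <- culture_scenario(scenario, ...)
  sc <- scenario
  nt <- floor(sc$t_end / sc$dt) + 1L
  tt <- seq(0, by = sc$dt, length.out = nt)
  cells <- co <- h2 <- co2 <- lac <- ace <- fe2 <- eh <- numeric(nt)
  cells[1] <- sc$cells0; co[1] <- sc$co0; lac[1] <- sc$lactate0
  eh[1] <- sc$eh0
  fe3 <- sc$fe3_0
  phase2 <- FALSE
  switch_time <- NA_real_
  glauconite <- sc$name == "glauconite_CO_lactate"

  for (i in 2:nt) {
    dt <- sc$dt
    dens <- cells[i - 1] / 1e8
    p <- if (phase2) sc$partition_phase2 else sc$partition_phase1
    y_ace <- if (phase2) sc$acetate_yield_phase2 else sc$acetate_yield_phase1

    v_co <- sc$vmax_co * dens * co[i - 1] / (co[i - 1] + sc$k_co)
    v_co <- min(v_co, co[i - 1] / dt)
    # CO electrons to Fe(III) are limited by remaining Fe(III)
    p_eff <- if (fe3 <= 0) 0 else min(p, fe3 / (2 * v_co * dt + 1e-12))

    # lactate catabolism to acetate requires Fe(III) as sink (4 e-)
    v_cat <- if (y_ace > 0 && fe3 > 0)
      sc$vmax_lac * (if (phase2) sc$lac_phase2_factor else 1) * dens *
        lac[i - 1] / (lac[i - 1] + sc$k_lac) *
        fe3 / (fe3 + sc$k_fe) else 0
    v_cat <- min(v_cat, fe3 / (4 * dt + 1e-12))
    # assimilated lactate carries no catabolic electrons
    v_assim <- if (y_ace > 0) v_cat * (1 - y_ace) / y_ace else
      sc$vmax_lac * dens * lac[i - 1] / (lac[i - 1] + sc$k_lac)
    if (glauconite && co[i - 1] <= 1e-9) v_assim <- 0
    tot_lac <- v_cat + v_assim
    if (tot_lac * dt > lac[i - 1]) {
      scale <- lac[i - 1] / (tot_lac * dt)
      v_cat <- v_cat * scale; v_assim <- v_assim * scale
    }

    d_fe2 <- (2 * p_eff * v_co + 4 * v_cat) * dt
    d_fe2 <- min(d_fe2, fe3)
    fe3 <- fe3 - d_fe2

    co[i] <- co[i - 1] - v_co * dt
    h2[i] <- h2[i - 1] + (1 - p_eff) * v_co * dt
    co2[i] <- co2[i - 1] + (v_co + v_cat) * dt
    lac[i] <- lac[i - 1] - (v_cat + v_assim) * dt
    ace[i] <- ace[i - 1] + v_cat * dt
    fe2[i] <- fe2[i - 1] + d_fe2
    cells[i] <- cells[i - 1] + sc$cell_yield * (4 * v_cat + 2 * v_co) * dt *
      max(0, 1 - cells[i - 1] / sc$cell_cap)
    eh[i] <- sc$eh0 + (sc$eh_floor - sc$eh0) *
      min(1, fe2[i] / sc$eh_fe2_scale)
    if (!phase2 && eh[i] < sc$eh_switch) {
      phase2 <- TRUE
      switch_time <- tt[i]
    }
  }

  df <- data.frame(time_h = tt, cells_per_ml = cells, CO_mmol = co,
                   H2_mmol = h2, CO2_mmol = co2, lactate_mM = lac,
                   acetate_mM = ace, Fe2_mM = fe2, Eh_mV = eh)
  if (sc$noise_sd > 0) {
    set.seed(as.integer(sc$seed))
    for (col in c("cells_per_ml", "CO_mmol", "H2_mmol", "CO2_mmol",
                  "lactate_mM", "acetate_mM", "Fe2_mM")) {
      scale <- max(abs(df[[col]]))
      df[[col]] <- pmax(0, df[[col]] +
                          rnorm(nt, 0, sc$noise_sd * scale))
    }
  }
  ts <- culture_timeseries(df)
  attr(ts, "scenario") <- sc$name
  attr(ts, "truth") <- list(partition_phase1 = sc$partition_phase1,
                            partition_phase2 = sc$partition_phase2,
                            switch_time = switch_time)
  ts
}
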