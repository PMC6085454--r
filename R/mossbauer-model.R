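# Moessbauer quadrupole-doublet model: domain objects, forward simulation and
# Fe-phase assignment.  Room-temperature paramagnetic spectra are modelled in
# the thin-absorber approximation as a superposition of symmetric doublets:
# two equal-area Lorentzian absorption lines at delta +/- Delta/2.

#' A symmetric quadrupole doublet
#'
#' @param delta isomer shift (mm/s).
#' @param splitting quadrupole splitting Delta (mm/s, >= 0); the two lines sit
#'   at \code{delta - splitting/2} and \code{delta + splitting/2}.
#' @param fwhm Lorentzian full width at half maximum Gamma (mm/s, > 0).
#' @param area integrated spectral area of the doublet (dimensionless fraction
#'   of baseline x mm/s, shared equally by the two lines).
#' @param label optional phase name.
#' @return An object of class \code{mb_doublet}.
#' @export
doublet <- function(delta, splitting, fwhm = 0.3, area = 1, label = NA_character_) {
  if (!is.finite(delta)) stop("delta must be finite")
  if (!is.finite(splitting) || splitting < 0) stop("splitting must be >= 0")
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be > 0")
  if (!is.finite(area) || area < 0) stop("area must be >= 0")
  structure(list(delta = delta, splitting = splitting, fwhm = fwhm,
                 area = area, label = label), class = "mb_doublet")
}

#' @export
print.mb_doublet <- function(x, ...) {
  cat(sprintf("doublet%s: delta=%.3f  Delta=%.3f  Gamma=%.3f  area=%.4g\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              x$delta, x$splitting, x$fwhm, x$area))
  invisible(x)
}

# coerce a list of doublets / data.frame into a canonical data.frame
.doublet_frame <- function(model) {
  if (inherits(model, "mb_doublet")) model <- list(model)
  if (is.data.frame(model)) {
    stopifnot(all(c("delta", "splitting", "fwhm", "area") %in% names(model)))
    if (!"label" %in% names(model)) model$label <- NA_character_
    return(model[, c("delta", "splitting", "fwhm", "area", "label")])
  }
  do.call(rbind, lapply(model, function(d)
    data.frame(delta = d$delta, splitting = d$splitting, fwhm = d$fwhm,
               area = d$area, label = d$label %||% NA_character_,
               stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# unit-area Lorentzian density
.lorentz <- function(v, center, fwhm) {
  hw <- fwhm / 2
  (hw / pi) / ((v - center)^2 + hw^2)
}

# total fractional absorption profile of a doublet model on a velocity grid
.absorption <- function(model, v) {
  df <- .doublet_frame(model)
  a <- numeric(length(v))
  for (i in seq_len(nrow(df))) {
    a <- a + df$area[i] / 2 *
      (.lorentz(v, df$delta[i] - df$splitting[i] / 2, df$fwhm[i]) +
       .lorentz(v, df$delta[i] + df$splitting[i] / 2, df$fwhm[i]))
  }
  a
}

#' Default velocity grid
#'
#' Symmetric +/- 4 mm/s grid of 512 channels, wide enough for silicate
#' Fe2+/Fe3+ and siderite doublets.
#' @param vmax half-range (mm/s). @param channels number of channels.
#' @return Numeric vector of velocities.
#' @export
velocity_grid <- function(vmax = 4, channels = 512) {
  seq(-vmax, vmax, length.out = channels)
}

#' Simulate a transmission Moessbauer spectrum
#'
#' Intensity per channel is
#' \deqn{I(v) = B\,\bigl(1 - \sum_k \tfrac{A_k}{2}[\mathcal{L}(v;\delta_k -
#'   \Delta_k/2,\Gamma_k) + \mathcal{L}(v;\delta_k + \Delta_k/2,\Gamma_k)]\bigr)}
#' with unit-area Lorentzians; counting noise, when requested, is Poisson per
#' channel.
#'
#' @param model list of \code{\link{doublet}}s (or a doublet data.frame).
#' @param baseline off-resonance counts per channel.
#' @param grid velocity grid (mm/s), strictly increasing, length >= 64.
#' @param noise logical; add Poisson counting noise.
#' @param seed integer seed, mandatory when \code{noise = TRUE}.
#' @return Object of class \code{mb_spectrum}: list with \code{velocity},
#'   \code{counts}, \code{baseline}.
#' @export
simulate_spectrum <- function(model, baseline = 1e6, grid = velocity_grid(),
                              noise = FALSE, seed = NULL) {
  if (length(grid) < 64 || is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing with >= 64 channels")
  absorb <- .absorption(model, grid)
  if (any(absorb > 1))
    stop("total absorption exceeds the baseline (depth > 1); reduce areas")
  mu <- baseline * (1 - absorb)
  counts <- if (noise) {
    if (is.null(seed)) stop("seed is required when noise = TRUE")
    set.seed(as.integer(seed))
    rpois(length(mu), mu)
  } else mu
  structure(list(velocity = grid, counts = counts, baseline = baseline),
            class = "mb_spectrum")
}

#' Read / write a two-column spectrum file
#'
#' Whitespace- or comma-separated velocity (mm/s) and counts.
#' @param path file path.
#' @param baseline optional baseline; estimated as the mean of the outer 5\%
#'   of channels when absent.
#' @return \code{read_spectrum}: an \code{mb_spectrum}.
#' @export
read_spectrum <- function(path, baseline = NULL) {
  first <- readLines(path, n = 1)
  df <- if (grepl(",", first)) read.csv(path, header = FALSE)
        else read.table(path, header = FALSE)
  v <- df[[1]]; y <- df[[2]]
  o <- order(v)
  v <- v[o]; y <- y[o]
  if (is.null(baseline)) {
    k <- max(3, round(0.05 * length(v)))
    baseline <- mean(c(head(y, k), tail(y, k)))
  }
  structure(list(velocity = v, counts = y, baseline = baseline),
            class = "mb_spectrum")
}

#' @rdname read_spectrum
#' @param s an \code{mb_spectrum}.
#' @export
write_spectrum <- function(s, path) {
  write.table(data.frame(velocity = s$velocity, counts = s$counts), path,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default Fe phase-assignment library
#'
#' Literature room-temperature (isomer shift, quadrupole splitting) windows
#' for the phases relevant to microbial glauconite reduction.  The windows are
#' conventional ranges, user-overridable, applied in order (first match wins).
#'
#' @return data.frame with columns \code{name}, \code{delta_min},
#'   \code{delta_max}, \code{split_min}, \code{split_max}, \code{state}.
#' @export
default_phase_library <- function() {
  data.frame(
    name = c("siderite", "Fe2+ octahedral silicate", "Fe3+ octahedral silicate"),
    delta_min = c(1.10, 1.00, 0.20),
    delta_max = c(1.35, 1.30, 0.50),
    split_min = c(1.60, 2.10, 0.30),
    split_max = c(2.05, 3.00, 1.40),
    state = c("Fe2+", "Fe2+", "Fe3+"),
    stringsAsFactors = FALSE)
}

#' Relative Fe site fractions from fitted areas
#'
#' Under the equal recoil-free-fraction assumption, relative subspectrum areas
#' equal relative Fe atom contents, so fractions are areas normalised to unit
#' sum.
#'
#' @param fit an \code{mb_fit} (from \code{\link{fit_spectrum}}), or a numeric
#'   vector of areas.
#' @return Numeric vector of fractions summing to 1.
#' @export
site_fractions <- function(fit) {
  a <- if (inherits(fit, "mb_fit")) fit$doublets$area else as.numeric(fit)
  if (any(a < 0)) stop("areas must be non-negative")
  s <- sum(a)
  if (s == 0) stop("all areas are zero; fractions undefined")
  a / s
}

#' Assign mineral-phase labels to fitted doublets
#'
#' Each doublet is labelled by the first library window containing its
#' (isomer shift, quadrupole splitting) point; unmatched doublets are
#' \code{"unassigned"}.
#'
#' @param fit an \code{mb_fit} or doublet data.frame.
#' @param library a phase library as from \code{\link{default_phase_library}}.
#' @return The input with \code{label} and \code{state} columns filled.
#' @export
assign_phases <- function(fit, library = default_phase_library()) {
  df <- if (inherits(fit, "mb_fit")) fit$doublets else .doublet_frame(fit)
  df$label <- "unassigned"
  df$state <- NA_character_
  for (i in seq_len(nrow(df))) {
    hit <- which(df$delta[i] >= library$delta_min &
                 df$delta[i] <= library$delta_max &
                 df$splitting[i] >= library$split_min &
                 df$splitting[i] <= library$split_max)
    if (length(hit)) {
      df$label[i] <- library$name[hit[1]]
      df$state[i] <- library$state[hit[1]]
    }
  }
  if (inherits(fit, "mb_fit")) {
    fit$doublets <- df
    fit
  } else df
}

#' Ferrous share of the spectral area
#'
#' Sum of site fractions of doublets assigned to an Fe2+ phase, in percent.
#'
#' @param fit an \code{mb_fit} or doublet data.frame with phase labels
#'   assigned (see \code{\link{assign_phases}}).
#' @return Percent of total area in Fe2+ phases.
#' @export
fe2_share <- function(fit) {
  df <- if (inherits(fit, "mb_fit")) fit$doublets
        else if (is.data.frame(fit)) fit
        else .doublet_frame(fit)
  if (!"state" %in% names(df))
    stop("phase states not assigned; run assign_phases() first")
  fr <- df$area / sum(df$area)
  100 * sum(fr[!is.na(df$state) & df$state == "Fe2+"])
}
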