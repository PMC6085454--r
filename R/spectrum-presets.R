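# Doublet-model presets for the glauconite reduction series.  The Fe2+ and
# siderite area fractions are the measured quantities the presets encode
# (initial 2.2%, 166 h 5.7%, 960 h 3.9% siderite); the individual isomer
# shifts, splittings, linewidths and the split of the remaining ferric area
# are documented room-temperature defaults for octahedral silicate and
# siderite sites, freely overridable.

.PRESETS <- list(
  glauconite_initial = data.frame(
    delta = c(0.36, 0.36, 1.12),
    splitting = c(0.40, 0.95, 2.60),
    fwhm = 0.30,
    area = c(0.600, 0.378, 0.022),
    label = c("Fe3+ octahedral silicate", "Fe3+ octahedral silicate",
              "Fe2+ octahedral silicate"),
    stringsAsFactors = FALSE),
  glauconite_166h = data.frame(
    delta = c(0.36, 0.36, 1.12),
    splitting = c(0.40, 0.95, 2.60),
    fwhm = 0.30,
    area = c(0.578, 0.365, 0.057),
    label = c("Fe3+ octahedral silicate", "Fe3+ octahedral silicate",
              "Fe2+ octahedral silicate"),
    stringsAsFactors = FALSE),
  glauconite_960h = data.frame(
    delta = c(0.36, 0.36, 1.12, 1.22),
    splitting = c(0.40, 0.95, 2.60, 1.80),
    fwhm = 0.30,
    area = c(0.550, 0.354, 0.057, 0.039),
    label = c("Fe3+ octahedral silicate", "Fe3+ octahedral silicate",
              "Fe2+ octahedral silicate", "siderite"),
    stringsAsFactors = FALSE))

#' Moessbauer doublet-model presets for the glauconite series
#'
#' Three stages of microbially driven glauconite reduction: the starting
#' mineral (ferrous share 2.2\% of spectral area), the mineral at 166 h
#' (ferrous share 5.7\%) and the final 960-h four-doublet state in which a
#' new ferrous carbonate phase, siderite, holds 3.9\% of the area.
#'
#' @param name one of \code{"glauconite_initial"}, \code{"glauconite_166h"},
#'   \code{"glauconite_960h"}.
#' @param total_absorption total integrated absorption area of the spectrum
#'   (baseline-relative, mm/s; default 0.12).  Relative areas are scaled by
#'   it, so \code{\link{site_fractions}} of the preset reproduce the encoded
#'   percentages regardless.
#' @return Doublet data.frame (columns \code{delta}, \code{splitting},
#'   \code{fwhm}, \code{area}, \code{label}) usable as a model for
#'   \code{\link{simulate_spectrum}}.
#' @examples
#' fe2_share(assign_phases(spectrum_preset("glauconite_initial")))  # 2.2
#' @export
spectrum_preset <- function(name, total_absorption = 0.12) {
  if (!name %in% names(.PRESETS))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(.PRESETS), collapse = ", "))
  df <- .PRESETS[[name]]
  df$area <- df$area * total_absorption
  df
}

#' Read / write a doublet model as YAML
#'
#' @param path YAML file; a list of doublet records with fields
#'   \code{delta}, \code{splitting}, \code{fwhm}, \code{area},
#'   optional \code{label}.
#' @return \code{read_doublet_yaml}: a doublet data.frame.
#' @export
read_doublet_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  recs <- if (!is.null(y$doublets)) y$doublets else y
  do.call(rbind, lapply(recs, function(r)
    data.frame(delta = r$delta, splitting = r$splitting,
               fwhm = r$fwhm %||% 0.3, area = r$area,
               label = r$label %||% NA_character_,
               stringsAsFactors = FALSE)))
}

#' @rdname read_doublet_yaml
#' @param model doublet data.frame (or list of \code{\link{doublet}}s).
#' @export
write_doublet_yaml <- function(model, path) {
  df <- .doublet_frame(model)
  yaml::write_yaml(list(doublets = lapply(seq_len(nrow(df)), function(i)
    list(delta = df$delta[i], splitting = df$splitting[i],
         fwhm = df$fwhm[i], area = df$area[i],
         label = if (is.na(df$label[i])) NULL else df$label[i]))), path)
  invisible(path)
}
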