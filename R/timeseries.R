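# Culture time-series container, CSV I/O, phase-boundary detection and
# per-phase CO-partition extraction.

.ts_columns <- c("time_h", "cells_per_ml", "CO_mmol", "H2_mmol", "CO2_mmol",
                 "lactate_mM", "acetate_mM", "Fe2_mM", "Eh_mV")

#' Construct a culture time series
#'
#' @param df data.frame with column \code{time_h} (strictly increasing) and
#'   any subset of \code{cells_per_ml}, \code{CO_mmol}, \code{H2_mmol},
#'   \code{CO2_mmol}, \code{lactate_mM}, \code{acetate_mM}, \code{Fe2_mM},
#'   \code{Eh_mV}.
#' @return A data.frame of class \code{culture_timeseries}.
#' @export
culture_timeseries <- function(df) {
  if (!"time_h" %in% names(df)) stop("column 'time_h' is required")
  if (is.unsorted(df$time_h, strictly = TRUE))
    stop("time_h must be strictly increasing")
  unknown <- setdiff(names(df), .ts_columns)
  if (length(unknown))
    warning("ignoring unknown columns: ", paste(unknown, collapse = ", "))
  df <- df[, intersect(.ts_columns, names(df)), drop = FALSE]
  class(df) <- c("culture_timeseries", "data.frame")
  df
}

#' Read a culture time series from CSV
#'
#' @param path CSV file with a \code{time_h} column; other recognised columns
#'   are optional.
#' @return A \code{\link{culture_timeseries}}.
#' @export
read_timeseries <- function(path) {
  culture_timeseries(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a culture time series to CSV
#' @param ts a \code{culture_timeseries}.
#' @param path output file.
#' @export
write_timeseries <- function(ts, path) {
  write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

#' Detect a growth-phase boundary on the Fe(II) curve
#'
#' Exhaustively fits a continuous two-segment piecewise-linear model with the
#' knot at each interior time point and returns the knot minimising the total
#' squared error.  If the best two-segment fit improves on a single line by
#' less than \code{tol} (relative SSE reduction), the curve is flagged as
#' having no distinct phases.
#'
#' @param ts a \code{culture_timeseries} with at least 6 points.
#' @param column response column, default \code{"Fe2_mM"}.
#' @param tol minimal relative SSE improvement to call two phases (default
#'   0.2).
#' @return List with \code{time} (the knot), \code{sse}, \code{sse_linear},
#'   \code{improvement} and \code{distinct} (logical).
#' @export
detect_breakpoint <- function(ts, column = "Fe2_mM", tol = 0.2) {
  if (!column %in% names(ts)) stop("column '", column, "' not present")
  t <- ts$time_h; y <- ts[[column]]
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 6) stop("need at least 6 time points")
  fit0 <- lm(y ~ t)
  sse0 <- sum(residuals(fit0)^2)
  cand <- t[3:(length(t) - 2)]           # keep >= 2 points in each segment
  sse <- vapply(cand, function(k) {
    sum(residuals(lm(y ~ t + pmax(t - k, 0)))^2)
  }, numeric(1))
  best <- which.min(sse)
  scale0 <- max(sse0, .Machine$double.eps * length(y) * max(1, mean(y)^2))
  improvement <- (sse0 - sse[best]) / scale0
  distinct <- sse0 > 1e-10 * length(y) * max(1, mean(y))^2 &&
    improvement >= tol
  if (!distinct)
    warning("no distinct phases detected (SSE improvement ",
            signif(improvement, 3), " below tolerance)")
  list(time = cand[best], sse = sse[best], sse_linear = sse0,
       improvement = improvement, distinct = distinct)
}

#' @importFrom stats residuals
NULL

# net change of a column between two row indices; 0 if column missing
.delta <- function(ts, column, i0, i1) {
  if (!column %in% names(ts)) return(0)
  v <- ts[[column]]
  v[i1] - v[i0]
}

#' Per-phase brutto-equations and CO partitions from a culture time series
#'
#' Splits the trajectory at the supplied breakpoints (or over the full span if
#' none), computes the net acetate, Fe(II) and H2 changes per phase and
#' composes a brutto-equation for each.  Lactate catabolized is measured by
#' acetate produced; when no acetate is formed in a phase (mica/glauconite
#' mode, lactate consumed as carbon source only) the lactate coefficient is
#' zero and all Fe(III) electrons are assigned to CO.
#'
#' @param ts a \code{culture_timeseries}.
#' @param breakpoints numeric vector of phase-boundary times (may be empty).
#' @return List of per-phase results, each with \code{phase} (label),
#'   \code{from}, \code{to}, \code{summary} (the phase deltas),
#'   \code{equation} (\code{brutto_equation}) and \code{partition}
#'   (\code{partition_result}).  Phases with no measurable activity are
#'   skipped with a warning.
#' @export
partition_from_timeseries <- function(ts, breakpoints = numeric(0)) {
  t <- ts$time_h
  if (length(breakpoints)) {
    if (any(breakpoints <= min(t)) || any(breakpoints >= max(t)))
      stop("breakpoints must lie strictly inside the time range")
    breakpoints <- sort(breakpoints)
  }
  edges <- c(min(t), breakpoints, max(t))
  out <- list()
  for (k in seq_len(length(edges) - 1)) {
    i0 <- which.min(abs(t - edges[k]))
    i1 <- which.min(abs(t - edges[k + 1]))
    L <- max(0, .delta(ts, "acetate_mM", i0, i1))
    F_ <- max(0, .delta(ts, "Fe2_mM", i0, i1))
    H <- max(0, .delta(ts, "H2_mmol", i0, i1))
    if (L == 0 && F_ == 0 && H == 0) {
      warning("phase ", k, " [", edges[k], ", ", edges[k + 1],
              "] h shows no activity; skipped")
      next
    }
    # acetate absent -> lactate is carbon source only; CO carries all Fe e-
    if (L > 0 && F_ < 4 * L) {
      # measured Fe(II) cannot absorb all lactate electrons within the phase
      # (noise or assimilation mismatch): attribute the surplus to lactate
      # assimilated, i.e. clip L to the electron-feasible value
      L <- F_ / 4
    }
    ph <- phase_summary(L, F_, H, label = paste0("phase_", k))
    eq <- compose_brutto(ph)
    out[[length(out) + 1]] <- list(
      phase = ph$label, from = edges[k], to = edges[k + 1],
      summary = ph, equation = eq, partition = co_partition(eq))
  }
  out
}
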