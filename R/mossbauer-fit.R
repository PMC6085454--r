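# Constrained nonlinear least-squares fitting of quadrupole-doublet spectra.
#
# The model is the thin-absorber superposition used by simulate_spectrum().
# Fits are weighted by the Poisson standard deviation per channel
# (sqrt(counts)), so the reduced chi-square of a good fit is ~1.  The
# "equal line widths" constraint shares one Lorentzian FWHM across all 2n
# lines; the unconstrained model gives every line its own width.

# parameter packing --------------------------------------------------------
# shared:   [log B, Gamma, (delta, Delta, A)_1..n]
# per-line: [log B, (Gamma1, Gamma2)_1..n, (delta, Delta, A)_1..n]

.mb_unpack <- function(par, n, shared) {
  B <- exp(par[1])
  if (shared) {
    gam <- matrix(par[2], n, 2)
    rest <- par[-(1:2)]
  } else {
    gam <- matrix(par[2:(2 * n + 1)], n, 2, byrow = TRUE)
    rest <- par[-(1:(2 * n + 1))]
  }
  m <- matrix(rest, n, 3, byrow = TRUE)
  list(B = B, gamma = gam, delta = m[, 1], splitting = m[, 2], area = m[, 3])
}

.mb_model <- function(par, v, n, shared) {
  p <- .mb_unpack(par, n, shared)
  absorb <- numeric(length(v))
  for (k in seq_len(n)) {
    absorb <- absorb + p$area[k] / 2 *
      (.lorentz(v, p$delta[k] - p$splitting[k] / 2, p$gamma[k, 1]) +
       .lorentz(v, p$delta[k] + p$splitting[k] / 2, p$gamma[k, 2]))
  }
  p$B * (1 - absorb)
}

# deterministic multi-start pool: room-temperature (delta, Delta) anchors for
# ferric and ferrous silicate sites, siderite and two generic fillers
.mb_start_pool <- function() {
  matrix(c(0.35, 0.40,
           0.35, 1.00,
           1.20, 1.80,
           1.15, 2.60,
           0.80, 1.40,
           1.20, 2.20), ncol = 2, byrow = TRUE)
}

#' Fit a spectrum as n quadrupole doublets
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) over a multi-start set of initial (isomer shift,
#' splitting) placements; the best solution by weighted SSE is kept, ties
#' broken by the smaller total line width.  With
#' \code{constraints$shared_fwhm} (the conventional "equal line widths"
#' constraint) one FWHM is shared by all lines; otherwise every Lorentzian
#' line has its own width.
#'
#' @param s an \code{mb_spectrum}.
#' @param n_doublets number of doublets (>= 1).
#' @param constraints list; only \code{shared_fwhm} (default TRUE) is used.
#' @param starts optional explicit starts: a list of matrices (or one matrix)
#'   with \code{n_doublets} rows of (delta, splitting).  When NULL a
#'   deterministic grid of room-temperature anchor combinations is used.
#' @param max_starts cap on the number of starting points tried (default 20).
#' @return Object of class \code{mb_fit}: \code{doublets} (data.frame with
#'   \code{delta}, \code{splitting}, \code{fwhm}, \code{area}, their 1-sigma
#'   uncertainties and \code{fraction}), \code{baseline}, \code{shared_fwhm},
#'   \code{sse} (weighted), \code{chi2_reduced}, \code{n_free},
#'   \code{uncertainties_ok}.
#' @export
fit_spectrum <- function(s, n_doublets, constraints = list(shared_fwhm = TRUE),
                         starts = NULL, max_starts = 20) {
  stopifnot(inherits(s, "mb_spectrum"), n_doublets >= 1)
  n <- as.integer(n_doublets)
  shared <- isTRUE(constraints$shared_fwhm %||% TRUE)
  v <- s$velocity
  y <- s$counts
  n_free <- if (shared) 2L + 3L * n else 1L + 2L * n + 3L * n
  if (length(v) < 8 * n_free)
    stop("spectrum has too few channels (", length(v), ") for ",
         n_free, " free parameters")
  w <- 1 / sqrt(pmax(y, 1))

  resid_fun <- function(par) (y - .mb_model(par, v, n, shared)) * w

  B0 <- as.numeric(stats::quantile(y, 0.98))
  dv <- mean(diff(v))
  area_tot <- max(sum((1 - y / B0) * dv), 0.01)

  # build the start list
  if (is.null(starts)) {
    pool <- .mb_start_pool()
    combos <- utils::combn(nrow(pool), min(n, nrow(pool)), simplify = FALSE)
    starts <- lapply(combos, function(i) pool[i, , drop = FALSE])
    if (length(starts) > max_starts) starts <- starts[seq_len(max_starts)]
  } else if (is.matrix(starts)) starts <- list(starts)

  lower_g <- 0.05; upper_g <- 2
  best <- NULL
  for (st in starts) {
    st <- as.matrix(st)
    if (nrow(st) < n) next
    par0 <- c(log(B0),
              if (shared) 0.3 else rep(0.3, 2 * n),
              as.vector(t(cbind(st[seq_len(n), 1], st[seq_len(n), 2],
                                rep(area_tot / n, n)))))
    ng <- if (shared) 1L else 2L * n
    lower <- c(log(B0) - 1, rep(lower_g, ng),
               rep(c(-3, 0, 0), n))
    upper <- c(log(B0) + 1, rep(upper_g, ng),
               rep(c(3, 5, 1), n))
    res <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-10, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res) || res$info %in% c(0, 9)) next
    sse <- sum(res$fvec^2)
    gtot <- sum(.mb_unpack(res$par, n, shared)$gamma)
    if (is.null(best) || sse < best$sse - 1e-9 ||
        (abs(sse - best$sse) <= 1e-9 && gtot < best$gtot)) {
      best <- list(res = res, sse = sse, gtot = gtot)
    }
  }
  if (is.null(best))
    stop("no start converged for ", n, "-doublet fit (",
         length(starts), " starts tried)")

  res <- best$res
  p <- .mb_unpack(res$par, n, shared)
  dof <- length(y) - n_free
  sigma2 <- best$sse / dof

  se <- rep(NA_real_, length(res$par))
  unc_ok <- FALSE
  cv <- tryCatch(solve(res$hessian) * sigma2, error = function(e) NULL)
  if (!is.null(cv) && all(is.finite(diag(cv))) && all(diag(cv) >= 0)) {
    se <- sqrt(diag(cv))
    unc_ok <- TRUE
  }
  sp <- .mb_unpack(se, n, shared)  # same packing for standard errors

  df <- data.frame(delta = p$delta, splitting = p$splitting,
                   fwhm = rowMeans(p$gamma), area = p$area,
                   delta_se = sp$delta, splitting_se = sp$splitting,
                   fwhm_se = rowMeans(sp$gamma), area_se = sp$area,
                   stringsAsFactors = FALSE)
  o <- order(df$delta, df$splitting)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df$fraction <- if (sum(df$area) > 0) df$area / sum(df$area) else NA_real_

  structure(list(doublets = df, baseline = p$B, shared_fwhm = shared,
                 sse = best$sse, chi2_reduced = best$sse / dof,
                 n_free = n_free, uncertainties_ok = unc_ok,
                 info = res$info),
            class = "mb_fit")
}

#' @export
print.mb_fit <- function(x, ...) {
  cat(sprintf("mossbauer fit: %d doublet(s), %s linewidths, chi2/dof = %.3g\n",
              nrow(x$doublets),
              if (x$shared_fwhm) "shared" else "free", x$chi2_reduced))
  print(format(x$doublets, digits = 4))
  invisible(x)
}
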