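# Electron-balance composition of overall catabolic ("brutto") equations for
# growth on lactate + CO with an Fe(III) mineral, and the partition of
# consumed CO between Fe(III) reduction and hydrogenogenesis.
#
# Half-reactions underlying the ledger:
#   lactate- + H2O + 4 Fe3+ -> acetate- + CO2 + 4 Fe2+ + 4 H+   (4 e- donor)
#   CO + H2O + 2 Fe3+       -> CO2 + 2 Fe2+ + 2 H+              (2 e- donor)
#   CO + H2O                -> CO2 + H2                          (2 e- to 2 H+)

#' Registry of catabolic half-reactions
#'
#' Electron book-keeping used throughout the balance module: lactate oxidation
#' to acetate donates 4 electrons, CO oxidation donates 2, Fe(III) accepts 1
#' per atom and protons accept 2 per H2 formed.
#'
#' @return A data.frame with columns \code{id}, \code{electrons_per_mole},
#'   \code{role} and \code{description}.
#' @export
half_reactions <- function() {
  data.frame(
    id = c("lactate_to_acetate", "co_oxidation", "fe3_reduction",
           "hydrogenogenesis"),
    electrons_per_mole = c(4L, 2L, 1L, 2L),
    role = c("donor", "donor", "acceptor", "acceptor"),
    description = c(
      "lactate- + H2O -> acetate- + CO2 + 4e- + 4H+",
      "CO + H2O -> CO2 + 2e- + 2H+",
      "Fe3+ + e- -> Fe2+",
      "2H+ + 2e- -> H2"),
    stringsAsFactors = FALSE)
}

#' Phase-wise metabolite summary
#'
#' Net changes over one growth phase, normalised however the caller prefers
#' (typically per mole of lactate catabolized).  Catabolized lactate is
#' measured by the acetate formed; lactate assimilated into biomass carries no
#' catabolic electrons and is excluded.
#'
#' @param lactate mol lactate catabolized (taken equal to acetate formed).
#' @param fe_reduced mol Fe(III) reduced to Fe(II).
#' @param h2 mol H2 produced.
#' @param label optional phase label.
#' @return An object of class \code{phase_summary}.
#' @export
phase_summary <- function(lactate, fe_reduced, h2, label = NULL) {
  vals <- c(lactate = lactate, fe_reduced = fe_reduced, h2 = h2)
  if (any(!is.finite(vals))) stop("phase summary values must be finite")
  if (any(vals < 0)) stop("phase summary values must be non-negative")
  if (all(vals == 0)) stop("phase summary must have at least one non-zero value")
  structure(list(lactate = lactate, fe_reduced = fe_reduced, h2 = h2,
                 label = label),
            class = "phase_summary")
}

#' Compose a brutto-equation from a phase summary
#'
#' Builds the balanced overall catabolic equation
#' \deqn{L\,lactate^- + CO + H_2O + Fe^{3+} \rightarrow
#'       acetate^- + CO_2 + Fe^{2+} + H^+ + H_2}
#' by closing the electron ledger \eqn{4L + 2\,CO = F + 2\,H_2}: lactate
#' electrons go to Fe(III) first, the remaining Fe(III) electrons and all H2
#' electrons come from CO.  All element and charge balances then hold exactly.
#'
#' @param phase a \code{\link{phase_summary}} (or a list with elements
#'   \code{lactate}, \code{fe_reduced}, \code{h2}).
#' @return An object of class \code{brutto_equation}: a named numeric vector of
#'   stoichiometric coefficients (\code{lactate}, \code{co}, \code{h2o},
#'   \code{fe3} reactants; \code{acetate}, \code{co2}, \code{fe2}, \code{h},
#'   \code{h2} products).
#' @examples
#' compose_brutto(phase_summary(1, 30, 17))  # 30 CO, 43% to Fe(III)
#' @export
compose_brutto <- function(phase) {
  L <- phase$lactate; F_ <- phase$fe_reduced; H <- phase$h2
  if (any(!is.finite(c(L, F_, H))) || any(c(L, F_, H) < 0))
    stop("L, F and H must be finite and non-negative")
  if (L > 0 && F_ < 4 * L)
    stop("donor electron excess: Fe(III) reduced (", F_,
         ") cannot absorb the 4 x ", L, " lactate electrons")
  co <- (F_ - 4 * L) / 2 + H
  eq <- c(lactate = L, co = co, h2o = co + L, fe3 = F_,
          acetate = L, co2 = co + L, fe2 = F_, h = F_, h2 = H)
  structure(eq, class = c("brutto_equation", "numeric"))
}

#' @export
print.brutto_equation <- function(x, ...) {
  fmt <- function(v, s) {
    keep <- v > 0
    paste(paste0(ifelse(abs(v[keep] - 1) < 1e-12, "",
                        paste0(format(v[keep], digits = 6), " ")),
                 s[keep]), collapse = " + ")
  }
  lhs <- fmt(x[c("lactate", "co", "h2o", "fe3")],
             c("lactate-", "CO", "H2O", "Fe3+"))
  rhs <- fmt(x[c("acetate", "co2", "fe2", "h", "h2")],
             c("acetate-", "CO2", "Fe2+", "H+", "H2"))
  cat(lhs, "->", rhs, "\n")
  invisible(x)
}

#' Element and charge residuals of a brutto-equation
#'
#' Recounts C, H, O, Fe and net charge on both sides of the equation
#' (lactate C3H5O3-, acetate C2H3O2-) and returns products-minus-reactants
#' residuals.  Any \code{\link{compose_brutto}} output gives all-zero
#' residuals; a perturbed coefficient shows up as a non-zero entry.
#'
#' @param b a \code{brutto_equation} (or compatible named vector).
#' @return Named numeric vector of residuals over \code{C}, \code{H},
#'   \code{O}, \code{Fe}, \code{charge}.
#' @export
check_balance <- function(b) {
  g <- function(n) if (n %in% names(b)) unname(b[n]) else 0
  c(C = 2 * g("acetate") + g("co2") -
        (3 * g("lactate") + g("co")),
    H = 3 * g("acetate") + g("h") + 2 * g("h2") -
        (5 * g("lactate") + 2 * g("h2o")),
    O = 2 * g("acetate") + 2 * g("co2") -
        (3 * g("lactate") + g("co") + g("h2o")),
    Fe = g("fe2") - g("fe3"),
    charge = (-g("acetate") + 2 * g("fe2") + g("h")) -
             (-g("lactate") + 3 * g("fe3")))
}

#' Partition consumed CO between Fe(III) reduction and hydrogenogenesis
#'
#' Of the CO in a brutto-equation, \eqn{(Fe^{3+} - 4L)/2} moles donate their
#' electrons to Fe(III) and the rest evolve H2.  The Fe(III)-directed fraction
#' is the headline quantity: 13 of 30 CO (about 43\%) in the first,
#' iron-reducing growth phase on ferrihydrite, and 3 of 270 (about 1\%) in the
#' later, hydrogenogenic phase.
#'
#' @param b a \code{brutto_equation}.
#' @return An object of class \code{partition_result}: list with
#'   \code{co_to_fe}, \code{co_to_h2}, \code{fraction_fe} (NA when the CO
#'   coefficient is zero, flagged by \code{defined = FALSE}).
#' @examples
#' co_partition(compose_brutto(phase_summary(1, 30, 17)))  # 13:17
#' @export
co_partition <- function(b) {
  resid <- check_balance(b)
  if (max(abs(resid)) > 1e-8)
    stop("equation is not balanced; residuals: ",
         paste(names(resid), signif(resid, 3), sep = "=", collapse = ", "))
  co_fe <- unname(b["fe3"] - 4 * b["lactate"]) / 2
  co_h2 <- unname(b["h2"])
  total <- co_fe + co_h2
  structure(list(
    co_to_fe = co_fe,
    co_to_h2 = co_h2,
    fraction_fe = if (total > 0) co_fe / total else NA_real_,
    defined = total > 0), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  if (!x$defined) {
    cat("CO partition undefined (no CO consumed)\n")
  } else {
    cat(sprintf("CO to Fe(III): %.4g   CO to H2: %.4g   fraction to Fe: %.1f%%\n",
                x$co_to_fe, x$co_to_h2, 100 * x$fraction_fe))
  }
  invisible(x)
}
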