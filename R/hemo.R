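#' Apparent blood viscosity (Fahraeus-Lindqvist effect)
#'
#' In-vitro apparent viscosity of blood in narrow tubes as a function of the
#' vessel radius, in centipoise:
#' \deqn{\eta(r) = 1.125\,(\kappa + \kappa^2(6 e^{-170 r} -
#'   2.44 e^{-8.09 r^{0.64}} + 2.2)), \quad
#'   \kappa = \left(\frac{r}{r - 5.5\times 10^{-4}}\right)^2}
#' with r in mm. The law has a pole at r = 5.5e-4 mm and tends to
#' 1.125 * 3.2 = 3.6 cP for large radii.
#'
#' @param r vessel radius in mm (must exceed 5.5e-4).
#' @return Viscosity in cP.
#' @export
blood_viscosity <- function(r) {
  vt_viscosity(as.numeric(r))
}

#' Poiseuille resistance of a cylindrical segment
#'
#' \deqn{R = \frac{8 \eta l}{\pi r^4}} with the viscosity given in cP and
#' converted to Pa s once at this boundary, lengths and radii in mm; the
#' resulting resistance is in Pa s / mm^3 so that pressure drops
#' \eqn{\Delta p = R q} come out in Pa for flows in mm^3/s.
#'
#' @param r radius (mm).
#' @param l length (mm).
#' @param eta viscosity (cP).
#' @export
poiseuille_resistance <- function(r, l, eta) {
  if (any(r <= 0) || any(l <= 0) || any(eta <= 0))
    stop("radius, length and viscosity must be positive")
  8 * (eta * 1e-3) * l / (pi * r^4)
}

#' Assign flows across a forest
#'
#' Constrained outlets carry their prescribed fraction of the total root
#' inflow Q; the remaining flow is split equally among the free terminals,
#' \eqn{q_f = (Q - \sum q^{out}_i) / N_{free}}. Internal vessel flows are the
#' sums over descendant terminals, so conservation holds exactly at every
#' junction. With multiple inlets the free-terminal outflow is shared
#' forest-wide, so each tree's effective inflow is q_f times the terminals it
#' captured plus its constrained outlets.
#'
#' @inheritParams vessels
#' @return The free-terminal outflow q_f (mm^3/s), invisibly.
#' @export
assign_flows <- function(forest) {
  invisible(vt_assign_flows(.fptr(forest)))
}

#' Fixed-point radius update
#'
#' Iterates the radius recursion to convergence: bottom-up reduced
#' (subtree-equivalent) resistances, sibling radius ratios
#' \eqn{r_{s1}/r_{s2} = (q_{s1} R^*_{s1} / (q_{s2} R^*_{s2}))^{1/4}}
#' (equalising distal pressure drops) normalised through Murray's law
#' \eqn{r_p^\gamma = r_{s1}^\gamma + r_{s2}^\gamma}, top-down radii from the
#' fixed root radius, then a viscosity refresh from the new radii. Unary
#' chains are treated as series resistances carrying a single radius.
#'
#' @inheritParams vessels
#' @param tol convergence tolerance on the maximum relative radius change.
#' @param max_iter iteration cap; non-convergence raises an error carrying
#'   the last residual.
#' @param constant_viscosity if a number, freezes the viscosity at that value
#'   (cP) instead of using the radius-dependent law.
#' @return List with `iterations` and `residual`, invisibly.
#' @export
update_radii <- function(forest, tol = 1e-6, max_iter = 200,
                         constant_viscosity = NULL) {
  stopifnot(tol > 0, max_iter >= 1)
  eta <- if (is.null(constant_viscosity)) NA_real_ else constant_viscosity
  invisible(vt_update_radii(.fptr(forest), tol, as.integer(max_iter), eta))
}

#' Per-vessel and terminal-path pressure drops
#'
#' \eqn{\Delta p_i = R_i q_i} with the Poiseuille resistance evaluated at the
#' converged radii and viscosities. `terminal_path_drops()` accumulates the
#' drops along each root-to-terminal path; with the pressure-equalising
#' sibling ratio rule all free terminals of a tree see the same total drop
#' (to the convergence tolerance).
#'
#' @inheritParams vessels
#' @return `pressure_drops()`: data.frame with id, resistance (Pa s/mm^3),
#'   flow and `dp` (Pa). `terminal_path_drops()`: data.frame with terminal id
#'   and cumulative `dp` from the root.
#' @export
pressure_drops <- function(forest) {
  v <- vessels(forest)
  R <- poiseuille_resistance(v$radius, v$length, v$viscosity)
  data.frame(id = v$id, resistance = R, flow = v$flow, dp = R * v$flow)
}

#' @rdname pressure_drops
#' @export
terminal_path_drops <- function(forest) {
  v <- vessels(forest)
  dp <- pressure_drops(forest)$dp
  term <- which(v$terminal)
  total <- vapply(term, function(i) {
    s <- 0
    while (!is.na(i)) {
      s <- s + dp[i]
      i <- v$parent[i]
    }
    s
  }, numeric(1))
  data.frame(id = term, dp = total, outlet = v$outlet[term])
}
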