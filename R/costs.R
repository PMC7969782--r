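#' Total intravascular volume of a forest
#'
#' \deqn{F_{vol} = \sum_i l_i \pi r_i^2} over all vessels (mm^3).
#'
#' @inheritParams vessels
#' @export
tree_volume <- function(forest) {
  v <- vessels(forest)
  sum(v$length * pi * v$radius^2)
}

#' Incremental volume cost of a candidate connection
#'
#' Tentatively inserts the terminal, re-converges the radii at full
#' tolerance, measures the change in total tree volume and restores the
#' forest bit-identically before returning.
#'
#' @inheritParams insert_terminal
#' @param tol,max_iter passed to [update_radii()].
#' @return The volume change in mm^3 (scalar).
#' @export
delta_volume <- function(forest, vessel, x_b, x_new, tol = 1e-6,
                         max_iter = 200) {
  before <- tree_volume(forest)
  h <- insert_terminal(forest, vessel, x_b, x_new)
  on.exit(rollback_insertion(forest, h))
  assign_flows(forest)
  update_radii(forest, tol = tol, max_iter = max_iter)
  tree_volume(forest) - before
}

#' Sprouting-cost mixture coefficients
#'
#' The sprouting cost of connecting a new vessel v is
#' \deqn{F_{sprout}(v) = c_v \frac{\Delta F_{vol}(v)}{V_{ref}} +
#'   c_p \frac{r_p}{r_{ref}} +
#'   c_d \left(\frac{\|x^d - x^p\|}{l_{ref}}\right)^2}
#' where the first term is the (normalised) incremental volume, the second
#' the parent-wall degradation cost (proportional to the parent radius, so
#' sprouting from small vessels is favoured) and the third the growth-signal
#' diffusion cost (quadratic in the distance grown). `V_ref` is the
#' currently vascularised volume (the total tree volume before the
#' insertion), `l_ref` its equivalent-sphere radius and `r_ref` the root
#' radius of the tree being connected; all three terms are therefore of
#' comparable magnitude throughout a run.
#'
#' @param c_v,c_p,c_d non-negative mixture coefficients, not all zero.
#' @export
sprout_coeffs <- function(c_v = 1, c_p = 0.5, c_d = 1) {
  stopifnot(c_v >= 0, c_p >= 0, c_d >= 0, c_v + c_p + c_d > 0)
  structure(list(c_v = c_v, c_p = c_p, c_d = c_d), class = "sprout_coeffs")
}

#' Sprouting cost of a candidate connection
#'
#' Evaluated on the same tentatively re-converged state as [delta_volume()]:
#' the parent radius entering the degradation term is the radius of the
#' parent of the new vessel after tentative convergence.
#'
#' @inheritParams delta_volume
#' @param coeffs a [sprout_coeffs()] object.
#' @export
sprout_cost <- function(forest, vessel, x_b, x_new, coeffs,
                        tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(coeffs, "sprout_coeffs"))
  before <- tree_volume(forest)
  V_ref <- before
  l_ref <- (3 * V_ref / (4 * pi))^(1 / 3)
  h <- insert_terminal(forest, vessel, x_b, x_new)
  on.exit(rollback_insertion(forest, h))
  assign_flows(forest)
  update_radii(forest, tol = tol, max_iter = max_iter)
  v <- vessels(forest)
  dvol <- tree_volume(forest) - before
  r_p <- v$radius[v$parent[h$v_new]]
  r_ref <- forest_roots(forest)$radius[v$tree[h$v_new]]
  l_new <- v$length[h$v_new]
  coeffs$c_v * dvol / V_ref + coeffs$c_p * r_p / r_ref +
    coeffs$c_d * (l_new / l_ref)^2
}
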