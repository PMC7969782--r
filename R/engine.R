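#' Stage parameter sets
#'
#' `geo_params()` holds the geometrical parameters: the Murray exponent
#' `gamma` and the symmetry ratio bound `delta`, either a constant or a
#' level-dependent step map (one bound below a bifurcation level, another at
#' or above it, resolved at the level of the parent vessel). `opt_params()`
#' holds the optimisation parameters: the slender-domain tuning `nu` of the
#' minimum-distance criterion, the relaxation factor `f_r`, the
#' neighbourhood factor `f_n` (connection search radius `f_n * l_c`), the
#' triangle discretisation `delta_v` (points per side), the number of
#' consecutive failures `n_fail` before a relaxation step, and the total
#' attempt guard. `angle_params()` holds the bifurcation/opening angle
#' windows in degrees.
#'
#' @param gamma Murray exponent (> 0).
#' @param delta symmetry bound in `[0, 1)`, or a [delta_map()].
#' @export
geo_params <- function(gamma = 3, delta = 0) {
  stopifnot(gamma > 0)
  if (!inherits(delta, "delta_map")) {
    stopifnot(delta >= 0, delta < 1)
    delta <- delta_map(delta, delta, level = .Machine$integer.max)
  }
  structure(list(gamma = gamma, delta = delta), class = "geo_params")
}

#' @rdname geo_params
#' @param low bound applied while the parent bifurcation level is below
#'   `level`.
#' @param high bound applied at or above `level`.
#' @param level level threshold.
#' @export
delta_map <- function(low, high, level) {
  stopifnot(low >= 0, low < 1, high >= 0, high < 1, level >= 0)
  structure(list(low = low, high = high, level = as.integer(level)),
            class = "delta_map")
}

#' @rdname geo_params
#' @param nu slender-domain tuning factor (> 0).
#' @param f_r relaxation factor in (0, 1).
#' @param f_n neighbourhood factor (> 0).
#' @param delta_v lattice points per triangle side (>= 3).
#' @param n_fail consecutive failures before one relaxation step.
#' @param max_attempts stage abort guard.
#' @export
opt_params <- function(nu = 1, f_r = 0.9, f_n = 8, delta_v = 7,
                       n_fail = 100, max_attempts = 1e6) {
  stopifnot(nu > 0, f_r > 0, f_r < 1, f_n > 0, delta_v >= 3, n_fail >= 1,
            max_attempts >= 1)
  structure(list(nu = nu, f_r = f_r, f_n = f_n, delta_v = as.integer(delta_v),
                 n_fail = as.integer(n_fail), max_attempts = max_attempts),
            class = "opt_params")
}

#' @rdname geo_params
#' @param theta_min,theta_max bifurcation angle window (degrees); `theta_max`
#'   defaults to the supplement of `theta_min`.
#' @param phi_min,phi_max opening angle window (degrees); `phi_max` defaults
#'   to the supplement of `phi_min`.
#' @export
angle_params <- function(theta_min = 0, theta_max = NULL,
                         phi_min = 0, phi_max = NULL) {
  if (is.null(theta_max)) theta_max <- 180 - theta_min
  if (is.null(phi_max)) phi_max <- 180 - phi_min
  stopifnot(theta_min >= 0, theta_min <= theta_max, theta_max <= 180,
            phi_min >= 0, phi_min <= 180, phi_max <= 180)
  structure(list(enabled = TRUE, theta_min = theta_min, theta_max = theta_max,
                 phi_min = phi_min, phi_max = phi_max),
            class = "angle_params")
}

#' Root specification for a stage
#'
#' @param position inlet (proximal) position of the root vessel (mm).
#' @param radius fixed root radius r1 (mm).
#' @param inflow root inflow Q (mm^3/s).
#' @param role,behaviour vessel type of the root segment.
#' @export
root_spec <- function(position, radius, inflow, role = "distribution",
                      behaviour = "versatile") {
  stopifnot(radius > 0, inflow > 0)
  structure(list(position = .pad3(position), radius = radius, inflow = inflow,
                 role = role, behaviour = behaviour), class = "root_spec")
}

#' Define a growth stage
#'
#' A stage is the elemental unit of the staged growth process: a domain, the
#' geometrical and optimisation parameter sets, a terminal budget, a cost
#' functional, the vessel type generated, a terminal-placement density,
#' optional angle constraints, optional new inlets, and an optional
#' restriction of the eligible parent vessels to those created by earlier
#' stages.
#'
#' @param domain a `vasc_domain`.
#' @param budget number of new terminals to commit (>= 0).
#' @param geo a [geo_params()].
#' @param opt an [opt_params()].
#' @param angles an [angle_params()] or `NULL` (disabled).
#' @param cost `"vol"` (incremental tree volume) or `"sprout"`.
#' @param coeffs a [sprout_coeffs()] when `cost = "sprout"`.
#' @param role,behaviour vessel type generated by this stage.
#' @param density a `vasc_density`.
#' @param roots list of [root_spec()]s creating new inlets before growth.
#' @param seed_stages integer vector of stage ids whose vessels may act as
#'   parent vessels in this stage (`NULL` = all).
#' @param label optional stage label.
#' @param search_iters local fixed-point iterations used while scoring
#'   candidates (full-tolerance convergence is run after each commit).
#' @export
growth_stage <- function(domain, budget, geo = geo_params(),
                         opt = opt_params(), angles = NULL,
                         cost = c("vol", "sprout"), coeffs = NULL,
                         role = "distribution", behaviour = "versatile",
                         density = uniform_density(), roots = NULL,
                         seed_stages = NULL, label = NULL, search_iters = 2) {
  stopifnot(inherits(domain, "vasc_domain"), budget >= 0,
            inherits(geo, "geo_params"), inherits(opt, "opt_params"))
  cost <- match.arg(cost)
  if (cost == "sprout" && is.null(coeffs))
    stop("the sprouting cost requires mixture coefficients (sprout_coeffs)")
  if (!is.null(angles)) stopifnot(inherits(angles, "angle_params"))
  if (!is.null(roots)) {
    if (inherits(roots, "root_spec")) roots <- list(roots)
    stopifnot(all(vapply(roots, inherits, TRUE, "root_spec")))
  }
  structure(list(domain = domain, budget = as.integer(budget), geo = geo,
                 opt = opt, angles = angles, cost = cost, coeffs = coeffs,
                 role = role, behaviour = behaviour, density = density,
                 roots = roots, seed_stages = seed_stages, label = label,
                 search_iters = as.integer(search_iters)),
            class = "growth_stage")
}

# fully resolved stage descriptor for the compiled engine
.stage_clist <- function(stage, label = NULL) {
  stopifnot(inherits(stage, "growth_stage"))
  d <- stage$domain
  V_ref <- domain_measure(d)
  l_ref <- if (d$D == 2) sqrt(V_ref / pi) else (3 * V_ref / (4 * pi))^(1 / 3)
  ang <- stage$angles %||%
    list(enabled = FALSE, theta_min = 0, theta_max = 180,
         phi_min = 0, phi_max = 180)
  co <- stage$coeffs %||% sprout_coeffs()
  lab <- label %||% stage$label %||% 1L
  list(domain = .domain_clist(d),
       gamma = stage$geo$gamma,
       delta = unclass(stage$geo$delta),
       nu = stage$opt$nu, f_r = stage$opt$f_r, f_n = stage$opt$f_n,
       delta_v = stage$opt$delta_v, n_fail = stage$opt$n_fail,
       max_attempts = stage$opt$max_attempts,
       angles = list(enabled = isTRUE(ang$enabled),
                     theta_min = ang$theta_min, theta_max = ang$theta_max,
                     phi_min = ang$phi_min, phi_max = ang$phi_max),
       cost = if (stage$cost == "vol") 0L else 1L,
       c_v = co$c_v, c_p = co$c_p, c_d = co$c_d,
       V_ref = V_ref, l_ref = l_ref,
       role = .role_code(stage$role), behaviour = .behaviour_code(stage$behaviour),
       label = as.integer(lab), l_c = characteristic_length(d),
       seed_stages = if (!is.null(stage$seed_stages))
         as.integer(stage$seed_stages),
       density = .density_clist(stage$density),
       search_iters = stage$search_iters, nchecks_frac = 0.1)
}

#' Minimum terminal distance threshold
#'
#' \deqn{l_{lim} = f \; l_c \; (\nu / (N_T + 1))^{1/D}} where `f` is the
#' accumulated relaxation factor. New terminal positions closer than this to
#' the existing forest are rejected, promoting space-filling growth.
#'
#' @param n_terminals current number of terminals N_T.
#' @param l_c characteristic length of the domain (mm).
#' @param D domain dimension (2 or 3).
#' @param nu slender-domain tuning factor.
#' @param relaxation accumulated relaxation factor in (0, 1].
#' @export
distance_threshold <- function(n_terminals, l_c, D, nu = 1, relaxation = 1) {
  stopifnot(l_c > 0, relaxation > 0, relaxation <= 1, D %in% c(2, 3))
  relaxation * l_c * (nu / (n_terminals + 1))^(1 / D)
}

#' Candidate bifurcation lattice
#'
#' Discretises the triangle spanned by the new terminal point and the target
#' vessel's endpoints into a barycentric lattice with `delta_v` points per
#' side, excluding the three vertices: `delta_v (delta_v + 1) / 2 - 3` trial
#' points for versatile vessels. Fixed-behaviour vessels keep only the
#' lattice points on their own axis, distal vessels yield the single distal
#' point, and non-branching vessels yield an empty set. Degenerate
#' (collinear) triangles fall back to the points on the vessel axis.
#'
#' @param x_new new terminal position (mm).
#' @param x_p,x_d endpoints of the target vessel.
#' @param delta_v lattice points per side (>= 3).
#' @param behaviour branching behaviour of the target vessel.
#' @return Matrix of trial points (rows), in the deterministic enumeration
#'   order used for tie-breaking.
#' @export
candidate_lattice <- function(x_new, x_p, x_d, delta_v = 7,
                              behaviour = "versatile") {
  vt_lattice(.pad3(x_new), .pad3(x_p), .pad3(x_d), as.integer(delta_v),
             .behaviour_code(behaviour))
}

#' Optimal connection for a terminal point
#'
#' Enumerates every eligible vessel within the neighbourhood radius
#' `f_n * l_c` of the terminal point and every lattice point of its
#' bifurcation triangle, scores each admissible candidate with the stage's
#' cost functional on a tentatively re-converged state, and returns the
#' feasible candidate of minimum cost (ties resolved by enumeration order).
#'
#' @inheritParams admissible
#' @param x_new accepted terminal position (mm).
#' @return A list describing the best candidate (`found = FALSE` when every
#'   candidate is infeasible, in which case the caller resamples).
#' @export
best_connection <- function(forest, stage, x_new) {
  vt_best_connection(.fptr(forest), .stage_clist(stage), .pad3(x_new))
}

#' Create a root segment for a new inlet
#'
#' Samples terminal points from the stage density until one yields a root
#' segment that satisfies containment (per the root vessel's role), the
#' aspect-ratio constraint, the minimum-distance criterion against other
#' trees, and non-intersection.
#'
#' @inheritParams best_connection
#' @param root a [root_spec()].
#' @return The id of the created root vessel.
#' @export
create_root <- function(forest, stage, root) {
  stopifnot(inherits(root, "root_spec"))
  id <- vt_create_root(.fptr(forest), .stage_clist(stage), root$position,
                       root$radius, root$inflow, .role_code(root$role),
                       .behaviour_code(root$behaviour))
  assign_flows(forest)
  update_radii(forest)
  id
}

#' Execute one growth stage
#'
#' Repeats terminal sampling (with the minimum-distance rejection rule and
#' its failure-driven relaxation), optimal-connection search, commit, and a
#' full-tolerance radius re-convergence, until the stage budget of new
#' terminals is committed. Terminal outflows are re-split after every commit
#' so all vessel flows track the homogeneous-outflow condition. The
#' relaxation accumulator resets after every successful connection.
#'
#' @inheritParams best_connection
#' @param tol,max_iter radius update settings applied after each commit.
#' @return A growth log: attempts, rejection counts, relaxation events and
#'   the ids of the vessels created in this stage.
#' @export
grow_stage <- function(forest, stage, tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(stage, "growth_stage"))
  cl <- .stage_clist(stage)
  if (!is.null(stage$roots))
    for (rs in stage$roots) create_root(forest, stage, rs)
  if (stage$budget == 0) {
    return(invisible(list(terminals_added = 0L, attempts = 0,
                          distance_rejections = 0L, connection_failures = 0L,
                          relaxations = 0L, new_vessels = integer())))
  }
  log <- vt_grow_stage(.fptr(forest), cl, stage$budget, tol,
                       as.integer(max_iter))
  invisible(log)
}

#' Run a sequence of growth stages
#'
#' Stages execute in order on a shared forest; stage t is labelled t and the
#' final forest is the union of all stage trees with the initial tree. Runs
#' are reproducible bit-for-bit for a given configuration and seed.
#'
#' @param stages list of [growth_stage()]s.
#' @param forest optional initial `vascular_forest` (pre-existing anatomy);
#'   a fresh forest is created when omitted.
#' @param seed optional RNG seed.
#' @param tol,max_iter radius update settings.
#' @return A list with the final `forest` and the per-stage growth `logs`.
#' @export
run_stages <- function(stages, forest = NULL, seed = NULL, tol = 1e-6,
                       max_iter = 200) {
  if (inherits(stages, "growth_stage")) stages <- list(stages)
  stopifnot(all(vapply(stages, inherits, TRUE, "growth_stage")))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(forest)) forest <- vascular_forest(gamma = stages[[1]]$geo$gamma)
  logs <- vector("list", length(stages))
  for (t in seq_along(stages)) {
    st <- stages[[t]]
    if (is.null(st$label)) st$label <- t
    logs[[t]] <- grow_stage(forest, st, tol = tol, max_iter = max_iter)
  }
  names(logs) <- vapply(seq_along(stages), function(t)
    as.character(stages[[t]]$label %||% t), character(1))
  list(forest = forest, logs = logs)
}
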