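#' Vascular forests
#'
#' A vascular forest holds one or more rooted N-ary trees of straight
#' cylindrical vessel segments sharing a perfusion domain. Each vessel has
#' proximal/distal endpoints (mm), radius (mm), flow (mm^3/s), a role
#' (distribution, transport or perforator), a branching behaviour
#' (non-branching, distal, fixed or versatile), and the id of the growth
#' stage that created it (0 for pre-existing anatomy). Roots carry a fixed
#' radius and inflow. The object has reference semantics: growth and
#' hemodynamic updates modify it in place.
#'
#' @param gamma Murray bifurcation exponent used by radius updates.
#' @return An object of class `vascular_forest`.
#' @export
vascular_forest <- function(gamma = 3) {
  stopifnot(gamma > 0)
  structure(list(ptr = vt_new_forest(gamma)), class = "vascular_forest")
}

.roles <- c(distribution = 0L, transport = 1L, perforator = 2L)
.behaviours <- c("non-branching" = 0L, distal = 1L, fixed = 2L, versatile = 3L)

.role_code <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  v <- .roles[match.arg(x, names(.roles))]
  unname(v)
}

.behaviour_code <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  v <- .behaviours[match.arg(x, names(.behaviours))]
  unname(v)
}

.fptr <- function(forest) {
  stopifnot(inherits(forest, "vascular_forest"))
  forest$ptr
}

#' @export
print.vascular_forest <- function(x, ...) {
  n <- vt_size(x$ptr)
  nt <- if (n > 0) vt_n_terminals(x$ptr) else 0L
  rt <- vt_roots(x$ptr)
  cat(sprintf("<vascular_forest: %d vessels, %d terminals, %d tree(s), gamma=%g>\n",
              n, nt, length(rt$id), vt_gamma(x$ptr)))
  if (length(rt$id))
    cat(sprintf("  root r1 = %s mm, Q = %s mm^3/s\n",
                paste(signif(rt$radius, 4), collapse = ", "),
                paste(signif(rt$inflow, 4), collapse = ", ")))
  invisible(x)
}

#' Add a root vessel to a forest
#'
#' Each root starts a new tree with a fixed root radius and inflow; the
#' pressure drop across the tree is an output of the model, not a constraint.
#'
#' @param forest a `vascular_forest`.
#' @param from,to proximal and distal endpoints (mm).
#' @param radius fixed root radius r1 (mm).
#' @param inflow root inflow Q (mm^3/s).
#' @param role,behaviour vessel role and branching behaviour.
#' @param stage stage id (0 = pre-existing).
#' @return The new vessel id (invisibly).
#' @export
add_root_vessel <- function(forest, from, to, radius, inflow,
                            role = "distribution", behaviour = "versatile",
                            stage = 0L) {
  id <- vt_add_root(.fptr(forest), .pad3(from), .pad3(to), radius, inflow,
                    .role_code(role), .behaviour_code(behaviour),
                    as.integer(stage))
  invisible(id)
}

#' Add a child vessel under an existing vessel
#'
#' Used to build pre-existing (image-derived) trees; the proximal point must
#' coincide exactly with the parent's distal point. Unary chains represent
#' tortuous vessels; junctions with three or more children are permitted
#' (N-ary trees).
#'
#' @inheritParams add_root_vessel
#' @param parent parent vessel id.
#' @param outlet_fraction if given, marks the vessel as a constrained outlet
#'   carrying this fraction of the total root inflow.
#' @export
add_child_vessel <- function(forest, parent, to, role = "distribution",
                             behaviour = "versatile", stage = 0L,
                             outlet_fraction = NA_real_) {
  tab <- vt_table(.fptr(forest))
  from <- tab$xd[parent, ]
  id <- vt_add_vessel(.fptr(forest), from, .pad3(to), as.integer(parent),
                      .role_code(role), .behaviour_code(behaviour),
                      as.integer(stage), outlet_fraction)
  invisible(id)
}

#' Vessel table of a forest
#'
#' @param forest a `vascular_forest`.
#' @return A data.frame with one row per vessel: endpoints, radius (mm),
#'   flow (mm^3/s), viscosity (cP), length (mm), parent id (NA for roots),
#'   role, behaviour, stage, tree, bifurcation level, number of children,
#'   outlet flag/fraction and terminal flag.
#' @export
vessels <- function(forest) {
  tb <- vt_table(.fptr(forest))
  n <- nrow(tb$xp)
  data.frame(
    id = seq_len(n),
    xp_x = tb$xp[, 1], xp_y = tb$xp[, 2], xp_z = tb$xp[, 3],
    xd_x = tb$xd[, 1], xd_y = tb$xd[, 2], xd_z = tb$xd[, 3],
    radius = tb$radius, flow = tb$flow, viscosity = tb$eta,
    length = tb$length,
    parent = ifelse(tb$parent == 0, NA_integer_, tb$parent),
    role = names(.roles)[tb$role + 1L],
    behaviour = names(.behaviours)[tb$behaviour + 1L],
    stage = tb$stage, tree = tb$tree, level = tb$level,
    n_children = tb$n_children,
    outlet = tb$outlet, outlet_fraction = tb$outlet_fraction,
    terminal = tb$terminal, radius_max = tb$rmax)
}

#' @rdname vessels
#' @export
n_vessels <- function(forest) vt_size(.fptr(forest))

#' @rdname vessels
#' @export
n_terminals <- function(forest) {
  if (n_vessels(forest) == 0) return(0L)
  vt_n_terminals(.fptr(forest))
}

#' @rdname vessels
#' @export
forest_roots <- function(forest) as.data.frame(vt_roots(.fptr(forest)))

#' Deep copy of a forest
#'
#' @inheritParams vessels
#' @export
forest_copy <- function(forest) {
  structure(list(ptr = vt_copy_forest(.fptr(forest))), class = "vascular_forest")
}

#' Tentative terminal insertion and rollback
#'
#' Connecting a terminal point `x_new` to vessel `v` at bifurcation point
#' `x_b` replaces `v` by a proximal segment, a distal segment inheriting the
#' original children, role and behaviour, and the new terminal vessel. When
#' `x_b` equals the distal point of `v` (the only admissible locus for
#' distal-behaviour vessels) no split occurs and the new vessel is appended
#' as an additional child. The returned handle restores the forest
#' bit-identically via [rollback_insertion()].
#'
#' @inheritParams vessels
#' @param vessel target vessel id.
#' @param x_b bifurcation point (mm).
#' @param x_new distal position of the new terminal (mm).
#' @param role,behaviour,stage attributes for the new vessel.
#' @return A handle (list with the pre-insertion snapshot and new ids).
#' @export
insert_terminal <- function(forest, vessel, x_b, x_new,
                            role = "distribution", behaviour = "versatile",
                            stage = NULL) {
  ptr <- .fptr(forest)
  n <- vt_size(ptr)
  if (vessel < 1 || vessel > n) stop("vessel ", vessel, " not in forest")
  tab <- vt_table(ptr)
  x_b <- .pad3(x_b); x_new <- .pad3(x_new)
  distal <- all(x_b == tab$xd[vessel, ])
  beh <- tab$behaviour[vessel]
  if (beh == 1L && !distal)
    stop("distal-behaviour vessels only accept their distal point as x_b")
  if (beh == 2L) {
    a <- tab$xp[vessel, ]; b <- tab$xd[vessel, ]
    d <- vt_segseg_distance(x_b, x_b, a, b)
    if (d > 1e-9 * tab$length[vessel])
      stop("fixed-behaviour vessels only accept x_b on their axis segment")
  }
  if (all(x_new == x_b)) stop("degenerate new vessel: x_new equals x_b")
  snap <- vt_copy_forest(ptr)
  st <- if (is.null(stage)) tab$stage[vessel] else as.integer(stage)
  ids <- vt_commit_candidate(ptr, .insert_stage_clist(.role_code(role),
                                                      .behaviour_code(behaviour),
                                                      st),
                             as.integer(vessel), x_b, x_new, distal)
  list(snapshot = snap, v_p = ids$v_p,
       v_s = if (ids$v_s > 0) ids$v_s else NA_integer_, v_new = ids$v_new)
}

#' @rdname insert_terminal
#' @param handle handle returned by [insert_terminal()].
#' @export
rollback_insertion <- function(forest, handle) {
  vt_restore_forest(.fptr(forest), handle$snapshot)
  invisible(forest)
}

# minimal stage descriptor for structural commits outside the growth loop
.insert_stage_clist <- function(role, behaviour, stage) {
  list(domain = .domain_clist(disc_domain(radius = 1)), gamma = 3,
       delta = list(low = 0, high = 0, level = .Machine$integer.max),
       nu = 1, f_r = 0.9, f_n = 8, delta_v = 7L, n_fail = 100L,
       max_attempts = 1e6,
       angles = list(enabled = FALSE, theta_min = 0, theta_max = 180,
                     phi_min = 0, phi_max = 180),
       cost = 0L, c_v = 0, c_p = 0, c_d = 0, V_ref = 1, l_ref = 1,
       role = role, behaviour = behaviour, label = as.integer(stage),
       l_c = 1, seed_stages = NULL,
       density = .density_clist(uniform_density()),
       search_iters = 2L, nchecks_frac = 0.1)
}

#' Spatial queries on a forest
#'
#' `neighbourhood()` returns all vessels whose segment lies within `radius`
#' of a point; `min_point_distance()` returns the distance from a point to
#' the closest point anywhere on the forest (interior of segments included)
#' together with that closest point.
#'
#' @inheritParams vessels
#' @param x query point (mm).
#' @param radius search radius (mm).
#' @export
neighbourhood <- function(forest, x, radius) {
  stopifnot(radius > 0)
  vt_neighbourhood(.fptr(forest), .pad3(x), radius)
}

#' @rdname neighbourhood
#' @export
min_point_distance <- function(forest, x) {
  vt_min_point_distance(.fptr(forest), .pad3(x))
}

#' Bifurcation level of a vessel
#'
#' The number of junctions with two or more children on the path from the
#' root (the root itself is level 0). Unary chain links representing
#' tortuous vessels do not increment the level.
#'
#' @inheritParams vessels
#' @param vessel vessel id.
#' @export
bifurcation_level <- function(forest, vessel) {
  stopifnot(vessel >= 1, vessel <= n_vessels(forest))
  vt_bif_level(.fptr(forest), as.integer(vessel))
}

#' Declare a constrained outlet
#'
#' Marks a terminal vessel as diverting a prescribed fraction of the total
#' root inflow to territories outside the modelled domain. Constrained
#' outlets are excluded from the equal terminal-outflow split.
#'
#' @inheritParams vessels
#' @param vessel terminal vessel id.
#' @param fraction outflow fraction of the total inflow, in (0, 1).
#' @export
set_outlet <- function(forest, vessel, fraction) {
  vt_set_outlet(.fptr(forest), as.integer(vessel), fraction)
  invisible(forest)
}

#' @rdname vessels
#' @export
children_of <- function(forest, vessel) {
  vt_children(.fptr(forest), as.integer(vessel))
}
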