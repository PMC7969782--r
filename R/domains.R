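#' Perfusion domains
#'
#' A perfusion domain is the closed region \eqn{\Omega} to be vascularised. It
#' carries a spatial dimension `D` (2 or 3), a point-membership predicate, a
#' measure (area in mm^2 for `D = 2`, volume in mm^3 for `D = 3`) and a
#' bounding box used for rejection sampling of terminal positions. 2D domains
#' live in the z = 0 plane of 3D space, so a single vessel representation
#' serves both dimensions; `D` only enters the perfusion-scale formulas.
#' Boundary points count as inside.
#'
#' @param center numeric centre (mm).
#' @param radius,inner,outer radii (mm).
#' @param label optional domain label.
#' @return An object of class `vasc_domain`.
#' @name domains
NULL

.domain <- function(type, D, params, lo, hi, measure, label = NULL,
                    V = NULL, F = NULL, subdomains = NULL) {
  stopifnot(measure > 0)
  structure(list(type = type, D = as.integer(D), params = as.numeric(params),
                 lo = as.numeric(lo), hi = as.numeric(hi),
                 measure = measure, label = label, V = V, F = F,
                 subdomains = subdomains),
            class = "vasc_domain")
}

.pad3 <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 2) x <- c(x, 0)
  if (length(x) != 3) stop("coordinates must have 2 or 3 components")
  x
}

#' @rdname domains
#' @export
disc_domain <- function(center = c(0, 0), radius = 1, label = "disc") {
  c3 <- .pad3(center)
  .domain("disc", 2, c(c3[1], c3[2], radius),
          lo = c(c3[1] - radius, c3[2] - radius, 0),
          hi = c(c3[1] + radius, c3[2] + radius, 0),
          measure = pi * radius^2, label = label)
}

#' @rdname domains
#' @export
annulus_domain <- function(center = c(0, 0), inner = 0.5, outer = 1,
                           label = "annulus") {
  stopifnot(outer > inner, inner >= 0)
  c3 <- .pad3(center)
  .domain("annulus", 2, c(c3[1], c3[2], inner, outer),
          lo = c(c3[1] - outer, c3[2] - outer, 0),
          hi = c(c3[1] + outer, c3[2] + outer, 0),
          measure = pi * (outer^2 - inner^2), label = label)
}

#' @rdname domains
#' @export
sphere_domain <- function(center = c(0, 0, 0), radius = 1, label = "sphere") {
  c3 <- .pad3(center)
  .domain("sphere", 3, c(c3, radius),
          lo = c3 - radius, hi = c3 + radius,
          measure = 4 / 3 * pi * radius^3, label = label)
}

#' @rdname domains
#' @export
shell_domain <- function(center = c(0, 0, 0), inner = 0.5, outer = 1,
                         label = "shell") {
  stopifnot(outer > inner, inner >= 0)
  c3 <- .pad3(center)
  .domain("shell", 3, c(c3, inner, outer),
          lo = c3 - outer, hi = c3 + outer,
          measure = 4 / 3 * pi * (outer^3 - inner^3), label = label)
}

#' @rdname domains
#' @param lower,upper opposite corners of an axis-aligned box (mm).
#' @export
box_domain <- function(lower = c(0, 0, 0), upper = c(1, 1, 1), label = "box") {
  lo <- .pad3(lower); hi <- .pad3(upper)
  stopifnot(all(hi >= lo))
  D <- if (hi[3] == lo[3]) 2L else 3L
  measure <- if (D == 2) prod((hi - lo)[1:2]) else prod(hi - lo)
  .domain("box", D, c(lo, hi), lo = lo, hi = hi, measure = measure, label = label)
}

#' @rdname domains
#' @param ... member domains.
#' @param overlap set to `TRUE` when members may overlap; the measure is then
#'   estimated by Monte-Carlo instead of summing member measures.
#' @export
union_domain <- function(..., overlap = FALSE, label = "union") {
  subs <- list(...)
  stopifnot(length(subs) >= 1, all(vapply(subs, inherits, TRUE, "vasc_domain")))
  D <- max(vapply(subs, `[[`, 1L, "D"))
  lo <- do.call(pmin, lapply(subs, `[[`, "lo"))
  hi <- do.call(pmax, lapply(subs, `[[`, "hi"))
  d <- .domain("union", D, numeric(), lo, hi,
               measure = sum(vapply(subs, `[[`, 1, "measure")), label = label,
               subdomains = subs)
  if (overlap) d$measure <- .mc_measure(d)
  d
}

#' Surface-mesh domain
#'
#' A watertight closed triangulated surface defines a 3D domain; membership is
#' decided by parity ray casting and the volume by the divergence theorem on
#' the mesh.
#'
#' @param path path to an ASCII STL, OBJ or PLY file (alternative to
#'   `vertices`/`faces`).
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based triangle vertex indices.
#' @inheritParams domains
#' @export
mesh_domain <- function(path = NULL, vertices = NULL, faces = NULL,
                        label = "mesh") {
  if (!is.null(path)) {
    m <- read_surface_mesh(path)
    vertices <- m$vertices; faces <- m$faces
  }
  stopifnot(is.matrix(vertices), ncol(vertices) == 3,
            is.matrix(faces), ncol(faces) == 3)
  vol <- vt_mesh_volume(vertices, faces)
  .domain("mesh", 3, numeric(),
          lo = apply(vertices, 2, min), hi = apply(vertices, 2, max),
          measure = vol, label = label, V = vertices,
          F = matrix(as.integer(faces), ncol = 3))
}

#' Extruded-shell domain around a surface
#'
#' A thin volumetric shell obtained by offsetting a closed surface inward and
#' outward, used to grow networks constrained to organ surfaces (e.g. a pial
#' shell over a cortical mesh).
#'
#' @inheritParams mesh_domain
#' @param inward,outward offsets in mm (both non-negative, not both zero).
#' @export
extruded_shell_domain <- function(path = NULL, vertices = NULL, faces = NULL,
                                  inward = 0, outward = 1,
                                  label = "extruded_shell") {
  stopifnot(inward >= 0, outward >= 0, inward + outward > 0)
  if (!is.null(path)) {
    m <- read_surface_mesh(path)
    vertices <- m$vertices; faces <- m$faces
  }
  pad <- outward
  d <- .domain("extruded_shell", 3, c(inward, outward),
               lo = apply(vertices, 2, min) - pad,
               hi = apply(vertices, 2, max) + pad,
               measure = 1, label = label, V = vertices,
               F = matrix(as.integer(faces), ncol = 3))
  d$measure <- .mc_measure(d)
  d
}

# Monte-Carlo measure of a domain from its bounding box, on a private RNG
# stream so domain construction does not consume the user's seed
.mc_measure <- function(d, n = 2e5) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(948301L)
  k <- if (d$D == 2) 2L else 3L
  X <- matrix(0, n, 3)
  for (j in seq_len(k))
    X[, j] <- stats::runif(n, d$lo[j], d$hi[j])
  inside <- vt_domain_contains(.domain_clist(d), X)
  box <- prod((d$hi - d$lo)[seq_len(k)])
  m <- mean(inside) * box
  if (m <= 0) stop("domain has zero Monte-Carlo measure")
  m
}

# descriptor list handed to the compiled membership/sampling routines
.domain_clist <- function(d) {
  stopifnot(inherits(d, "vasc_domain"))
  list(type = d$type, D = d$D, params = d$params, lo = d$lo, hi = d$hi,
       V = d$V, F = d$F,
       subdomains = if (!is.null(d$subdomains))
         lapply(d$subdomains, .domain_clist))
}

#' @export
print.vasc_domain <- function(x, ...) {
  cat(sprintf("<vasc_domain '%s': %s, D=%d, measure %.6g mm^%d, l_c %.6g mm>\n",
              x$label %||% "", x$type, x$D, x$measure, x$D,
              characteristic_length(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Domain measure and characteristic length
#'
#' The characteristic length is the equivalent-disc radius
#' \eqn{\sqrt{A/\pi}} for `D = 2` and the equivalent-sphere radius
#' \eqn{(3V/(4\pi))^{1/3}} for `D = 3`. It represents the expected perfusion
#' radius per terminal and scales the minimum-distance criterion and the
#' connection-search neighbourhood.
#'
#' @param domain a `vasc_domain`.
#' @return Length in mm.
#' @export
characteristic_length <- function(domain) {
  stopifnot(inherits(domain, "vasc_domain"))
  if (!(domain$measure > 0)) stop("domain has zero measure")
  if (domain$D == 2) sqrt(domain$measure / pi)
  else (3 * domain$measure / (4 * pi))^(1 / 3)
}

#' @rdname characteristic_length
#' @export
domain_measure <- function(domain) {
  stopifnot(inherits(domain, "vasc_domain"))
  domain$measure
}

#' Point membership in a domain
#'
#' @param domain a `vasc_domain`.
#' @param x a coordinate vector or an n x 2/3 matrix of points (mm).
#' @return Logical (one value per point). The closed region convention is
#'   used: boundary points are inside.
#' @export
domain_contains <- function(domain, x) {
  stopifnot(inherits(domain, "vasc_domain"))
  if (!is.matrix(x)) x <- matrix(.pad3(x), 1)
  if (ncol(x) == 2) x <- cbind(x, 0)
  if (ncol(x) != 3) stop("points must have 2 or 3 coordinates")
  if (domain$D == 2 && any(x[, 3] != 0))
    stop("dimension mismatch: 3D point queried against a 2D domain")
  vt_domain_contains(.domain_clist(domain), x)
}

#' Segment containment
#'
#' Checks that `n_checks` equally spaced points along the segment (endpoints
#' included) all lie inside the domain. The default resolution ties the check
#' spacing to a tenth of the domain's characteristic length.
#'
#' @inheritParams domain_contains
#' @param a,b segment endpoints (mm).
#' @param n_checks number of membership checks (>= 2).
#' @export
segment_in_domain <- function(domain, a, b, n_checks = NULL) {
  a <- .pad3(a); b <- .pad3(b)
  if (is.null(n_checks)) {
    l <- sqrt(sum((b - a)^2))
    n_checks <- max(2, ceiling(l / (0.1 * characteristic_length(domain))) + 1)
  }
  if (n_checks < 2) stop("n_checks must be at least 2")
  vt_segment_in_domain(.domain_clist(domain), a, b, as.integer(n_checks))
}

# ------------------------------------------------------------------ densities

#' Terminal-placement densities
#'
#' The distal positions of new terminals are drawn from a spatial probability
#' density restricted to the domain; regions of higher density receive a
#' proportionally higher share of the perfusion. Supported densities are
#' uniform, Gaussian, Gaussian mixtures, and arbitrary non-negative functions
#' (sampled by bounded rejection).
#'
#' @param mean,sd per-axis mean and standard deviation (mm); 2D densities use
#'   two components.
#' @param means,sds lists of per-component means/sds for mixtures.
#' @param weights mixture weights (re-normalised).
#' @param fn function taking a length-3 coordinate and returning a
#'   non-negative density value.
#' @param pmax upper bound of `fn` over the domain (rejection envelope).
#' @return An object of class `vasc_density`.
#' @name densities
NULL

#' @rdname densities
#' @export
uniform_density <- function() {
  structure(list(type = "uniform"), class = "vasc_density")
}

#' @rdname densities
#' @export
gaussian_density <- function(mean = c(0, 0), sd = c(1, 1)) {
  structure(list(type = "gaussian",
                 mean = matrix(.pad3(mean), 1),
                 sd = matrix(.pad3(sd), 1),
                 weights = 1),
            class = "vasc_density")
}

#' @rdname densities
#' @export
mixture_density <- function(means, sds, weights = NULL) {
  stopifnot(length(means) == length(sds))
  if (is.null(weights)) weights <- rep(1, length(means))
  stopifnot(length(weights) == length(means), all(weights >= 0), sum(weights) > 0)
  structure(list(type = "mixture",
                 mean = do.call(rbind, lapply(means, .pad3)),
                 sd = do.call(rbind, lapply(sds, .pad3)),
                 weights = as.numeric(weights)),
            class = "vasc_density")
}

#' @rdname densities
#' @export
function_density <- function(fn, pmax) {
  stopifnot(is.function(fn), pmax > 0)
  structure(list(type = "function", fn = fn, pmax = pmax),
            class = "vasc_density")
}

.density_clist <- function(d) {
  stopifnot(inherits(d, "vasc_density"))
  unclass(d)
}

#' Sample terminal positions from a density restricted to a domain
#'
#' Rejection sampling against the domain (uniform and user-function densities
#' use the bounding box as the proposal). An acceptance rate below the floor
#' signals a degenerate density/domain pair and raises an error.
#'
#' @inheritParams domain_contains
#' @param density a `vasc_density` (default uniform).
#' @param n number of points.
#' @param floor minimum tolerated acceptance rate.
#' @return n x 3 matrix of points inside the domain (z = 0 for 2D domains).
#' @export
sample_point <- function(domain, density = uniform_density(), n = 1,
                         floor = 1e-6) {
  stopifnot(inherits(domain, "vasc_domain"), n >= 1)
  vt_sample_points(.domain_clist(domain), .density_clist(density),
                   as.integer(n), as.integer(min(2^31 - 1, ceiling(1 / floor))))
}
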