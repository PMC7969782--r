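#' Interchange table of a forest
#'
#' The interchange format is a flat parent-pointer table: one row per vessel
#' with id, parent id (NA for roots), endpoints (mm), radius (mm), flow
#' (mm^3/s), role, behaviour, stage label, bifurcation level, the optional
#' constrained-outlet fraction, and root radius/inflow on root rows. The
#' flat table supports N-ary trees, unary chains and atlas-style imports
#' without a bespoke parser.
#'
#' @inheritParams vessels
#' @param canonical if `TRUE` (default) rows are emitted in preorder (each
#'   parent before its children, trees in order) and renumbered
#'   sequentially, which makes write-then-read the identity; `canonical =
#'   FALSE` keeps the forest's internal vessel order and ids.
#' @export
forest_to_table <- function(forest, canonical = TRUE) {
  v <- vessels(forest)
  rt <- forest_roots(forest)
  v$root_radius <- NA_real_
  v$root_inflow <- NA_real_
  v$root_radius[rt$id] <- rt$radius
  v$root_inflow[rt$id] <- rt$inflow
  v$outlet_fraction[!v$outlet] <- NA_real_
  if (canonical && nrow(v) > 0) {
    ord <- integer(0)
    for (r0 in rt$id) {
      stack <- r0
      while (length(stack)) {
        i <- stack[[1]]
        stack <- c(children_of(forest, i), stack[-1])
        ord <- c(ord, i)
      }
    }
    v <- v[ord, ]
    remap <- integer(nrow(v))
    remap[ord] <- seq_len(nrow(v))
    v$id <- seq_len(nrow(v))
    v$parent <- ifelse(is.na(v$parent), NA_integer_, remap[v$parent])
    rownames(v) <- NULL
  }
  v[c("id", "parent", "xp_x", "xp_y", "xp_z", "xd_x", "xd_y", "xd_z",
      "radius", "flow", "role", "behaviour", "stage", "level",
      "outlet_fraction", "root_radius", "root_inflow")]
}

#' @rdname forest_to_table
#' @param table a data.frame in the interchange layout.
#' @param gamma Murray exponent for the rebuilt forest.
#' @param update if `TRUE`, re-run flow assignment and the radius update
#'   after rebuilding.
#' @export
forest_from_table <- function(table, gamma = 3, update = TRUE) {
  req <- c("id", "parent", "xp_x", "xp_y", "xp_z", "xd_x", "xd_y", "xd_z")
  miss <- setdiff(req, names(table))
  if (length(miss)) stop("interchange table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(table$id)) stop("duplicate vessel ids in interchange table")
  orphan <- !is.na(table$parent) & !(table$parent %in% table$id)
  if (any(orphan))
    stop("unresolvable parent id for vessel(s) ",
         paste(table$id[orphan], collapse = ", "))
  f <- vascular_forest(gamma = gamma)
  # insert parents before children; map external ids to internal ids
  ord <- integer(0)
  placed <- rep(FALSE, nrow(table))
  repeat {
    ready <- !placed & (is.na(table$parent) | table$parent %in% table$id[placed])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) stop("interchange table contains a parent cycle")
  idmap <- integer(nrow(table))
  names(idmap) <- as.character(table$id)
  for (k in ord) {
    row <- table[k, ]
    role <- if ("role" %in% names(table)) row$role else "distribution"
    beh <- if ("behaviour" %in% names(table)) row$behaviour else "versatile"
    stg <- if ("stage" %in% names(table)) row$stage else 0L
    if (is.na(row$parent)) {
      if (is.null(table$root_radius) || is.na(row$root_radius) ||
          is.null(table$root_inflow) || is.na(row$root_inflow))
        stop("root vessel ", row$id, " lacks root_radius/root_inflow")
      id <- add_root_vessel(f, c(row$xp_x, row$xp_y, row$xp_z),
                            c(row$xd_x, row$xd_y, row$xd_z),
                            radius = row$root_radius, inflow = row$root_inflow,
                            role = role, behaviour = beh, stage = stg)
    } else {
      frac <- if ("outlet_fraction" %in% names(table)) row$outlet_fraction
              else NA_real_
      id <- add_child_vessel(f, idmap[[as.character(row$parent)]],
                             c(row$xd_x, row$xd_y, row$xd_z),
                             role = role, behaviour = beh, stage = stg,
                             outlet_fraction = frac)
    }
    idmap[[as.character(row$id)]] <- id
  }
  if ("radius" %in% names(table) || "flow" %in% names(table)) {
    vt_restore_state(.fptr(f), unname(idmap[as.character(table$id)]),
                     if (is.null(table$radius)) rep(NA_real_, nrow(table))
                     else table$radius,
                     if (is.null(table$flow)) rep(NA_real_, nrow(table))
                     else table$flow)
  }
  if (update && n_vessels(f) > 0) {
    assign_flows(f)
    update_radii(f)
  }
  f
}

#' Read and write vascular trees
#'
#' CSV and JSON carry the interchange table (lossless round trip); `vtk`
#' writes legacy ASCII VTK polydata with per-cell radius, flow, stage,
#' bifurcation level and tree attributes for rendering (e.g. in ParaView).
#' Coordinates are absolute mm, always 3D (2D trees in the z = 0 plane).
#'
#' @inheritParams vessels
#' @param path file path; the format is inferred from the extension unless
#'   given explicitly.
#' @param format one of `"csv"`, `"json"`, `"vtk"`.
#' @export
write_tree <- function(forest, path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  tab <- forest_to_table(forest)
  switch(format,
         csv = utils::write.csv(tab, path, row.names = FALSE),
         json = jsonlite::write_json(tab, path, dataframe = "columns",
                                     digits = NA, na = "null"),
         vtk = write_vtk(forest, path),
         stop("unsupported tree format '", format, "'"))
  invisible(path)
}

#' @rdname write_tree
#' @inheritParams forest_from_table
#' @export
read_tree <- function(path, format = NULL, gamma = 3, update = TRUE) {
  format <- format %||% tolower(tools::file_ext(path))
  tab <- switch(format,
                csv = utils::read.csv(path),
                json = as.data.frame(jsonlite::read_json(path,
                                                         simplifyVector = TRUE)),
                stop("unsupported tree format '", format, "'"))
  forest_from_table(tab, gamma = gamma, update = update)
}

#' @rdname write_tree
#' @export
write_vtk <- function(forest, path) {
  v <- vessels(forest)
  # merge coincident endpoints so chains and junctions connect
  pts <- rbind(as.matrix(v[c("xp_x", "xp_y", "xp_z")]),
               as.matrix(v[c("xd_x", "xd_y", "xd_z")]))
  key <- apply(pts, 1, paste, collapse = " ")
  uk <- !duplicated(key)
  upts <- pts[uk, , drop = FALSE]
  idx <- match(key, key[uk]) - 1L
  n <- nrow(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "vasctree vascular forest", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(upts))), con)
  writeLines(apply(format(upts, digits = 17, scientific = TRUE, trim = TRUE),
                   1, paste, collapse = " "), con)
  writeLines(sprintf("LINES %d %d", n, 3L * n), con)
  writeLines(sprintf("2 %d %d", idx[seq_len(n)], idx[n + seq_len(n)]), con)
  writeLines(sprintf("CELL_DATA %d", n), con)
  scalar <- function(name, x, type = "double") {
    writeLines(c(sprintf("SCALARS %s %s 1", name, type),
                 "LOOKUP_TABLE default",
                 format(x, digits = 17, scientific = TRUE, trim = TRUE)), con)
  }
  scalar("radius", v$radius)
  scalar("flow", v$flow)
  scalar("stage", v$stage, "int")
  scalar("level", v$level, "int")
  scalar("tree", v$tree, "int")
  invisible(path)
}

# ------------------------------------------------------------- mesh readers

#' Read a triangulated surface mesh
#'
#' Minimal readers for ASCII STL, OBJ and PLY files (triangular faces).
#'
#' @param path file path; format from the extension.
#' @return List with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @export
read_surface_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = .read_stl(path),
         obj = .read_obj(path),
         ply = .read_ply(path),
         stop("unsupported mesh format '", ext, "'"))
}

.read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("no ASCII STL vertices found in ", path)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  key <- apply(nums, 1, paste, collapse = " ")
  uk <- !duplicated(key)
  verts <- nums[uk, , drop = FALSE]
  faces <- matrix(match(key, key[uk]), ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- strsplit(trimws(grep("^v\\s", lines, value = TRUE)), "\\s+")
  fl <- strsplit(trimws(grep("^f\\s", lines, value = TRUE)), "\\s+")
  verts <- do.call(rbind, lapply(vl, function(p) as.numeric(p[2:4])))
  faces <- do.call(rbind, lapply(fl, function(p)
    as.integer(sub("/.*", "", p[2:4]))))
  list(vertices = verts, faces = faces)
}

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file: ", path)
  endh <- grep("^end_header", lines)[1]
  nv <- as.integer(sub(".*vertex\\s+", "", grep("element vertex", lines,
                                                value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("element face", lines,
                                              value = TRUE)[1]))
  vrows <- strsplit(trimws(lines[endh + seq_len(nv)]), "\\s+")
  frows <- strsplit(trimws(lines[endh + nv + seq_len(nf)]), "\\s+")
  verts <- do.call(rbind, lapply(vrows, function(p) as.numeric(p[1:3])))
  faces <- do.call(rbind, lapply(frows, function(p) as.integer(p[2:4]) + 1L))
  list(vertices = verts, faces = faces)
}

# ------------------------------------------------------------- configuration

.cfg_err <- function(errors, fmt, ...) c(errors, sprintf(fmt, ...))

.parse_cfg_domain <- function(x, errors) {
  make <- function() {
    shape <- x$shape %||% x$type
    switch(shape,
           disc = disc_domain(unlist(x$center %||% c(0, 0)), x$radius %||% 1),
           annulus = annulus_domain(unlist(x$center %||% c(0, 0)),
                                    x$inner, x$outer),
           sphere = sphere_domain(unlist(x$center %||% c(0, 0, 0)),
                                  x$radius %||% 1),
           shell = shell_domain(unlist(x$center %||% c(0, 0, 0)),
                                x$inner, x$outer),
           box = box_domain(unlist(x$lower), unlist(x$upper)),
           mesh = mesh_domain(path = x$path),
           extruded_shell = extruded_shell_domain(path = x$path,
                                                  inward = x$inward %||% 0,
                                                  outward = x$outward %||% 1),
           stop("unknown domain shape '", shape, "'"))
  }
  tryCatch(list(value = make(), errors = errors),
           error = function(e) list(value = NULL,
                                    errors = .cfg_err(errors, "domain: %s",
                                                      conditionMessage(e))))
}

.parse_cfg_density <- function(x) {
  if (is.null(x)) return(uniform_density())
  switch(x$type %||% "uniform",
         uniform = uniform_density(),
         gaussian = gaussian_density(unlist(x$mean), unlist(x$sd)),
         mixture = mixture_density(lapply(x$means, unlist),
                                   lapply(x$sds, unlist),
                                   unlist(x$weights %||% NULL)),
         stop("unknown density type '", x$type, "'"))
}

#' Load a stage-sequence configuration
#'
#' Reads a YAML (or JSON) configuration describing a sequence of growth
#' stages: per-stage domain, geometrical parameters (including a piecewise
#' level-dependent symmetry bound), optimisation parameters, angle windows,
#' terminal budget, cost functional with sprouting coefficients, generated
#' vessel type, placement density, new inlets and parent-stage restriction.
#' All violations are collected and reported together.
#'
#' @param path configuration file.
#' @return List with `stages` (list of [growth_stage()]) and `seed` if set.
#' @export
load_config <- function(path) {
  cfg <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path) else yaml::read_yaml(path)
  if (is.null(cfg$stages)) stop("configuration lacks a 'stages' list")
  errors <- character()
  known_stage <- c("label", "domain", "geo", "opt", "angles", "budget", "cost",
                   "coeffs", "vessel", "density", "roots", "seed_stages",
                   "search_iters")
  stages <- vector("list", length(cfg$stages))
  for (t in seq_along(cfg$stages)) {
    s <- cfg$stages[[t]]
    unk <- setdiff(names(s), known_stage)
    if (length(unk))
      errors <- .cfg_err(errors, "stage %d: unknown key(s) %s", t,
                         paste(unk, collapse = ", "))
    pd <- .parse_cfg_domain(s$domain %||% list(), errors)
    errors <- pd$errors
    geo <- tryCatch({
      g <- s$geo %||% list()
      del <- g$delta %||% 0
      if (is.list(del)) del <- delta_map(del$low, del$high, del$level)
      geo_params(gamma = g$gamma %||% 3, delta = del)
    }, error = function(e) {
      errors <<- .cfg_err(errors, "stage %d geo: %s", t, conditionMessage(e))
      NULL
    })
    opt <- tryCatch({
      o <- s$opt %||% list()
      opt_params(nu = o$nu %||% 1, f_r = o$f_r %||% 0.9, f_n = o$f_n %||% 8,
                 delta_v = o$delta_v %||% 7, n_fail = o$n_fail %||% 100,
                 max_attempts = o$max_attempts %||% 1e6)
    }, error = function(e) {
      errors <<- .cfg_err(errors, "stage %d opt: %s", t, conditionMessage(e))
      NULL
    })
    ang <- if (!is.null(s$angles))
      tryCatch(angle_params(theta_min = s$angles$theta_min %||% 0,
                            theta_max = s$angles$theta_max,
                            phi_min = s$angles$phi_min %||% 0,
                            phi_max = s$angles$phi_max),
               error = function(e) {
                 errors <<- .cfg_err(errors, "stage %d angles: %s", t,
                                     conditionMessage(e))
                 NULL
               })
    cost <- s$cost %||% "vol"
    co <- NULL
    if (is.list(cost)) {
      co <- sprout_coeffs(cost$c_v %||% 1, cost$c_p %||% 0.5, cost$c_d %||% 1)
      cost <- cost$name
    }
    roots <- NULL
    if (!is.null(s$roots))
      roots <- lapply(s$roots, function(r)
        root_spec(unlist(r$position), r$radius, r$inflow,
                  role = r$role %||% "distribution",
                  behaviour = r$behaviour %||% "versatile"))
    if (is.null(s$budget) || s$budget < 0)
      errors <- .cfg_err(errors, "stage %d: missing or negative budget", t)
    if (!is.null(pd$value) && !is.null(geo) && !is.null(opt) &&
        length(errors) == 0) {
      stages[[t]] <- growth_stage(
        domain = pd$value, budget = s$budget, geo = geo, opt = opt,
        angles = ang, cost = cost, coeffs = co,
        role = s$vessel$role %||% "distribution",
        behaviour = s$vessel$behaviour %||% "versatile",
        density = .parse_cfg_density(s$density), roots = roots,
        seed_stages = if (!is.null(s$seed_stages)) unlist(s$seed_stages),
        label = s$label %||% t,
        search_iters = s$search_iters %||% 2)
    }
  }
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  list(stages = stages, seed = cfg$seed)
}
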