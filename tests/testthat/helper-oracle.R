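# Independent reference implementations used as test oracles. These are
# deliberately plain-R re-derivations (direct formulas, no shared caches)
# of the quantities the compiled engine computes incrementally.

orc_dist_point_seg <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- if (L2 > 0) max(0, min(1, sum((p - a) * ab) / L2)) else 0
  sqrt(sum((p - (a + t * ab))^2))
}

orc_dist_seg_seg <- function(a0, a1, b0, b1) {
  # exact clamped closest approach between two segments
  u <- a1 - a0; v <- b1 - b0; w <- a0 - b0
  A <- sum(u * u); B <- sum(u * v); C <- sum(v * v)
  D <- sum(u * w); E <- sum(v * w)
  den <- A * C - B * B
  if (den <= 1e-14 * A * C || A == 0 || C == 0) {
    return(min(orc_dist_point_seg(a0, b0, b1), orc_dist_point_seg(a1, b0, b1),
               orc_dist_point_seg(b0, a0, a1), orc_dist_point_seg(b1, a0, a1)))
  }
  s <- max(0, min(1, (B * E - C * D) / den))
  t <- (B * s + E) / C
  if (t < 0) {
    t <- 0; s <- max(0, min(1, -D / A))
  } else if (t > 1) {
    t <- 1; s <- max(0, min(1, (B - D) / A))
  }
  sqrt(sum((a0 + s * u - b0 - t * v)^2))
}

# Full fixed-point radius computation from a vessel table.
# tab: data.frame with id, parent (NA for roots), length, flow columns and
# root rows carrying root_radius; eta_fixed freezes the viscosity.
orc_radii <- function(tab, gamma = 3, tol = 1e-10, max_iter = 500,
                      eta_fixed = NULL) {
  n <- nrow(tab)
  kids <- lapply(tab$id, function(i) tab$id[!is.na(tab$parent) & tab$parent == i])
  idx <- match(tab$id, tab$id)
  post <- integer(0)
  visit <- function(i) {
    for (c in kids[[match(i, tab$id)]]) visit(c)
    post <<- c(post, i)
  }
  for (rt in tab$id[is.na(tab$parent)]) visit(rt)
  eta <- if (is.null(eta_fixed)) rep(3.6, n) else
    if (length(eta_fixed) == 1) rep(eta_fixed, n) else eta_fixed
  r <- rep(0, n)
  Rstar <- rep(0, n)
  for (it in seq_len(max_iter)) {
    beta <- vector("list", n)
    for (i in post) {
      k <- match(i, tab$id)
      C <- 8 * (eta[k] * 1e-3) * tab$length[k] / pi
      ch <- kids[[k]]
      if (!length(ch)) {
        Rstar[k] <- C
      } else {
        km <- match(ch, tab$id)
        tc <- (tab$flow[km] * Rstar[km])^(1 / 4)
        be <- tc / sum(tc^gamma)^(1 / gamma)
        beta[[k]] <- be
        Rstar[k] <- C + 1 / sum(be^4 / Rstar[km])
      }
    }
    rold <- r
    # explicit preorder from each root
    for (rt in tab$id[is.na(tab$parent)]) {
      stack <- rt
      while (length(stack)) {
        i <- stack[[1]]
        stack <- stack[-1]
        k <- match(i, tab$id)
        if (is.na(tab$parent[k])) r[k] <- tab$root_radius[k]
        ch <- kids[[k]]
        if (length(ch)) {
          km <- match(ch, tab$id)
          r[km] <- r[k] * beta[[k]]
          stack <- c(stack, ch)
        }
      }
    }
    if (is.null(eta_fixed)) eta <- as.numeric(blood_viscosity(r))
    if (max(abs(r - rold) / pmax(rold, 1e-300)) < tol && it > 1) break
  }
  list(radius = r, Rstar = Rstar, eta = eta,
       volume = sum(pi * r^2 * tab$length))
}

# assign flows on a table: constrained outlets carry fraction * Q_total,
# free leaves share the remainder equally; internal rows sum their children
orc_flows <- function(tab) {
  kids <- lapply(tab$id, function(i) tab$id[!is.na(tab$parent) & tab$parent == i])
  leaf <- lengths(kids) == 0
  Q <- sum(tab$root_inflow, na.rm = TRUE)
  ofr <- if ("outlet_fraction" %in% names(tab)) tab$outlet_fraction else
    rep(NA_real_, nrow(tab))
  isout <- leaf & !is.na(ofr) & ofr > 0
  qf <- (Q - sum(ofr[isout]) * Q) / sum(leaf & !isout)
  q <- rep(NA_real_, nrow(tab))
  q[leaf] <- ifelse(isout[leaf], ofr[leaf] * Q, qf)
  repeat {
    todo <- which(is.na(q))
    if (!length(todo)) break
    for (k in todo) {
      km <- match(kids[[k]], tab$id)
      if (!anyNA(q[km])) q[k] <- sum(q[km])
    }
  }
  q
}

# Exhaustive full-recompute optimal connection search mirroring the engine's
# feasibility gate but recomputing every candidate tree from scratch.
orc_best_connection <- function(forest, stage, x_t) {
  v <- vessels(forest)
  tab <- forest_to_table(forest, canonical = FALSE)
  d <- stage$domain
  l_c <- characteristic_length(d)
  gamma <- stage$geo$gamma
  dv <- stage$opt$delta_v
  x_t <- c(x_t, 0)[1:3]
  best <- NULL
  vol0 <- tree_volume(forest)
  for (j in v$id) {
    a <- c(v$xp_x[j], v$xp_y[j], v$xp_z[j])
    b <- c(v$xd_x[j], v$xd_y[j], v$xd_z[j])
    if (orc_dist_point_seg(x_t, a, b) > stage$opt$f_n * l_c) next
    if (v$behaviour[j] == "non-branching") next
    pts <- candidate_lattice(x_t, a, b, dv, v$behaviour[j])
    if (!nrow(pts)) next
    for (p in seq_len(nrow(pts))) {
      xb <- pts[p, ]
      distal <- all(xb == b)
      cand <- orc_eval(forest, v, tab, stage, j, xb, x_t, distal, gamma, vol0)
      if (is.null(cand)) next
      if (is.null(best) || cand$cost < best$cost) best <- cand
    }
  }
  best
}

# build the candidate tree as a table, fully re-converge, apply the gate
orc_eval <- function(forest, v, tab, stage, j, xb, x_t, distal, gamma, vol0) {
  nid <- max(tab$id) + c(1, 2)
  t2 <- tab
  if (distal) {
    new <- tab[j, ]
    new$id <- nid[1]
    new$parent <- tab$id[j]
    new[c("xp_x", "xp_y", "xp_z")] <- as.list(xb)
    new[c("xd_x", "xd_y", "xd_z")] <- as.list(x_t)
    new$outlet_fraction <- NA_real_
    new$root_radius <- NA_real_
    t2 <- rbind(t2, new)
    ids <- list(v_p = NA, v_s = tab$id[j], v_new = nid[1])
  } else {
    vs <- tab[j, ]
    vs$id <- nid[1]
    vs$parent <- tab$id[j]
    vs[c("xp_x", "xp_y", "xp_z")] <- as.list(xb)
    vs$root_radius <- NA_real_
    t2$outlet_fraction[j] <- NA_real_
    t2[j, c("xd_x", "xd_y", "xd_z")] <- as.list(xb)
    t2$parent[!is.na(t2$parent) & t2$parent == tab$id[j]] <- nid[1]
    new <- tab[j, ]
    new$id <- nid[2]
    new$parent <- tab$id[j]
    new[c("xp_x", "xp_y", "xp_z")] <- as.list(xb)
    new[c("xd_x", "xd_y", "xd_z")] <- as.list(x_t)
    new$outlet_fraction <- NA_real_
    new$root_radius <- NA_real_
    t2 <- rbind(t2, vs, new)
    ids <- list(v_p = tab$id[j], v_s = nid[1], v_new = nid[2])
  }
  t2$length <- sqrt((t2$xd_x - t2$xp_x)^2 + (t2$xd_y - t2$xp_y)^2 +
                    (t2$xd_z - t2$xp_z)^2)
  if (any(t2$length == 0)) return(NULL)
  t2$flow <- orc_flows(t2)
  sol <- orc_radii(t2, gamma = gamma)
  t2$radius <- sol$radius

  kp <- if (distal) j else match(tab$id[j], t2$id)
  ks <- match(ids$v_s, t2$id)
  kn <- match(ids$v_new, t2$id)
  # aspect for the new trio and for the re-scaled root path (the engine
  # rejects connections whose reshaped tree violates the aspect constraint)
  trio <- if (distal) kn else c(kp, ks, kn)
  if (any(t2$length[trio] / t2$radius[trio] <= 2.02)) return(NULL)
  anc <- t2$parent[kp]
  while (!is.na(anc)) {
    ka <- match(anc, t2$id)
    if (t2$length[ka] / t2$radius[ka] <= 2.02) return(NULL)
    anc <- t2$parent[ka]
  }
  # bifurcation-site containment by the parent's role
  if (v$role[j] %in% c("distribution", "perforator") &&
      !domain_contains(stage$domain, xb)) return(NULL)
  # symmetry at the new junction
  delta <- stage$geo$delta
  deff <- if (v$level[j] < delta$level) delta$low else delta$high
  if (deff > 0 && !distal) {
    if (min(t2$radius[c(ks, kn)]) / max(t2$radius[c(ks, kn)]) <= deff)
      return(NULL)
  }
  # angles
  if (!is.null(stage$angles) && !distal) {
    a <- c(v$xp_x[j], v$xp_y[j], v$xp_z[j])
    b <- c(v$xd_x[j], v$xd_y[j], v$xd_z[j])
    th <- bifurcation_angle(xb, b, x_t)
    if (th <= stage$angles$theta_min || th >= stage$angles$theta_max)
      return(NULL)
    ph <- tryCatch(opening_angle(xb, a, b, x_t), error = function(e) NULL)
    if (!is.null(ph) &&
        (ph <= stage$angles$phi_min || ph >= stage$angles$phi_max))
      return(NULL)
  }
  # new-segment containment by the stage's vessel type
  if (stage$role == "distribution" &&
      !segment_in_domain(stage$domain, xb, x_t)) return(NULL)
  if (stage$role == "perforator" &&
      !domain_contains(stage$domain, x_t)) return(NULL)
  # cylinder clash of v_new: the whole overlap interval is examined with
  # the arc-length junction exemption (5% clearance margin, as the engine)
  l_new <- t2$length[kn]
  l_pj <- if (distal) v$length[j] else
    sqrt(sum((xb - c(v$xp_x[j], v$xp_y[j], v$xp_z[j]))^2))
  for (o in setdiff(v$id, j)) {
    o0 <- c(v$xp_x[o], v$xp_y[o], v$xp_z[o])
    o1 <- c(v$xd_x[o], v$xd_y[o], v$xd_z[o])
    cl <- vasctree:::.seg_closest(xb, x_t, o0, o1)
    rn <- t2$radius[kn]; ro <- t2$radius[match(o, t2$id)]
    bound <- 1.05 * (rn + ro)
    if (cl$d >= bound) next
    if (v$tree[o] != v$tree[j]) return(NULL)
    rmx <- if ("radius_max" %in% names(v)) v$radius_max[o] else v$radius[o]
    thr <- 2 * (rn + max(ro, rmx))
    gd <- function(u) {
      ab <- o1 - o0; L2 <- sum(ab^2)
      p <- xb + u * (x_t - xb)
      t <- if (L2 > 0) max(0, min(1, sum((p - o0) * ab) / L2)) else 0
      list(d = sqrt(sum((p - (o0 + t * ab))^2)), t = t)
    }
    bad <- function(u) {
      g <- gd(u)
      u * l_new +
        vasctree:::.arc_gap(v, j, l_pj / v$length[j], o, g$t) > thr
    }
    sl <- if (gd(0)$d < bound) 0 else {
      lo <- 0; hi <- cl$s
      for (it in 1:20) { m <- (lo+hi)/2; if (gd(m)$d < bound) hi <- m else lo <- m }
      hi
    }
    sh <- if (gd(1)$d < bound) 1 else {
      lo <- cl$s; hi <- 1
      for (it in 1:20) { m <- (lo+hi)/2; if (gd(m)$d < bound) lo <- m else hi <- m }
      lo
    }
    if (cl$d < 1e-7 && cl$s > 1e-6 && cl$s < 1 - 1e-6 &&
        cl$t > 1e-6 && cl$t < 1 - 1e-6) return(NULL)  # proper axis crossing
    if (cl$d < 0.5 * (rn + ro) && bad(cl$s)) return(NULL)
    if (bad(sl) && bad(sh) && bad(cl$s)) return(NULL)
  }
  cost <- if (stage$cost == "vol") {
    sol$volume - vol0
  } else {
    V_ref <- vol0                      # currently vascularised volume
    l_ref <- (3 * V_ref / (4 * pi))^(1 / 3)
    rp <- if (distal) t2$radius[ks] else t2$radius[kp]
    rref <- forest_roots(forest)$radius[v$tree[j]]
    lnew <- t2$length[kn]
    stage$coeffs$c_v * (sol$volume - vol0) / V_ref +
      stage$coeffs$c_p * rp / rref + stage$coeffs$c_d * (lnew / l_ref)^2
  }
  list(vessel = j, x_b = xb, cost = cost, dvol = sol$volume - vol0)
}
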