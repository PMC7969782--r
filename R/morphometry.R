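#' Morphometry report of a finished forest
#'
#' Per-group (growth stage, tree, or initial branch) summaries of the
#' generated network: vessel and terminal counts, total intravascular
#' volume, radius quantiles, and bifurcation-level histograms. A histogram
#' of log10 radius is included per group together with a descriptive
#' multimodality flag; multimodal radius distributions typically indicate
#' vessels transporting blood to territories vascularised at another stage
#' coexisting with local distribution vessels.
#'
#' @inheritParams vessels
#' @param by grouping: `"stage"`, `"tree"`, or `"branch"` (subtrees rooted at
#'   the children of each root, i.e. the main branches of the initial tree).
#' @return List with `groups` (summary data.frame), `levels` (bifurcation
#'   level counts per group), `log_radius` (per-group histograms with a
#'   `multimodal` flag) and `total_volume` (equal to [tree_volume()]).
#' @export
morphometry_report <- function(forest, by = c("stage", "tree", "branch")) {
  by <- match.arg(by)
  v <- vessels(forest)
  grp <- switch(by,
                stage = v$stage,
                tree = v$tree,
                branch = .branch_labels(forest, v))
  qs <- function(x) stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1))
  groups <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    w <- v[grp == g, ]
    data.frame(group = g, n_vessels = nrow(w), n_terminals = sum(w$terminal),
               volume = sum(w$length * pi * w$radius^2),
               radius_min = qs(w$radius)[1], radius_q25 = qs(w$radius)[2],
               radius_median = qs(w$radius)[3], radius_q75 = qs(w$radius)[4],
               radius_max = qs(w$radius)[5],
               length_median = stats::median(w$length))
  }))
  levels <- table(group = grp, level = v$level)
  logr <- lapply(split(v$radius, grp), function(r) {
    h <- graphics::hist(log10(r), breaks = "FD", plot = FALSE)
    counts <- h$counts
    # descriptive multimodality: interior local maxima of the smoothed counts
    s <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
    s[is.na(s)] <- counts[is.na(s)]
    peaks <- sum(diff(sign(diff(c(-Inf, s, -Inf)))) == -2)
    list(breaks = h$breaks, counts = counts, multimodal = peaks > 1)
  })
  list(groups = groups, levels = levels, log_radius = logr,
       total_volume = tree_volume(forest))
}

.branch_labels <- function(forest, v) {
  lab <- integer(nrow(v))
  nxt <- 0L
  for (rt in forest_roots(forest)$id) {
    lab[rt] <- nxt
    for (b in children_of(forest, rt)) {
      nxt <- nxt + 1L
      stack <- b
      while (length(stack)) {
        i <- stack[[1]]
        stack <- stack[-1]
        lab[i] <- nxt
        stack <- c(stack, children_of(forest, i))
      }
    }
    nxt <- nxt + 1L
  }
  lab
}
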