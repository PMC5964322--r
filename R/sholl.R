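#' Read a neuron reconstruction in SWC format
#'
#' Parses the plain-text SWC morphology format (one node per line: id, type
#' code, x, y, z in micrometers, radius, parent id; comment lines start with
#' `#`). The trace must contain exactly one root (parent = -1) and the
#' parent pointers must form a tree.
#'
#' @param path SWC file path.
#' @return list of class `neuron_trace` with `nodes` (data.frame) and
#'   `root` (root node id).
#' @export
read_swc <- function(path) {
  nodes <- utils::read.table(path, comment.char = "#",
                             col.names = c("id", "type", "x", "y", "z",
                                           "radius", "parent"))
  as_neuron_trace(nodes)
}

#' Build a neuron trace from a node table
#'
#' @param nodes data.frame with columns id, type, x, y, z, radius, parent.
#' @return a `neuron_trace`.
#' @export
as_neuron_trace <- function(nodes) {
  if (!nrow(nodes)) stop("empty trace: no nodes")
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1])
  }
  if (any(!is.finite(nodes$x) | !is.finite(nodes$y) | !is.finite(nodes$z))) {
    stop("non-finite node coordinates")
  }
  roots <- nodes$id[nodes$parent == -1]
  if (length(roots) == 0L) stop("no root node (parent = -1) found")
  if (length(roots) > 1L) {
    stop("multiple roots: ", paste(roots, collapse = ", "))
  }
  pj <- match(nodes$parent, nodes$id)
  dangling <- nodes$parent != -1 & is.na(pj)
  if (any(dangling)) {
    stop("node ", nodes$id[dangling][1], " references absent parent ",
         nodes$parent[dangling][1])
  }
  # cycle check: every node must reach the root by following parents
  depth <- rep(NA_integer_, nrow(nodes))
  depth[nodes$parent == -1] <- 0L
  for (it in seq_len(nrow(nodes))) {
    newly <- is.na(depth) & !is.na(depth[pj])
    if (!any(newly)) break
    depth[newly] <- depth[pj[newly]] + 1L
  }
  if (anyNA(depth)) {
    stop("cyclic parent references involving node ",
         nodes$id[is.na(depth)][1])
  }
  structure(list(nodes = nodes, root = roots), class = "neuron_trace")
}

#' Write a neuron trace to SWC
#'
#' @param trace a `neuron_trace`.
#' @param path output path.
#' @export
write_swc <- function(trace, path) {
  stopifnot(inherits(trace, "neuron_trace"))
  utils::write.table(trace$nodes, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Sholl intersection profile of a neuron trace
#'
#' Counts, for each concentric radius around the soma, the number of
#' parent-child segments whose endpoint distances to the soma straddle the
#' radius (`d_near < r <= d_far`). By default the trace is projected onto
#' the XY plane (z discarded) before measuring distances, matching analysis
#' of maximum-intensity projections; 3D distances are available via
#' `projection = "xyz"`. Default radii run from 10 to 350 micrometers in
#' 10-micrometer steps (35 radii).
#'
#' @param trace a `neuron_trace`.
#' @param r0 initial radius (micrometers).
#' @param step radius step size.
#' @param rmax end radius (inclusive).
#' @param projection "xy" (planar, default) or "xyz".
#' @return list of class `sholl_profile` with `radii` and integer
#'   `intersections`.
#' @export
sholl_profile <- function(trace, r0 = 10, step = 10, rmax = 350,
                          projection = c("xy", "xyz")) {
  stopifnot(inherits(trace, "neuron_trace"))
  projection <- match.arg(projection)
  nodes <- trace$nodes
  if (!nrow(nodes)) stop("empty trace")
  radii <- seq(r0, rmax, by = step)
  soma <- nodes[nodes$id == trace$root, , drop = FALSE]
  dx <- nodes$x - soma$x
  dy <- nodes$y - soma$y
  d <- if (projection == "xy") sqrt(dx^2 + dy^2) else
    sqrt(dx^2 + dy^2 + (nodes$z - soma$z)^2)
  pj <- match(nodes$parent, nodes$id)
  seg <- which(nodes$parent != -1)
  d_near <- pmin(d[seg], d[pj[seg]])
  d_far <- pmax(d[seg], d[pj[seg]])
  inter <- vapply(radii, function(r) sum(d_near < r & r <= d_far),
                  integer(1))
  structure(list(radii = radii, intersections = inter),
            class = "sholl_profile")
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat("sholl_profile:", length(x$radii), "radii (",
      x$radii[1], "to", x$radii[length(x$radii)], "),",
      "max intersections", max(x$intersections), "\n")
  invisible(x)
}

#' Simulate a dendritic arbor as a random outward-growing tree
#'
#' Grows `n_primary` neurites from the soma in segments of length
#' `step_len`, branching at each extension with probability
#' `branch_prob` (a constant, or a function of the current radial distance,
#' which allows emulating phenotypes that alter branching only within a
#' radial band). Growth directions stay within 60 degrees of the outward
#' radial direction, so the distance to the soma increases monotonically
#' along every segment. A small z-jitter is added so that the planar
#' projection is non-trivial.
#'
#' @param n_primary number of primary neurites.
#' @param step_len segment length (micrometers).
#' @param max_radius growth stops beyond this radial distance.
#' @param branch_prob branching probability per extension step; a number or
#'   a function `f(radius)`.
#' @param seed RNG seed.
#' @return a `neuron_trace`.
#' @export
simulate_neuron <- function(n_primary = 4L, step_len = 15, max_radius = 250,
                            branch_prob = 0.12, seed = 1L) {
  set.seed(seed)
  pfun <- if (is.function(branch_prob)) branch_prob else
    function(r) branch_prob
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = 5, parent = -1L)
  nid <- 1L
  # tips: list of (x, y, parent id)
  tips <- lapply(seq_len(n_primary), function(i) {
    ang <- 2 * pi * (i - 1) / n_primary + stats::runif(1, -0.2, 0.2)
    list(x = 0, y = 0, parent = 1L, ang = ang)
  })
  grow_dir <- function(x, y, want) {
    # clamp the direction to +/- 60 degrees of radial so d(t) is monotone
    if (x == 0 && y == 0) return(want)
    radial <- atan2(y, x)
    dev <- ((want - radial + pi) %% (2 * pi)) - pi
    radial + max(-pi / 3, min(pi / 3, dev))
  }
  while (length(tips)) {
    new_tips <- list()
    for (tp in tips) {
      ang <- grow_dir(tp$x, tp$y, tp$ang + stats::rnorm(1, 0, 0.35))
      nx <- tp$x + step_len * cos(ang)
      ny <- tp$y + step_len * sin(ang)
      nid <- nid + 1L
      nodes <- rbind(nodes, data.frame(
        id = nid, type = 3L, x = nx, y = ny,
        z = stats::rnorm(1, 0, 2), radius = 0.5, parent = tp$parent))
      r <- sqrt(nx^2 + ny^2)
      if (r < max_radius) {
        new_tips[[length(new_tips) + 1L]] <-
          list(x = nx, y = ny, parent = nid, ang = ang)
        if (stats::runif(1) < pfun(r)) {
          side <- sample(c(-1, 1), 1)
          new_tips[[length(new_tips) + 1L]] <-
            list(x = nx, y = ny, parent = nid, ang = ang + side * 0.8)
        }
      }
    }
    tips <- new_tips
  }
  as_neuron_trace(nodes)
}

#' Compare Sholl profiles between two groups of neurons
#'
#' Omnibus two-way ANOVA (factors: group and radius, neurons as replicates)
#' plus per-radius two-sample t-tests with Bonferroni correction across
#' radii, reporting mean and s.e.m. per radius per group.
#'
#' @param profiles_a,profiles_b lists of [sholl_profile()] objects (>= 2
#'   neurons per group, identical radii grids).
#' @param alpha significance level applied to Bonferroni-corrected p-values.
#' @return list with `per_radius` (data.frame: radius, group means and
#'   s.e.m., t statistic, raw and Bonferroni p, significance flag) and
#'   `anova` (data.frame of effects with F and p).
#' @export
compare_sholl_groups <- function(profiles_a, profiles_b, alpha = 0.05) {
  get_mat <- function(ps) {
    stopifnot(length(ps) >= 2L)
    radii <- ps[[1]]$radii
    for (p in ps) {
      if (!isTRUE(all.equal(p$radii, radii))) {
        stop("all profiles must share the same radii grid")
      }
    }
    list(radii = radii,
         mat = do.call(rbind, lapply(ps, `[[`, "intersections")))
  }
  A <- get_mat(profiles_a)
  B <- get_mat(profiles_b)
  if (!isTRUE(all.equal(A$radii, B$radii))) {
    stop("the two groups must share the same radii grid")
  }
  radii <- A$radii
  n_r <- length(radii)

  long <- data.frame(
    y = c(as.vector(A$mat), as.vector(B$mat)),
    group = factor(rep(c("A", "B"), c(length(A$mat), length(B$mat)))),
    radius = factor(c(rep(radii, each = nrow(A$mat)),
                      rep(radii, each = nrow(B$mat))))
  )
  fit <- stats::aov(y ~ group * radius, data = long)
  sm <- summary(fit)[[1]]
  anova_tab <- data.frame(
    effect = trimws(rownames(sm)),
    F = sm[["F value"]], p = sm[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )

  sem <- function(v) stats::sd(v) / sqrt(length(v))
  per <- lapply(seq_len(n_r), function(i) {
    a <- A$mat[, i]; b <- B$mat[, i]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      t <- 0; p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      w <- welch_t_test(a, b)
      t <- w$statistic; p <- w$p_value
    }
    data.frame(radius = radii[i], mean_a = mean(a), sem_a = sem(a),
               mean_b = mean(b), sem_b = sem(b), t = t, p_raw = p)
  })
  per <- do.call(rbind, per)
  per$p_bonferroni <- pmin(1, per$p_raw * n_r)
  per$significant <- per$p_bonferroni <= alpha
  list(per_radius = per, anova = anova_tab, alpha = alpha)
}
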