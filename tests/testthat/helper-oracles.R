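# Shared fixtures and independent oracles for the test suite.

# default human-scaled morphometry + anatomy, computed once
test_table <- function() {
  scale_to_human(load_morphometry("default"))
}

# forced binary cascade: one segment per element, each order-m element ends in
# exactly two order-(m-1) daughters (no side branches possible)
cascade_morphometry <- function() {
  morphometry_from_list(list(
    orders = lapply(6:11, function(o) list(
      order = o, mean_radius_mm = 0.05 * 2^(o - 6),
      mean_segment_length_mm = if (o == 11) 140 else 2 + o / 10,
      sd_segment_length_mm = 0.2, segments_per_element = 1)),
    connectivity = setNames(lapply(7:11, function(m)
      setNames(list(2), as.character(m - 1))), as.character(7:11)),
    length_bounds_mm = list(rca_min = 60, rca_max = 250,
                            left_min = 60, left_max = 250),
    viscosity_pa_s = 3.6e-3,
    human_scale = rep(1, 6)))
}

# hand-built tree from explicit fields (bypasses the stochastic generator)
manual_tree <- function(parent, length, radius, order = NULL,
                        viscosity = 3.6e-3, name = "RCA") {
  n <- length(parent)
  if (is.null(order)) order <- rep(6L, n)
  seg <- data.frame(id = seq_len(n), parent = as.integer(parent),
                    order = as.integer(order),
                    element = seq_len(n), length = length, radius = radius)
  seg$resistance <- segment_resistance(seg$length, seg$radius, viscosity)
  structure(list(name = name, seg = seg,
                 trunk_ids = 1L, lcx_root = NA_integer_,
                 lcx_trunk = integer(0), viscosity = viscosity, seed = NULL),
            class = "coro_tree")
}

# random binary tree of exactly n_seg segments (grown by bifurcating a random
# terminal), with plausible length/radius ranges
random_tree <- function(n_seg, seed) {
  set.seed(seed)
  parent <- c(0L)
  while (length(parent) + 2L <= n_seg) {
    terminals <- setdiff(seq_along(parent), parent)
    at <- terminals[sample.int(length(terminals), 1L)]
    parent <- c(parent, at, at)
  }
  n <- length(parent)
  # calibre range of the modeled orders (SN 6-11): 0.1-1.6 mm
  manual_tree(parent, length = runif(n, 0.5, 10), radius = runif(n, 0.1, 1.6))
}

# independent dense Kirchhoff oracle: solve nodal pressures from the full
# linear system (flow conservation at every free node), in SI units
kirchhoff_solve <- function(tree, boundary = pressure_boundary()) {
  seg <- tree$seg
  n <- nrow(seg)
  g <- 1 / seg$resistance
  p_in <- boundary$inlet_pressure * 133.322
  p_term <- boundary$terminal_pressure * 133.322
  term <- terminal_ids(tree)
  free <- setdiff(seq_len(n), term)   # node i = distal node of segment i
  m <- length(free)
  row_of <- integer(n); row_of[free] <- seq_len(m)
  A <- matrix(0, m, m); b <- numeric(m)
  fixed_p <- function(node) if (node == 0L) p_in else p_term
  for (i in seq_len(n)) {
    u <- seg$parent[i]; v <- i
    for (side in 1:2) {
      node <- if (side == 1) v else u
      other <- if (side == 1) u else v
      if (node == 0L || node %in% term) next
      r <- row_of[node]
      A[r, r] <- A[r, r] + g[i]
      if (other == 0L || other %in% term) {
        b[r] <- b[r] + g[i] * fixed_p(other)
      } else {
        A[r, row_of[other]] <- A[r, row_of[other]] - g[i]
      }
    }
  }
  p <- numeric(n)
  p[term] <- p_term
  if (m > 0) p[free] <- solve(A, b)
  pprox <- ifelse(seg$parent == 0L, p_in, p[pmax(seg$parent, 1L)])
  pprox[seg$parent == 0L] <- p_in
  q <- g * (pprox - p)
  list(node_pressures = p / 133.322, segment_flows = q * 1e9)
}

# brute-force nearest distance to an ellipsoid surface by dense sampling
ellipsoid_distance_oracle <- function(p, center, semi, n_u = 400, n_phi = 800) {
  u <- seq(1e-4, pi - 1e-4, length.out = n_u)
  phi <- seq(0, 2 * pi, length.out = n_phi)
  gr <- expand.grid(u = u, phi = phi)
  pts <- cbind(center[1] + semi[1] * sin(gr$u) * cos(gr$phi),
               center[2] + semi[2] * sin(gr$u) * sin(gr$phi),
               center[3] + semi[3] * cos(gr$u))
  min(sqrt(rowSums(sweep(pts, 2, p)^2)))
}

# slab anatomy: tissue between z = 0 and z = thick
slab_anatomy <- function(thick = 4) {
  anatomy(walls = list(lo = plane_wall(c(0, 0, 0), c(0, 0, 1)),
                       hi = plane_wall(c(0, 0, thick), c(0, 0, 1))),
          regions = list(slab = c(lo = 1L, hi = -1L)))
}

# solid sphere of radius a (tissue inside)
sphere_anatomy <- function(a = 10) {
  anatomy(walls = list(surf = ellipsoid_wall(c(0, 0, 0), rep(a, 3))),
          regions = list(ball = c(surf = -1L)))
}

# spherical shell with named endo/epi walls (distance-map tests)
shell_anatomy <- function(a = 10, b = 20) {
  anatomy(walls = list(lv_endo = ellipsoid_wall(c(0, 0, 0), rep(a, 3)),
                       lv_epi = ellipsoid_wall(c(0, 0, 0), rep(b, 3))),
          regions = list(LV = c(lv_endo = 1L, lv_epi = -1L)))
}

# Study-scale control ensemble shared by the acceptance tests; built once.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_ensemble <- function() {
  if (is.null(.acceptance_cache$ens)) {
    tab <- test_table()
    anat <- ventricle_anatomy()
    .acceptance_cache$tab <- tab
    .acceptance_cache$anat <- anat
    .acceptance_cache$ens <- simulate_ensemble(
      ensemble_spec(n_instances = 540L, base_seed = 1000L), tab, anat,
      conditions = list(control = list(),
                        sten001 = cond_stenosis(0.01),
                        sten025 = cond_stenosis(0.25),
                        blk6 = cond_block(6, 0.9),
                        blk10 = cond_block(10, 0.9)))
  }
  .acceptance_cache
}
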