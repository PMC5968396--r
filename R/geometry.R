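# 3D arterial geometry: branching angles from flow and calibre, space-filling
# via self-avoidance and boundary-avoidance vectors, iterative repair of
# boundary violations, and trunk placement along epicardial paths.
#
# The exported primitives below are the reference implementation; the C++
# engine in src/place.cpp repeats them verbatim for ensemble-scale runs and
# is pinned against the R engine in the test suite.

#' Space-filling algorithm parameters
#'
#' @param xi avoidance exponent of the self-avoidance weight (default 2)
#' @param cs,cb combination weights of the normalized self-avoidance and
#'   boundary-avoidance vectors (default 0.5 each)
#' @param max_repair_iterations iteration budget when moving a violating
#'   position back into tissue (default 200)
#' @param step_frac repair step size as a fraction of the segment length
#'   (default 1/20)
#' @param recompute_every recompute the repair direction every this many
#'   iterations (default 10)
#' @param convention `"corrected"` branching-angle index convention (the
#'   law-of-cosines form whose straight-continuation limit is a zero angle)
#'   or `"printed"` (swapped daughter indices)
#' @return object of class `coro_avoidance`
#' @export
avoidance_params <- function(xi = 2, cs = 0.5, cb = 0.5,
                             max_repair_iterations = 200L,
                             step_frac = 1 / 20, recompute_every = 10L,
                             convention = c("corrected", "printed")) {
  convention <- match.arg(convention)
  if (xi <= 0) stop("xi: must be > 0")
  if (cs + cb <= 0) stop("cs/cb: cs + cb must be > 0")
  structure(list(xi = xi, cs = cs, cb = cb,
                 max_repair_iterations = as.integer(max_repair_iterations),
                 step_frac = step_frac,
                 recompute_every = as.integer(recompute_every),
                 convention = convention, corrected = convention == "corrected"),
            class = "coro_avoidance")
}

#' Initial branching angles of a bifurcation
#'
#' Law-of-cosines construction on vectors of magnitude `Q / r^2`: the parent
#' "momentum" vector is the sum of the daughters'. Arguments of the arccos
#' are clamped to `[-1, 1]`.
#'
#' @param Qp,rp parent flow and radius
#' @param QL,rL left daughter flow and radius
#' @param QR,rR right daughter flow and radius
#' @param convention `"corrected"` (default) keeps the same-side daughter
#'   term positive in the numerator; `"printed"` swaps the daughter indices
#' @return named vector `c(theta_L, theta_R)` in radians, both in `[0, pi]`
#' @export
branching_angles <- function(Qp, rp, QL, rL, QR, rR,
                             convention = c("corrected", "printed")) {
  convention <- match.arg(convention)
  if (Qp <= 0) stop("Qp: parent flow must be > 0")
  ang <- function(Qs, rs, Qo, ro) {
    up <- Qp^2 / rp^4; us <- Qs^2 / rs^4; uo <- Qo^2 / ro^4
    num <- if (convention == "corrected") up + us - uo else up + uo - us
    den <- 2 * Qp * Qs / (rp^2 * rs^2)
    acos(max(-1, min(1, num / den)))
  }
  c(theta_L = ang(QL, rL, QR, rR), theta_R = ang(QR, rR, QL, rL))
}

#' Self-avoidance vector
#'
#' Sum over already-placed contributor nodes of the unit vector from the node
#' toward the generating junction, weighted `(Ls/d)^xi / (1 + (Ls/d)^xi)`.
#' Nodes belonging to segments with radius smaller than both daughters are
#' excluded, as are coincident nodes.
#'
#' @param x_c generating junction position (mm)
#' @param positions n x 3 matrix of placed node positions (mm)
#' @param radii segment radius per placed node (mm)
#' @param L_s expected length of the generating segment (mm)
#' @param xi avoidance exponent
#' @param r_min smaller daughter radius (mm); contributors need radius >= r_min
#' @return 3-vector
#' @export
self_avoidance_vector <- function(x_c, positions, radii, L_s, xi = 2,
                                  r_min = 0) {
  positions <- as_points(positions)
  keep <- radii >= r_min - 1e-12
  if (!any(keep)) return(c(0, 0, 0))
  s <- sweep(-positions[keep, , drop = FALSE], 2, as.numeric(x_c), "+")
  d <- sqrt(rowSums(s^2))
  ok <- d >= 1e-9
  if (!any(ok)) return(c(0, 0, 0))
  s <- s[ok, , drop = FALSE]; d <- d[ok]
  u <- (L_s / d)^xi
  w <- (u / (1 + u)) / d
  colSums(s * w)
}

#' Boundary avoidance vector
#'
#' Sum over anatomy walls of the into-tissue unit normal at the nearest
#' surface point, weighted `exp(-d / (2 L))`. Defined at tissue points; for
#' violated positions use [repair_position()].
#'
#' @param x_c tissue point (mm)
#' @param anat a `coro_anatomy`
#' @param L expected daughter segment length (mm)
#' @return 3-vector
#' @export
boundary_avoidance_vector <- function(x_c, anat, L) {
  bn <- boundary_normals(x_c, anat)
  v <- c(0, 0, 0)
  for (w in bn) v <- v + w$normal * exp(-w$distance / (2 * L))
  v
}

#' Combined branching direction
#'
#' `c_s * v_s/|v_s| + c_b * D/|D|`; a zero-magnitude input contributes
#' nothing, and if both are zero the parent direction `s_p` is used.
#'
#' @param v_s self-avoidance vector
#' @param D boundary-avoidance vector
#' @param cs,cb combination weights
#' @param s_p fallback parent direction (unit)
#' @return 3-vector
#' @export
combined_direction <- function(v_s, D, cs = 0.5, cb = 0.5, s_p = NULL) {
  v <- c(0, 0, 0)
  nv <- sqrt(sum(v_s^2)); nD <- sqrt(sum(D^2))
  if (nv > 1e-12) v <- v + cs * v_s / nv
  if (nD > 1e-12) v <- v + cb * D / nD
  if (sqrt(sum(v^2)) < 1e-12) {
    if (is.null(s_p)) stop("both inputs zero and no parent direction supplied")
    v <- s_p
  }
  v
}

#' Branching plane normal
#'
#' `(s_p x v_d) x v_d`, normalized: a unit vector perpendicular to `v_d` in
#' the span of `{s_p, v_d}`. For (near-)parallel inputs, a deterministic
#' fallback orthogonalizes a fixed reference axis against `v_d`.
#'
#' @param s_p parent direction
#' @param v_d combined branching direction
#' @return unit 3-vector
#' @export
branching_plane_normal <- function(s_p, v_d) {
  vd <- v_d / sqrt(sum(v_d^2))
  nb <- cross3_r(cross3_r(s_p, vd), vd)
  nn <- sqrt(sum(nb^2))
  if (nn < 1e-9) {
    nb <- c(1, 0, 0) - vd[1] * vd
    nn <- sqrt(sum(nb^2))
    if (nn < 1e-9) {
      nb <- c(0, 1, 0) - vd[2] * vd
      nn <- sqrt(sum(nb^2))
    }
  }
  nb / nn
}

cross3_r <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotate a vector about a unit axis (Rodrigues formula)
#'
#' @param v vector to rotate
#' @param axis unit rotation axis
#' @param theta angle (radians)
#' @return rotated vector (norm-preserving)
#' @export
rotate_about_axis <- function(v, axis, theta) {
  v * cos(theta) + cross3_r(axis, v) * sin(theta) +
    axis * sum(axis * v) * (1 - cos(theta))
}

#' Assign initial daughter node positions
#'
#' Rotates the combined direction about the branching-plane normal by
#' `+theta_L` (left) and `-theta_R` (right) and steps the daughter lengths
#' from the junction.
#'
#' @param x_c junction position (mm)
#' @param v_d combined branching direction (normalized internally)
#' @param n_b unit branching-plane normal
#' @param theta_L,theta_R branching angles (radians)
#' @param L_L,L_R daughter lengths (mm)
#' @return list with `x_L`, `x_R` (3-vectors) and directions `v_L`, `v_R`
#' @export
assign_child_positions <- function(x_c, v_d, n_b, theta_L, theta_R, L_L, L_R) {
  vd <- v_d / sqrt(sum(v_d^2))
  vL <- rotate_about_axis(vd, n_b, theta_L)
  vR <- rotate_about_axis(vd, n_b, -theta_R)
  list(x_L = x_c + L_L * vL, x_R = x_c + L_R * vR, v_L = vL, v_R = vR)
}

# Repair direction at an arbitrary point: per wall, the tissue-side unit
# normal at the nearest surface point (side resolved by probing both sides at
# 0.5 and 1.5 mm), weighted exp(-d/(2L)).
boundary_push_direction <- function(x, anat, L) {
  v <- c(0, 0, 0)
  for (w in anat$walls) {
    nr <- wall_nearest(w, x)
    d <- nr$distance[1]
    g <- if (d > 1e-12) (x - nr$point[1, ]) / d else wall_gradient(w, x)
    # resolve which side of the wall is tissue; skip walls with no tissue on
    # either side nearby (they carry no usable direction)
    n <- NULL
    for (delta in c(0.5, 1.5)) {
      ip <- inside_tissue(nr$point[1, ] + delta * g, anat)
      im <- inside_tissue(nr$point[1, ] - delta * g, anat)
      if (ip && !im) { n <- g; break }
      if (im && !ip) { n <- -g; break }
    }
    if (is.null(n)) next
    v <- v + n * exp(-d / (2 * L))
  }
  v
}

#' Repair a boundary-violating position
#'
#' Moves the point in increments of `step_frac * L` along the
#' boundary-avoidance direction (recomputed every `recompute_every` steps)
#' until it lies in tissue or the iteration budget is exhausted. A point
#' already inside is returned unchanged with zero iterations; exhaustion is a
#' placement failure (the caller prunes the unplaced sub-tree), not an error.
#'
#' @param x starting position (mm)
#' @param anat a `coro_anatomy`
#' @param L segment length scale (mm)
#' @param params a `coro_avoidance`
#' @return list with `position`, `success`, `iterations`
#' @export
repair_position <- function(x, anat, L, params = avoidance_params()) {
  dir <- c(0, 0, 0)
  for (it in seq_len(params$max_repair_iterations) - 1L) {
    if (inside_tissue(x, anat)) {
      return(list(position = x, success = TRUE, iterations = it))
    }
    if (it %% params$recompute_every == 0L) {
      dir <- boundary_push_direction(x, anat, L)
      nd <- sqrt(sum(dir^2))
      if (nd < 1e-12) {
        dir <- -x; nd <- sqrt(sum(dir^2))
        if (nd < 1e-12) {
          return(list(position = x, success = FALSE,
                      iterations = params$max_repair_iterations))
        }
      }
      dir <- dir / nd
    }
    x <- x + params$step_frac * L * dir
  }
  list(position = x, success = inside_tissue(x, anat),
       iterations = params$max_repair_iterations)
}

# ---------------------------------------------------------------------------
# Trunk placement along epicardial paths

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# point on a shrunken ellipsoid surface: meridian parameter u (0 = apex pole),
# azimuth phi
ell_pt <- function(center, semi, u, phi) {
  cbind(center[1] + semi[1] * sin(u) * cos(phi),
        center[2] + semi[2] * sin(u) * sin(phi),
        center[3] - semi[3] * cos(u))
}

# Dense polylines for the three trunks. The RCA runs in the right AV groove
# on the RV epicardial surface then descends the posterior interventricular
# groove; the LAD descends the anterior groove from base toward the apex and
# may wrap onto the posterior wall; the LCX sweeps the left lateral
# epicardium in the AV groove. Paths sit slightly inside the epicardium.
trunk_polyline <- function(name, anat, start_pos = NULL) {
  lv <- anat$walls$lv_epi; rv <- anat$walls$rv_epi
  base_z <- anat$walls$base$point[3]
  if (is.null(lv) || is.null(rv)) {
    stop("trunk path infeasible: anatomy lacks lv_epi/rv_epi walls")
  }
  slv <- 0.98 * lv$semi
  srv <- 0.97 * rv$semi
  z0 <- base_z - 2
  if (name == "LAD") {
    u0 <- acos(clamp(-z0 / slv[3], -1, 1))
    w <- seq(0, u0 + 2.2, length.out = 900)
    u <- u0 - w
    phi <- ifelse(u >= 0, 120, 300) * pi / 180
    ell_pt(lv$center, slv, abs(u), phi)
  } else if (name == "RCA") {
    cz <- rv$center[3]
    # phase 1: right AV groove sweep
    t1 <- seq(0, 1, length.out = 350)
    z1 <- z0 - 13 * t1
    u1 <- acos(clamp((cz - z1) / srv[3], -1, 1))
    p1 <- ell_pt(rv$center, srv, u1, (100 + 160 * t1) * pi / 180)
    # phase 2: posterior descent on the RV surface
    u2 <- seq(u1[length(u1)], 0.35, length.out = 250)
    p2 <- ell_pt(rv$center, srv, u2, 260 * pi / 180)
    # phase 3: continue toward the LV apex on the LV surface
    z2 <- p2[nrow(p2), 3]
    u3a <- acos(clamp(-z2 / slv[3], -1, 1))
    u3 <- seq(u3a, 0.12, length.out = 200)
    p3 <- ell_pt(lv$center, slv, u3, 260 * pi / 180)
    rbind(p1, p2[-1, , drop = FALSE], p3)
  } else if (name == "LCX") {
    stopifnot(!is.null(start_pos))
    zs <- start_pos[3]
    t <- seq(0, 1, length.out = 900)
    phi0 <- atan2(start_pos[2] / slv[2], start_pos[1] / slv[1])
    phi <- phi0 - 8 * t
    # drift toward the wide equatorial belt so the path capacity stays ample
    # even when the attachment sits low on the trunk
    z <- clamp(zs + (-10 - zs) * 0.8 * t, -0.93 * slv[3], base_z)
    u <- acos(clamp(-z / slv[3], -1, 1))
    rbind(matrix(start_pos, ncol = 3), ell_pt(lv$center, slv, u, phi)[-1, ])
  } else stop("unknown trunk: ", name)
}

# Node positions at cumulative arc lengths along a polyline.
place_along_polyline <- function(poly, lengths) {
  dseg <- sqrt(rowSums(diff(poly)^2))
  arc <- c(0, cumsum(dseg))
  targets <- cumsum(lengths)
  if (targets[length(targets)] > arc[length(arc)]) {
    stop("trunk path infeasible: required ",
         round(targets[length(targets)], 1), " mm, path offers ",
         round(arc[length(arc)], 1), " mm")
  }
  out <- matrix(0, length(targets), 3)
  for (j in seq_along(targets)) {
    i <- findInterval(targets[j], arc, rightmost.closed = TRUE)
    f <- (targets[j] - arc[i]) / (arc[i + 1] - arc[i])
    out[j, ] <- poly[i, ] + f * (poly[i + 1, ] - poly[i, ])
  }
  out
}

# ---------------------------------------------------------------------------
# Full placement

# Pure-R engine mirroring src/place.cpp (used for cross-checks and as the
# readable statement of the algorithm).
place_tree_r <- function(dat, anat, params) {
  n <- length(dat$parent)
  pos <- dat$pos0
  placed <- dat$preplaced
  repaired <- logical(n)
  cpos <- rbind(dat$ext_pos, dat$pos0[dat$preplaced, , drop = FALSE])
  crad <- c(dat$ext_rad, dat$radius[dat$preplaced])

  add_contrib <- function(x, r) {
    cpos <<- rbind(cpos, matrix(x, ncol = 3)); crad <<- c(crad, r)
  }
  place_child <- function(cidx, xc, vdir) {
    x <- xc + dat$seg_len[cidx] * vdir
    ok <- inside_tissue(x, anat)
    if (!ok) {
      rep <- repair_position(x, anat, dat$seg_len[cidx], params)
      ok <- rep$success; x <- rep$position
      if (ok) repaired[cidx] <<- TRUE
    }
    if (ok) {
      placed[cidx] <<- TRUE
      pos[cidx, ] <<- x
      add_contrib(x, dat$radius[cidx])
    }
  }

  for (s in dat$proc_order) {
    if (!placed[s]) next
    a <- dat$ch1[s]; b <- dat$ch2[s]
    if (is.na(a)) next
    need_a <- !is.na(a) && !dat$preplaced[a]
    need_b <- !is.na(b) && !dat$preplaced[b]
    if (!need_a && !need_b) next
    xc <- pos[s, ]
    sp <- if (dat$parent[s] == 0L) xc - dat$root_prox else xc - pos[dat$parent[s], ]
    nsp <- sqrt(sum(sp^2))
    sp <- if (nsp < 1e-12) c(0, 0, -1) else sp / nsp
    rL <- dat$radius[a]; QL <- dat$flow[a]
    rR <- if (!is.na(b)) dat$radius[b] else dat$radius[a]
    QR <- if (!is.na(b)) dat$flow[b] else 0
    th <- branching_angles(dat$flow[s], dat$radius[s], QL, rL,
                           max(QR, .Machine$double.xmin), rR,
                           convention = params$convention)
    rmin <- min(rL, rR)
    Ls <- dat$ls_junction[s]
    vs <- self_avoidance_vector(xc, cpos, crad, Ls, params$xi, rmin)
    D <- if (inside_tissue(xc, anat)) {
      boundary_avoidance_vector(xc, anat, Ls)
    } else boundary_push_direction(xc, anat, Ls)
    vd <- combined_direction(vs, D, params$cs, params$cb, s_p = sp)
    vd <- vd / sqrt(sum(vd^2))
    nb <- branching_plane_normal(sp, vd)
    ch <- assign_child_positions(xc, vd, nb, th[1], th[2], 1, 1)
    if (need_a) place_child(a, xc, ch$v_L)
    if (need_b) place_child(b, xc, ch$v_R)
  }
  list(pos = pos, placed = placed, repaired = repaired)
}

# Assemble engine inputs shared by both engines.
placement_data <- function(tree, table, flows, trunk_pos, preplaced,
                           root_prox, ext_pos, ext_rad) {
  seg <- tree$seg
  n <- nrow(seg)
  ch <- tree_children(tree)
  depth <- tree_depths(tree)
  mlen <- setNames(table$order_stats$mean_segment_length,
                   table$order_stats$order)
  ls <- numeric(n)
  has1 <- !is.na(ch$ch1); has2 <- !is.na(ch$ch2)
  l1 <- ifelse(has1, mlen[as.character(seg$order[ch$ch1])], 0)
  l2 <- ifelse(has2, mlen[as.character(seg$order[ch$ch2])], l1)
  ls <- (l1 + l2) / 2
  # at each junction, daughter L = larger radius
  swap <- has2 & seg$radius[ch$ch2] > seg$radius[ch$ch1]
  tmp <- ch$ch1[swap]; ch$ch1[swap] <- ch$ch2[swap]; ch$ch2[swap] <- tmp
  proc <- order(depth, -seg$radius)
  list(parent = seg$parent, ch1 = ch$ch1, ch2 = ch$ch2,
       order = seg$order, radius = seg$radius, flow = flows,
       seg_len = seg$length, ls_junction = ls,
       preplaced = preplaced, pos0 = trunk_pos, root_prox = root_prox,
       proc_order = proc, ext_pos = ext_pos, ext_rad = ext_rad)
}

#' Assign 3D geometry to a tree topology
#'
#' Solves topology-level flows (branching angles require per-segment flow),
#' lays the trunk elements along their epicardial paths (RCA right AV groove,
#' LAD anterior interventricular groove base-to-apex, LCX left AV groove from
#' its LAD attachment), then processes the remaining junctions root-outward:
#' branching angles, self-avoidance, boundary avoidance, combined direction,
#' branching-plane rotation, placement and, if needed, iterative repair.
#' Sub-trees whose positions could not be assigned are pruned and flows are
#' re-solved on the pruned tree.
#'
#' @param tree a fresh `coro_tree`
#' @param anat a `coro_anatomy` from [ventricle_anatomy()]
#' @param table the human-scaled `coro_morphometry` used to build the tree
#' @param boundary a `coro_boundary`
#' @param params a `coro_avoidance`
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference); both
#'   implement the identical algorithm
#' @param external optional list with `pos` (m x 3) and `radius` of placed
#'   nodes from other trees of the same instance (self-avoidance contributors)
#' @return a placed `coro_tree` with `pos` (distal node coordinates, mm),
#'   `root_prox` (ostium), `flow` (re-solved `coro_flow`), and attributes
#'   `n_pruned` / `pruned_terminal_fraction`
#' @export
generate_geometry <- function(tree, anat, table,
                              boundary = pressure_boundary(),
                              params = avoidance_params(),
                              engine = c("cpp", "r"), external = NULL) {
  engine <- match.arg(engine)
  sol <- solve_flow(tree, boundary)
  seg <- tree$seg
  n <- nrow(seg)
  n_term0 <- length(terminal_ids(tree))

  trunk_pos <- matrix(0, n, 3)
  preplaced <- logical(n)
  poly <- trunk_polyline(tree$name, anat)
  tp <- place_along_polyline(poly, seg$length[tree$trunk_ids])
  trunk_pos[tree$trunk_ids, ] <- tp
  preplaced[tree$trunk_ids] <- TRUE
  root_prox <- poly[1, ]
  if (!is.na(tree$lcx_root)) {
    att <- tree$seg$parent[tree$lcx_root]  # a trunk segment
    lpoly <- trunk_polyline("LCX", anat, start_pos = trunk_pos[att, ])
    lp <- place_along_polyline(lpoly, seg$length[tree$lcx_trunk])
    trunk_pos[tree$lcx_trunk, ] <- lp
    preplaced[tree$lcx_trunk] <- TRUE
  }
  ext_pos <- if (is.null(external)) matrix(0, 0, 3) else as_points(external$pos)
  ext_rad <- if (is.null(external)) numeric(0) else external$radius

  dat <- placement_data(tree, table, sol$segment_flows, trunk_pos, preplaced,
                        root_prox, ext_pos, ext_rad)
  res <- if (engine == "cpp") {
    .cpp_place_tree(dat$parent - 1L,
                    ifelse(is.na(dat$ch1), -1L, dat$ch1 - 1L),
                    ifelse(is.na(dat$ch2), -1L, dat$ch2 - 1L),
                    dat$radius, dat$flow, dat$seg_len, dat$ls_junction,
                    dat$preplaced, dat$pos0, dat$root_prox,
                    dat$proc_order - 1L, dat$ext_pos, dat$ext_rad,
                    anatomy_to_cpp(anat),
                    params[c("xi", "cs", "cb", "max_repair_iterations",
                             "step_frac", "recompute_every", "corrected")])
  } else {
    place_tree_r(dat, anat, params)
  }

  placed <- as.logical(res$placed)
  tree$pos <- as.matrix(res$pos)
  tree$placed <- placed
  tree$repaired <- as.logical(res$repaired)
  tree$preplaced <- preplaced
  n_pruned_term <- sum(!placed[terminal_ids(tree)])
  if (!all(placed)) tree <- renumber_tree(tree, placed)
  # cascade: a junction whose daughters were all pruned is a dead stub, not a
  # perfusion outlet; remove such leaves until every terminal has order 6
  repeat {
    term <- terminal_ids(tree)
    bad <- term[tree$seg$order[term] > 6L]
    if (!length(bad)) break
    if (any(tree$seg$parent[bad] == 0L)) {
      stop("placement failed: the trunk lost all its daughters")
    }
    tree <- renumber_tree(tree, !(seq_len(nrow(tree$seg)) %in% bad))
  }
  tree$root_prox <- root_prox
  validate_tree(tree, allow_series = TRUE)
  tree$flow <- solve_flow(tree, boundary)
  attr(tree, "n_pruned") <- sum(!placed)
  attr(tree, "pruned_terminal_fraction") <- n_pruned_term / n_term0
  tree
}

#' Generate one placed whole-heart instance
#'
#' Assembles and places the RCA tree and the LAD tree (carrying the LCX
#' sub-tree) for one seed. The RCA is placed first; its node positions feed
#' the LAD/LCX placement as self-avoidance contributors.
#'
#' @param table human-scaled `coro_morphometry`
#' @param anat a `coro_anatomy`
#' @param seed integer seed (fully determines the instance)
#' @param boundary a `coro_boundary`
#' @param params a `coro_avoidance`
#' @param engine placement engine, `"cpp"` or `"r"`
#' @return list with placed `rca` and `lad` trees (each carrying `$flow`)
#' @export
generate_instance <- function(table, anat, seed,
                              boundary = pressure_boundary(),
                              params = avoidance_params(),
                              engine = "cpp") {
  rca_top <- assemble_tree("RCA", table, seed = seed)
  lad_top <- assemble_tree("LAD", table)  # continues the seeded RNG stream
  rca <- generate_geometry(rca_top, anat, table, boundary, params, engine)
  lad <- generate_geometry(lad_top, anat, table, boundary, params, engine,
                           external = list(pos = rca$pos,
                                           radius = rca$seg$radius))
  list(rca = rca, lad = lad, seed = seed)
}

#' Export a placed tree as VTK polylines
#'
#' Legacy-format VTK file with one polyline per segment and per-segment
#' radius, order and (if solved) flow as cell data.
#'
#' @param tree a placed `coro_tree`
#' @param path output `.vtk` path
#' @return `path`, invisibly
#' @export
write_tree_vtk <- function(tree, path) {
  if (is.null(tree$pos)) stop("tree has no geometry")
  seg <- tree$seg
  n <- nrow(seg)
  prox <- matrix(0, n, 3)
  root <- which(seg$parent == 0L)
  prox[root, ] <- tree$root_prox
  nr <- seg$parent != 0L
  prox[nr, ] <- tree$pos[seg$parent[nr], , drop = FALSE]
  pts <- rbind(prox, tree$pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "coronary tree", "ASCII",
               "DATASET POLYDATA", paste("POINTS", 2 * n, "float")), con)
  write(t(pts), con, ncolumns = 3)
  writeLines(paste("LINES", n, 3 * n), con)
  write(t(cbind(2L, seq_len(n) - 1L, n + seq_len(n) - 1L)), con, ncolumns = 3)
  writeLines(c(paste("CELL_DATA", n), "SCALARS radius_mm float 1",
               "LOOKUP_TABLE default"), con)
  write(seg$radius, con, ncolumns = 9)
  writeLines(c("SCALARS order int 1", "LOOKUP_TABLE default"), con)
  write(seg$order, con, ncolumns = 9)
  if (!is.null(tree$flow)) {
    writeLines(c("SCALARS flow_mm3_s float 1", "LOOKUP_TABLE default"), con)
    write(tree$flow$segment_flows, con, ncolumns = 9)
  }
  invisible(path)
}
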