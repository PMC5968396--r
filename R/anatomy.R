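# Idealized ventricular anatomy: tissue bounded by truncated-ellipsoid
# surfaces (plus the basal truncation plane), expressed generically as a set
# of walls and tissue regions so that degenerate test anatomies (slabs,
# spheres) use the same machinery.
#
# A wall has a signed value g(p): for an ellipsoid, sum(((p-c)/a)^2) - 1
# (negative inside); for a plane, (p - point) . normal. A region is a
# conjunction of wall conditions (-1: g <= 0, +1: g >= 0, 0: ignore); tissue
# is the union of regions. All boundaries are inclusive.

BOUNDARY_TOL <- 1e-9

#' Ellipsoid wall
#' @param center centre (mm)
#' @param semi semi-axes (mm)
#' @return wall object
#' @export
ellipsoid_wall <- function(center, semi) {
  stopifnot(length(center) == 3, length(semi) == 3, all(semi > 0))
  list(type = "ellipsoid", center = as.numeric(center), semi = as.numeric(semi))
}

#' Planar wall
#' @param point a point on the plane (mm)
#' @param normal plane normal (normalized internally)
#' @return wall object
#' @export
plane_wall <- function(point, normal) {
  stopifnot(length(point) == 3, length(normal) == 3)
  n <- as.numeric(normal); n <- n / sqrt(sum(n^2))
  list(type = "plane", point = as.numeric(point), normal = n)
}

#' Generic anatomy from walls and regions
#'
#' @param walls named list of walls ([ellipsoid_wall()] / [plane_wall()])
#' @param regions named list; each region is a named integer vector over wall
#'   names with -1 (point must be inside/below the wall), +1 (outside/above)
#' @return object of class `coro_anatomy`
#' @export
anatomy <- function(walls, regions) {
  stopifnot(length(walls) > 0, length(regions) > 0)
  for (r in regions) {
    if (!all(names(r) %in% names(walls))) stop("regions: unknown wall name")
  }
  structure(list(walls = walls, regions = regions), class = "coro_anatomy")
}

#' Default biventricular anatomy
#'
#' Idealized truncated-ellipsoid ventricles: LV endo/epicardial ellipsoids
#' about the origin, an RV endo/epicardial pair shifted leftward forming a
#' crescent free wall of about 5 mm thickness, all truncated by a basal plane
#' 10 mm above the equator. Tissue is the LV wall (between LV endo- and
#' epicardium) plus the RV free wall (inside the RV epicardium, outside the RV
#' endocardium and outside the LV epicardium).
#'
#' @param lv_epi_semi,lv_endo_semi LV epicardial/endocardial semi-axes (mm)
#' @param rv_center RV ellipsoid pair centre (mm)
#' @param rv_epi_semi,rv_endo_semi RV semi-axes (mm)
#' @param base_z basal truncation plane height (mm)
#' @return a `coro_anatomy` with regions `LV` and `RV`
#' @export
ventricle_anatomy <- function(lv_epi_semi = c(40, 40, 68),
                              lv_endo_semi = c(30, 30, 58),
                              rv_center = c(-15, 0, 8),
                              rv_epi_semi = c(45, 38, 58),
                              rv_endo_semi = c(40, 33, 53),
                              base_z = 10) {
  if (any(lv_endo_semi >= lv_epi_semi)) {
    stop("lv_endo_semi: endocardial surface must lie strictly inside the epicardial one")
  }
  if (any(rv_endo_semi >= rv_epi_semi)) {
    stop("rv_endo_semi: endocardial surface must lie strictly inside the epicardial one")
  }
  walls <- list(
    lv_endo = ellipsoid_wall(c(0, 0, 0), lv_endo_semi),
    lv_epi = ellipsoid_wall(c(0, 0, 0), lv_epi_semi),
    rv_endo = ellipsoid_wall(rv_center, rv_endo_semi),
    rv_epi = ellipsoid_wall(rv_center, rv_epi_semi),
    base = plane_wall(c(0, 0, base_z), c(0, 0, 1)))
  regions <- list(
    LV = c(lv_epi = -1L, lv_endo = 1L, base = -1L),
    RV = c(rv_epi = -1L, rv_endo = 1L, lv_epi = 1L, base = -1L))
  anatomy(walls, regions)
}

as_points <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

# signed wall value, vectorized over rows of p
wall_value <- function(wall, p) {
  p <- as_points(p)
  if (wall$type == "ellipsoid") {
    q <- sweep(p, 2, wall$center)
    rowSums(sweep(q, 2, wall$semi, "/")^2) - 1
  } else {
    drop(sweep(p, 2, wall$point) %*% wall$normal)
  }
}

#' Tissue membership test
#'
#' @param p a point or an n x 3 matrix of points (mm)
#' @param anat a `coro_anatomy`
#' @return logical vector: whether each point lies in (or on the boundary of)
#'   any tissue region
#' @export
inside_tissue <- function(p, anat) {
  p <- as_points(p)
  vals <- lapply(anat$walls, wall_value, p = p)
  ok <- rep(FALSE, nrow(p))
  for (r in anat$regions) {
    rok <- rep(TRUE, nrow(p))
    for (w in names(r)) {
      rok <- rok & if (r[[w]] < 0) vals[[w]] <= BOUNDARY_TOL else vals[[w]] >= -BOUNDARY_TOL
    }
    ok <- ok | rok
  }
  ok
}

#' Region (ventricle) membership
#'
#' @param p points (n x 3)
#' @param anat a `coro_anatomy`
#' @return character vector of region names (first matching region), NA for
#'   points outside tissue
#' @export
region_of <- function(p, anat) {
  p <- as_points(p)
  vals <- lapply(anat$walls, wall_value, p = p)
  out <- rep(NA_character_, nrow(p))
  for (rn in names(anat$regions)) {
    r <- anat$regions[[rn]]
    rok <- rep(TRUE, nrow(p))
    for (w in names(r)) {
      rok <- rok & if (r[[w]] < 0) vals[[w]] <= BOUNDARY_TOL else vals[[w]] >= -BOUNDARY_TOL
    }
    out[is.na(out) & rok] <- rn
  }
  out
}

# Nearest point on an ellipsoid surface from arbitrary points (inside or
# outside), via bisection on the Lagrange parameter t of
# x_i = c_i + a_i^2 q_i / (t + a_i^2). Vectorized over rows.
ellipsoid_nearest <- function(p, center, semi) {
  p <- as_points(p)
  q <- sweep(p, 2, center)
  # measure-zero axis-aligned degeneracies: nudge exact zeros
  q[abs(q) < 1e-9] <- 1e-9
  a2 <- semi^2
  n <- nrow(q)
  f <- function(t) {
    # t: vector length n
    s <- 0
    for (i in 1:3) s <- s + (semi[i] * q[, i] / (t + a2[i]))^2
    s - 1
  }
  lo <- rep(-min(a2) + 1e-12 * max(a2), n)
  hi <- pmax(sqrt(rowSums(q^2)) * max(semi), max(a2))
  for (k in 1:60) {
    grow <- f(hi) > 0
    if (!any(grow)) break
    hi[grow] <- hi[grow] * 2
  }
  for (k in 1:100) {
    mid <- 0.5 * (lo + hi)
    pos <- f(mid) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  t <- 0.5 * (lo + hi)
  x <- q
  for (i in 1:3) x[, i] <- center[i] + a2[i] * q[, i] / (t + a2[i])
  list(point = x, distance = sqrt(rowSums((p - x)^2)))
}

# Nearest surface point and distance for any wall type.
wall_nearest <- function(wall, p) {
  p <- as_points(p)
  if (wall$type == "ellipsoid") {
    ellipsoid_nearest(p, wall$center, wall$semi)
  } else {
    g <- drop(sweep(p, 2, wall$point) %*% wall$normal)
    list(point = p - outer(g, wall$normal), distance = abs(g))
  }
}

#' Boundary normals and distances at a tissue point
#'
#' For each wall of the anatomy, the unit normal at the nearest surface point
#' oriented away from the wall toward the query point (for tissue points:
#' into the tissue), and the Euclidean distance to that surface point.
#'
#' @param p a single tissue point (mm)
#' @param anat a `coro_anatomy`
#' @return named list per wall: `normal` (unit), `distance` (mm)
#' @export
boundary_normals <- function(p, anat) {
  p <- as.numeric(p)
  if (!inside_tissue(p, anat)) {
    stop("point outside tissue; use the repair path for violated positions")
  }
  lapply(anat$walls, function(w) {
    nr <- wall_nearest(w, p)
    d <- nr$distance[1]
    v <- p - nr$point[1, ]
    n <- if (d > 1e-12) v / d else {
      # on the wall: fall back to the wall's own normal oriented into tissue
      g <- wall_gradient(w, p)
      probe <- p + 0.5 * g
      if (inside_tissue(probe, anat)) g else -g
    }
    list(normal = n, distance = d)
  })
}

# outward unit gradient of the wall value at p
wall_gradient <- function(wall, p) {
  if (wall$type == "ellipsoid") {
    g <- 2 * (p - wall$center) / wall$semi^2
    g / sqrt(sum(g^2))
  } else {
    wall$normal
  }
}

# Flatten an anatomy into plain numeric structures for the C++ engine:
# per-wall type (0 ellipsoid, 1 plane) and a 6-vector of parameters
# (center,semi) or (point,normal); regions as a matrix of conditions.
anatomy_to_cpp <- function(anat) {
  wn <- names(anat$walls)
  types <- vapply(anat$walls, function(w) if (w$type == "ellipsoid") 0L else 1L,
                  integer(1))
  params <- t(vapply(anat$walls, function(w) {
    if (w$type == "ellipsoid") c(w$center, w$semi) else c(w$point, w$normal)
  }, numeric(6)))
  reg <- matrix(0L, nrow = length(anat$regions), ncol = length(wn),
                dimnames = list(names(anat$regions), wn))
  for (rn in names(anat$regions)) {
    r <- anat$regions[[rn]]
    reg[rn, names(r)] <- as.integer(r)
  }
  list(types = as.integer(types), params = params, regions = reg)
}

#' @export
print.coro_anatomy <- function(x, ...) {
  cat("Anatomy: ", length(x$walls), " walls (",
      paste(names(x$walls), collapse = ", "), "), regions: ",
      paste(names(x$regions), collapse = ", "), "\n", sep = "")
  invisible(x)
}
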