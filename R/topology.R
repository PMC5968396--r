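# Arterial tree topology: stochastic generation of binary Strahler-ordered
# trees (orders 6-11) from morphometry statistics.
#
# Representation: a `coro_tree` holds a segment table in topological order
# (parents precede children). Segment i's distal node is "node i"; its
# proximal node is the distal node of its parent (node 0 = inlet/ostium).
# A fresh tree is strictly binary: every non-terminal segment has exactly two
# children. Pruning may leave serial pass-through nodes (one child), which the
# flow solver treats as series resistances.

PA_PER_MMHG <- 133.322

#' Poiseuille resistance of a cylindrical segment
#'
#' `R = 8 * mu * L / (pi * r^4)`, returned in SI units (Pa.s/m^3) with
#' millimetre inputs converted internally.
#'
#' @param length_mm segment length (mm); may be 0
#' @param radius_mm lumen radius (mm); must be > 0
#' @param viscosity blood viscosity (Pa.s)
#' @return resistance in Pa.s/m^3
#' @export
segment_resistance <- function(length_mm, radius_mm, viscosity) {
  if (any(radius_mm <= 0)) stop("radius_mm: must be > 0")
  if (any(length_mm < 0)) stop("length_mm: must be >= 0")
  if (any(viscosity <= 0)) stop("viscosity: must be > 0")
  8 * viscosity * (length_mm * 1e-3) / (pi * (radius_mm * 1e-3)^4)
}

# Positive (truncated-normal) segment length draws.
draw_lengths <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Sample one arterial element
#'
#' Draws the segment count consistently with the order's segments-per-element
#' ratio (1 + Poisson(ratio - 1), so the expectation equals the ratio) and
#' segment lengths from a positive-truncated normal. All segments of an
#' element share the order's (constant) radius.
#'
#' @param order Strahler order in 6..11
#' @param table a `coro_morphometry`
#' @return list with `order`, `radius` (mm) and `segment_lengths` (mm)
#' @export
sample_element <- function(order, table) {
  row <- order_row(table, order)
  k <- 1L + rpois(1L, row$segments_per_element - 1)
  list(order = as.integer(order),
       radius = row$mean_radius,
       segment_lengths = draw_lengths(k, row$mean_segment_length,
                                      row$sd_segment_length))
}

# Growable segment store used during assembly.
new_store <- function(cap = 1024L) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$parent <- integer(cap); env$order <- integer(cap)
  env$element <- integer(cap); env$length <- numeric(cap)
  env$radius <- numeric(cap); env$n_elem <- 0L
  env
}

store_add <- function(env, parent, order, element, length, radius) {
  n <- env$n + 1L
  if (n > length(env$parent)) {
    for (f in c("parent", "order", "element")) {
      env[[f]] <- c(env[[f]], vector(typeof(env[[f]]), length(env[[f]])))
    }
    for (f in c("length", "radius")) {
      env[[f]] <- c(env[[f]], numeric(length(env[[f]])))
    }
  }
  env$n <- n
  env$parent[n] <- parent; env$order[n] <- order; env$element[n] <- element
  env$length[n] <- length; env$radius[n] <- radius
  n
}

# Sample a side-branch order for a parent of order m.
sample_side_order <- function(table, m) {
  w <- side_branch_weights(table, m)
  if (sum(w) <= 0) return(m - 1L)
  ords <- as.integer(names(w))
  if (length(ords) == 1L) return(ords)
  ords[sample.int(length(ords), 1L, prob = w)]
}

# Recursively append an element of `order` whose first segment attaches below
# `parent_seg`; returns nothing (writes into the store).
add_element <- function(env, table, order, parent_seg) {
  env$n_elem <- env$n_elem + 1L
  eid <- env$n_elem
  row <- order_row(table, order)
  if (order == 6L) {
    # No side branches are possible below order 6, so an order-6 element is a
    # single terminal segment carrying the element's total sampled length.
    k <- 1L + rpois(1L, row$segments_per_element - 1)
    len <- sum(draw_lengths(k, row$mean_segment_length, row$sd_segment_length))
    store_add(env, parent_seg, 6L, eid, len, row$mean_radius)
    return(invisible(NULL))
  }
  k <- 1L + rpois(1L, row$segments_per_element - 1)
  lens <- draw_lengths(k, row$mean_segment_length, row$sd_segment_length)
  prev <- parent_seg
  for (j in seq_len(k)) {
    sid <- store_add(env, prev, as.integer(order), eid, lens[j], row$mean_radius)
    if (j < k) {
      # internal junction: one lower-order side branch
      add_element(env, table, sample_side_order(table, order), sid)
    }
    prev <- sid
  }
  # element end: two order-(m-1) daughters
  add_element(env, table, order - 1L, prev)
  add_element(env, table, order - 1L, prev)
  invisible(NULL)
}

# Sample a trunk (root-element) segment-length chain honouring total bounds.
sample_trunk <- function(table, order, lo, hi, max_retries) {
  row <- order_row(table, order)
  k_mid <- max(1L, as.integer(round((lo + hi) / 2 / row$mean_segment_length)))
  for (try in seq_len(max_retries)) {
    k <- 1L + rpois(1L, k_mid - 1L)
    lens <- draw_lengths(k, row$mean_segment_length, row$sd_segment_length)
    if (sum(lens) >= lo && sum(lens) <= hi) return(lens)
  }
  stop("trunk length bounds [", lo, ", ", hi, "] mm unsatisfiable after ",
       max_retries, " resamples for order-", order, " trunk")
}

#' Assemble a stochastic coronary tree topology
#'
#' Builds a binary arterial tree from the morphometry table. The root element
#' (trunk) of the named artery is resampled until its total length falls in
#' the configured bounds (RCA 120-192 mm; LAD and LCX 100-160 mm). Within an
#' element of k segments, each of the k-1 internal junctions spawns one
#' lower-order side branch drawn from the connectivity-matrix row, and the
#' element terminates in two daughters one order lower (order-6 elements are
#' terminal). For the LAD, an LCX sub-tree of order 10 (with its own bounded
#' trunk) is attached at a junction chosen uniformly from the proximal third
#' of the LAD trunk.
#'
#' @param name `"RCA"` or `"LAD"` (the LAD tree carries the LCX sub-tree)
#' @param table a human-scaled `coro_morphometry`
#' @param seed optional integer; when given, seeds R's RNG for a reproducible
#'   topology
#' @param max_retries resampling budget for the trunk length bounds
#' @return a `coro_tree`
#' @export
assemble_tree <- function(name = c("RCA", "LAD"), table, seed = NULL,
                          max_retries = 64L) {
  name <- match.arg(name)
  validate_morphometry(table)
  if (!is.null(seed)) set.seed(seed)
  lb <- table$length_bounds
  bounds <- if (name == "RCA") c(lb$rca_min, lb$rca_max) else c(lb$left_min, lb$left_max)

  env <- new_store()
  env$n_elem <- 1L
  root_order <- 11L
  row <- order_row(table, root_order)
  lens <- sample_trunk(table, root_order, bounds[1], bounds[2], max_retries)
  k <- length(lens)
  # LCX attaches at an internal junction in the proximal third of the LAD trunk
  lcx_at <- if (name == "LAD" && k > 1L) {
    cand <- seq_len(max(1L, floor((k - 1L) / 3)))
    cand[sample.int(length(cand), 1L)]
  } else 0L
  trunk_ids <- integer(k)
  lcx_root <- NA_integer_
  prev <- 0L
  for (j in seq_len(k)) {
    sid <- store_add(env, prev, root_order, 1L, lens[j], row$mean_radius)
    trunk_ids[j] <- sid
    if (j < k) {
      if (j == lcx_at) {
        # LCX: order-10 element with its own bounded trunk, then the usual
        # recursive assembly below it
        env$n_elem <- env$n_elem + 1L
        eid <- env$n_elem
        lrow <- order_row(table, 10L)
        llens <- sample_trunk(table, 10L, lb$left_min, lb$left_max, max_retries)
        lprev <- sid
        lcx_trunk <- integer(length(llens))
        for (jj in seq_along(llens)) {
          lsid <- store_add(env, lprev, 10L, eid, llens[jj], lrow$mean_radius)
          lcx_trunk[jj] <- lsid
          if (jj < length(llens)) {
            add_element(env, table, sample_side_order(table, 10L), lsid)
          }
          lprev <- lsid
        }
        add_element(env, table, 9L, lprev)
        add_element(env, table, 9L, lprev)
        lcx_root <- lcx_trunk[1]
        attr(lcx_root, "trunk") <- lcx_trunk
      } else {
        add_element(env, table, sample_side_order(table, root_order), sid)
      }
    }
    prev <- sid
  }
  add_element(env, table, root_order - 1L, prev)
  add_element(env, table, root_order - 1L, prev)

  n <- env$n
  seg <- data.frame(id = seq_len(n),
                    parent = env$parent[seq_len(n)],
                    order = env$order[seq_len(n)],
                    element = env$element[seq_len(n)],
                    length = env$length[seq_len(n)],
                    radius = env$radius[seq_len(n)])
  seg$resistance <- segment_resistance(seg$length, seg$radius, table$viscosity)
  tree <- structure(list(name = name, seg = seg, trunk_ids = trunk_ids,
                         lcx_root = lcx_root,
                         lcx_trunk = if (is.na(lcx_root)) integer(0) else attr(lcx_root, "trunk"),
                         viscosity = table$viscosity, seed = seed),
                    class = "coro_tree")
  tree$lcx_root <- as.integer(tree$lcx_root)
  tree
}

# children index lists: ch1/ch2 integer vectors (NA when absent)
tree_children <- function(tree) {
  n <- nrow(tree$seg)
  ch1 <- rep(NA_integer_, n); ch2 <- rep(NA_integer_, n)
  p <- tree$seg$parent
  for (i in seq_len(n)) {
    pi <- p[i]
    if (pi > 0L) {
      if (is.na(ch1[pi])) ch1[pi] <- i
      else if (is.na(ch2[pi])) ch2[pi] <- i
      else stop("segment ", pi, " has more than two children")
    }
  }
  list(ch1 = ch1, ch2 = ch2)
}

tree_depths <- function(tree) {
  p <- tree$seg$parent
  d <- integer(nrow(tree$seg))
  for (i in seq_along(p)) d[i] <- if (p[i] == 0L) 0L else d[p[i]] + 1L
  d
}

#' Terminal segments of a tree
#'
#' @param tree a `coro_tree`
#' @return integer ids of segments with no children (all order 6 in a fresh
#'   tree; their distal nodes are the perfusion outlets)
#' @export
terminal_ids <- function(tree) {
  which(!(tree$seg$id %in% tree$seg$parent))
}

#' Total trunk length
#'
#' Sum of segment lengths along the maximal-order element chain from the root
#' (the artery's main trunk).
#'
#' @param tree a `coro_tree`
#' @return length in mm
#' @export
total_trunk_length <- function(tree) {
  sum(tree$seg$length[tree$trunk_ids])
}

#' Recompute Strahler orders from the leaves
#'
#' Assigns order 6 to terminals and propagates rootward: at a junction of two
#' equal orders the parent order increments, otherwise the larger order is
#' kept; serial (single-child) nodes keep the child order. For a freshly
#' assembled tree this reproduces the morphometric order labels exactly.
#'
#' @param tree a `coro_tree`
#' @return integer vector of recomputed orders per segment
#' @export
strahler_orders <- function(tree) {
  ch <- tree_children(tree)
  n <- nrow(tree$seg)
  s <- integer(n)
  for (i in rev(seq_len(n))) {
    if (is.na(ch$ch1[i])) s[i] <- 6L
    else if (is.na(ch$ch2[i])) s[i] <- s[ch$ch1[i]]
    else {
      a <- s[ch$ch1[i]]; b <- s[ch$ch2[i]]
      s[i] <- if (a == b) a + 1L else max(a, b)
    }
  }
  s
}

#' Validate a tree topology
#'
#' Checks the structural invariants: exactly one root; parents precede
#' children (acyclic, connected); every non-terminal node has two daughters
#' (one is tolerated only when `allow_series = TRUE`, the state after
#' pruning); terminals have order 6; daughter order never exceeds parent
#' order; positive lengths and radii; and the stored resistance matches the
#' Poiseuille law to 1e-12 relative.
#'
#' @param tree a `coro_tree`
#' @param allow_series allow serial pass-through nodes (post-pruning state)
#' @return `tree`, invisibly; stops with a named-field message otherwise
#' @export
validate_tree <- function(tree, allow_series = FALSE) {
  seg <- tree$seg
  n <- nrow(seg)
  if (!identical(seg$id, seq_len(n))) stop("seg$id: must be 1..n in order")
  if (sum(seg$parent == 0L) != 1L) stop("seg$parent: exactly one root required")
  if (any(seg$parent >= seg$id)) stop("seg$parent: parents must precede children")
  nch <- tabulate(seg$parent[seg$parent > 0L], nbins = n)
  if (any(nch > 2L)) stop("node adjacency: a node has more than two daughters")
  if (!allow_series && any(nch == 1L)) {
    stop("node adjacency: serial (single-daughter) node in a fresh tree")
  }
  if (any(seg$order[nch == 0L] != 6L)) {
    stop("terminal order: every terminal segment must have order 6")
  }
  has_p <- seg$parent > 0L
  if (any(seg$order[has_p] > seg$order[seg$parent[has_p]])) {
    stop("order monotonicity: daughter order exceeds parent order")
  }
  if (any(seg$length <= 0)) stop("seg$length: must be > 0")
  if (any(seg$radius <= 0)) stop("seg$radius: must be > 0")
  expect_r <- segment_resistance(seg$length, seg$radius, tree$viscosity)
  if (any(abs(seg$resistance - expect_r) > 1e-12 * expect_r)) {
    stop("seg$resistance: inconsistent with Poiseuille law")
  }
  for (e in split(seq_len(n), seg$element)) {
    if (length(unique(seg$order[e])) != 1L || length(unique(seg$radius[e])) != 1L) {
      stop("element: member segments must share order and radius")
    }
  }
  invisible(tree)
}

# Renumber a tree after deleting segments; `keep` is a logical row filter.
renumber_tree <- function(tree, keep) {
  map <- integer(nrow(tree$seg)); map[keep] <- seq_len(sum(keep))
  seg <- tree$seg[keep, , drop = FALSE]
  seg$id <- seq_len(nrow(seg))
  p <- seg$parent
  p[p > 0L] <- map[p[p > 0L]]
  seg$parent <- p
  rownames(seg) <- NULL
  tree$seg <- seg
  tree$trunk_ids <- map[tree$trunk_ids][keep[tree$trunk_ids]]
  if (!is.na(tree$lcx_root)) {
    tree$lcx_root <- if (keep[tree$lcx_root]) map[tree$lcx_root] else NA_integer_
    tree$lcx_trunk <- map[tree$lcx_trunk][keep[tree$lcx_trunk]]
  }
  if (!is.null(tree$pos)) tree$pos <- tree$pos[keep, , drop = FALSE]
  for (f in c("placed", "repaired", "preplaced")) {
    if (!is.null(tree[[f]])) tree[[f]] <- tree[[f]][keep]
  }
  tree
}

# All descendants (inclusive) of segment `id`.
descendant_ids <- function(tree, id) {
  n <- nrow(tree$seg)
  inset <- logical(n); inset[id] <- TRUE
  p <- tree$seg$parent
  if (id < n) {
    for (i in (id + 1L):n) if (p[i] > 0L && inset[p[i]]) inset[i] <- TRUE
  }
  which(inset)
}

#' Prune a sub-tree
#'
#' Removes segment `id` and its entire distal sub-tree. The parent junction
#' becomes a serial pass-through node (the sibling branch absorbs it), so the
#' result is validated with `allow_series = TRUE`.
#'
#' @param tree a `coro_tree`
#' @param id root segment of the sub-tree to remove (not the tree root)
#' @return pruned `coro_tree`
#' @export
prune_subtree <- function(tree, id) {
  if (tree$seg$parent[id] == 0L) stop("cannot prune the root segment")
  drop <- descendant_ids(tree, id)
  keep <- !(seq_len(nrow(tree$seg)) %in% drop)
  tree <- renumber_tree(tree, keep)
  validate_tree(tree, allow_series = TRUE)
}

#' Export a tree as an edge-list table
#'
#' One row per segment: id, parent node, child node, order, element, length,
#' radius (plus coordinates and placement status when geometry exists).
#'
#' @param tree a `coro_tree`
#' @return data frame
#' @export
as_segment_table <- function(tree) {
  seg <- tree$seg
  out <- data.frame(id = seg$id, parent_node = seg$parent, child_node = seg$id,
                    order = seg$order, element = seg$element,
                    L_mm = seg$length, r_mm = seg$radius)
  if (!is.null(tree$pos)) {
    out$x_mm <- tree$pos[, 1]; out$y_mm <- tree$pos[, 2]; out$z_mm <- tree$pos[, 3]
  }
  out
}

#' Write a tree edge list to CSV
#' @param tree a `coro_tree`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tree_csv <- function(tree, path) {
  write.csv(as_segment_table(tree), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.coro_tree <- function(x, ...) {
  term <- terminal_ids(x)
  cat("Coronary tree <", x$name, ">: ", nrow(x$seg), " segments, ",
      length(unique(x$seg$element)), " elements, ", length(term),
      " terminals; trunk ", format(total_trunk_length(x), digits = 4),
      " mm", if (!is.null(x$pos)) "; placed" else "", "\n", sep = "")
  invisible(x)
}
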