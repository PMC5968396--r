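# Virtual experiments on seeded ensembles: control, inlet-pressure sweeps,
# single-segment stenosis, order-wise blocking, and combined grids.
# Structural modifications change radii only (geometry is reused), so each
# condition is a cheap re-solve of flows on the placed trees.

#' Stenose a single segment
#'
#' Replaces one segment's radius and recomputes its Poiseuille resistance;
#' every other segment is untouched. The segment is detached into its own
#' element (elements have constant radius).
#'
#' @param tree a `coro_tree`
#' @param segment_id id of the segment to constrict
#' @param new_radius new lumen radius (mm)
#' @return modified `coro_tree`
#' @export
stenose_segment <- function(tree, segment_id, new_radius) {
  if (length(segment_id) != 1 || is.na(segment_id) ||
      segment_id < 1 || segment_id > nrow(tree$seg)) {
    stop("segment_id: selector must match exactly one segment")
  }
  if (new_radius <= 0) stop("new_radius: must be > 0")
  if (tree$seg$radius[segment_id] == new_radius) return(tree)
  tree$seg$radius[segment_id] <- new_radius
  tree$seg$element[segment_id] <- max(tree$seg$element) + 1L
  tree$seg$resistance[segment_id] <-
    segment_resistance(tree$seg$length[segment_id], new_radius, tree$viscosity)
  tree
}

#' Deterministic stenosis target on the LAD trunk
#'
#' The mid-trunk segment: the order-11 trunk segment whose chain midpoint is
#' nearest to half the total trunk length.
#'
#' @param tree the LAD `coro_tree`
#' @return segment id
#' @export
select_lad_stenosis_segment <- function(tree) {
  ids <- tree$trunk_ids
  lens <- tree$seg$length[ids]
  mid <- cumsum(lens) - lens / 2
  ids[which.min(abs(mid - sum(lens) / 2))]
}

#' Block all sub-trees of a Strahler order
#'
#' Reduces the radius of the root segment of every order-`order` sub-tree
#' (segments of that order whose parent has a higher order) by
#' `reduction_fraction` of its control value; for order 6 this is every
#' terminal segment. Resistances are recomputed.
#'
#' @param tree a `coro_tree`
#' @param order Strahler order in 6..10 (order 11 is single-segment stenosis
#'   territory)
#' @param reduction_fraction fraction removed from the radius, in (0, 1)
#'   (0.9 leaves 10% of the control radius)
#' @return modified `coro_tree`
#' @export
block_order <- function(tree, order, reduction_fraction) {
  if (!(order %in% 6:10)) stop("order: must be in 6..10")
  if (reduction_fraction <= 0 || reduction_fraction >= 1) {
    stop("reduction_fraction: must be in (0, 1)")
  }
  seg <- tree$seg
  pord <- rep(Inf, nrow(seg))
  has_p <- seg$parent > 0L
  pord[has_p] <- seg$order[seg$parent[has_p]]
  ids <- which(seg$order == order & pord > order)
  if (length(ids)) {
    seg$radius[ids] <- seg$radius[ids] * (1 - reduction_fraction)
    seg$element[ids] <- max(seg$element) + seq_along(ids)
    seg$resistance[ids] <- segment_resistance(seg$length[ids], seg$radius[ids],
                                              tree$viscosity)
    tree$seg <- seg
  }
  tree
}

#' Ensemble specification
#'
#' @param n_instances ensemble size (the study-scale default is 540)
#' @param base_seed integer; instance i uses seed `base_seed + i`
#' @return object of class `coro_ensemble_spec`
#' @export
ensemble_spec <- function(n_instances = 540L, base_seed = 1L) {
  if (n_instances < 1) stop("n_instances: must be >= 1")
  structure(list(n_instances = as.integer(n_instances),
                 base_seed = as.integer(base_seed)),
            class = "coro_ensemble_spec")
}

#' Simulate a seeded ensemble under one or more conditions
#'
#' Generates `n_instances` placed whole-heart instances (seed `base_seed + i`
#' for instance i), applies each condition's structural modification (radii
#' only; node positions are reused), re-solves flows under the condition's
#' boundary, and collects per-instance voxel deposits and total terminal
#' outflow.
#'
#' @param spec a `coro_ensemble_spec`
#' @param table human-scaled `coro_morphometry`
#' @param anat a `coro_anatomy`
#' @param conditions named list; each entry is a list with optional `modify`
#'   (a function `instance -> instance`) and optional `boundary` (a
#'   `coro_boundary`; default control 100/20 mmHg)
#' @param boundary default boundary for conditions without their own
#' @param params a `coro_avoidance`
#' @param spacing voxel edge (mm) of the deposit grid
#' @param engine placement engine
#' @return object of class `coro_ensemble`: `grid` (tissue skeleton),
#'   `deposits[[condition]][[i]]`, `totals` (n x conditions matrix, mm^3/s),
#'   `pruned_fraction` per instance, plus the inputs
#' @export
simulate_ensemble <- function(spec, table, anat,
                              conditions = list(control = list()),
                              boundary = pressure_boundary(),
                              params = avoidance_params(),
                              spacing = 1, engine = "cpp") {
  grid <- tissue_grid(anat, spacing)
  cn <- names(conditions)
  if (is.null(cn) || any(cn == "")) stop("conditions: must be a named list")
  deposits <- setNames(lapply(cn, function(x) vector("list", spec$n_instances)), cn)
  totals <- matrix(NA_real_, spec$n_instances, length(cn),
                   dimnames = list(NULL, cn))
  pruned <- numeric(spec$n_instances)
  for (i in seq_len(spec$n_instances)) {
    inst <- generate_instance(table, anat, seed = spec$base_seed + i,
                              boundary = boundary, params = params,
                              engine = engine)
    pruned[i] <- mean(c(attr(inst$rca, "pruned_terminal_fraction"),
                        attr(inst$lad, "pruned_terminal_fraction")))
    for (cj in cn) {
      cond <- conditions[[cj]]
      ci <- inst[c("rca", "lad")]
      if (!is.null(cond$modify)) ci <- cond$modify(ci)
      bnd <- if (!is.null(cond$boundary)) cond$boundary else boundary
      tot <- 0
      for (tn in names(ci)) {
        ci[[tn]]$flow <- solve_flow(ci[[tn]], bnd)
        tot <- tot + ci[[tn]]$flow$total_inflow
      }
      deposits[[cj]][[i]] <- bf_deposits(ci, grid)
      totals[i, cj] <- tot
    }
  }
  structure(list(grid = grid, deposits = deposits, totals = totals,
                 pruned_fraction = pruned, spec = spec,
                 conditions = conditions, boundary = boundary,
                 spacing = spacing),
            class = "coro_ensemble")
}

#' Ensemble-mean BF map for a condition
#' @param ens a `coro_ensemble`
#' @param condition condition name (default first)
#' @return a `coro_bfmap`
#' @export
ensemble_map <- function(ens, condition = names(ens$deposits)[1]) {
  voxelize(ens$deposits[[condition]], ens$grid)
}

# condition constructors -----------------------------------------------------

#' Stenosis condition: constrict the mid-trunk LAD segment
#' @param radius_mm new radius of the selected LAD trunk segment
#' @param boundary optional condition-specific boundary
#' @return condition list for [simulate_ensemble()]
#' @export
cond_stenosis <- function(radius_mm, boundary = NULL) {
  list(modify = function(inst) {
    id <- select_lad_stenosis_segment(inst$lad)
    inst$lad <- stenose_segment(inst$lad, id, radius_mm)
    inst
  }, boundary = boundary)
}

#' Order-blocking condition
#' @param order Strahler order 6..10
#' @param fraction radius reduction fraction in (0, 1)
#' @param boundary optional condition-specific boundary
#' @return condition list for [simulate_ensemble()]
#' @export
cond_block <- function(order, fraction, boundary = NULL) {
  list(modify = function(inst) {
    lapply(inst, block_order, order = order, reduction_fraction = fraction)
  }, boundary = boundary)
}

#' Pressure condition (structure unmodified)
#' @param inlet_mmHg inlet pressure, mmHg
#' @param terminal_mmHg terminal pressure, mmHg
#' @return condition list for [simulate_ensemble()]
#' @export
cond_pressure <- function(inlet_mmHg, terminal_mmHg = 20) {
  list(modify = NULL, boundary = pressure_boundary(inlet_mmHg, terminal_mmHg))
}

#' Experiment configuration
#'
#' @param kind one of `control`, `pressure_sweep`, `stenosis`, `block_order`,
#'   `combined`
#' @param pressures inlet pressures (mmHg) for sweeps (default 30..200 by 10)
#' @param stenosis_radii LAD stenosis radii (mm)
#' @param block_orders Strahler orders to block
#' @param fractions radius-reduction fractions
#' @param combined_pressures pressures of the combined grid
#' @param combined_orders orders of the combined grid
#' @param terminal_pressure shared terminal pressure (mmHg)
#' @return object of class `coro_experiment_config`
#' @export
experiment_config <- function(kind = c("control", "pressure_sweep", "stenosis",
                                       "block_order", "combined"),
                              pressures = seq(30, 200, by = 10),
                              stenosis_radii = c(1.53, 0.25, 0.075, 0.01),
                              block_orders = 6:10,
                              fractions = c(0.7, 0.8, 0.9),
                              combined_pressures = c(30, 100, 200),
                              combined_orders = c(6, 10),
                              terminal_pressure = 20) {
  kind <- match.arg(kind)
  if (any(pressures <= terminal_pressure)) {
    stop("inlet_pressure: all sweep pressures must exceed the terminal pressure (",
         terminal_pressure, " mmHg)")
  }
  if (any(stenosis_radii <= 0)) stop("stenosis_radii: must be > 0")
  if (any(fractions <= 0 | fractions >= 1)) stop("fractions: must be in (0, 1)")
  if (!all(block_orders %in% 6:10)) stop("block_orders: must be in 6..10")
  structure(list(kind = kind, pressures = pressures,
                 stenosis_radii = stenosis_radii, block_orders = block_orders,
                 fractions = fractions, combined_pressures = combined_pressures,
                 combined_orders = combined_orders,
                 terminal_pressure = terminal_pressure),
            class = "coro_experiment_config")
}

# expand a config into named conditions
config_conditions <- function(config) {
  tp <- config$terminal_pressure
  switch(config$kind,
    control = list(control = list()),
    pressure_sweep = setNames(
      lapply(config$pressures, cond_pressure, terminal_mmHg = tp),
      paste0("P", config$pressures)),
    stenosis = c(list(control = list()),
                 setNames(lapply(config$stenosis_radii, cond_stenosis),
                          paste0("r", config$stenosis_radii))),
    block_order = c(list(control = list()), {
      grid <- expand.grid(o = config$block_orders, f = config$fractions)
      setNames(lapply(seq_len(nrow(grid)), function(i)
        cond_block(grid$o[i], grid$f[i])),
        paste0("SN", grid$o, "_f", grid$f))
    }),
    combined = {
      grid <- expand.grid(p = config$combined_pressures,
                          o = config$combined_orders, f = config$fractions)
      setNames(lapply(seq_len(nrow(grid)), function(i) {
        c0 <- cond_block(grid$o[i], grid$f[i])
        c0$boundary <- pressure_boundary(grid$p[i], tp)
        c0
      }), paste0("SN", grid$o, "_f", grid$f, "_P", grid$p))
    })
}

#' Heterogeneity metrics of an ensemble condition
#'
#' @param ens a `coro_ensemble`
#' @param condition condition name
#' @param anat the anatomy (for transmural layering); optional
#' @param dmap precomputed [endocardial_distance_map()]; optional
#' @return list: `total_bf` (ensemble-mean total terminal outflow, mm^3/s),
#'   `mean_voxel_bf`, `rd_high`, `rd_low`, `fd`, `modality`, and (given an
#'   anatomy) `transmural`
#' @export
condition_metrics <- function(ens, condition, anat = NULL, dmap = NULL) {
  map <- ensemble_map(ens, condition)
  het <- heterogeneity(map)
  pdf <- relative_flow_pdf(map)
  out <- list(total_bf = mean(ens$totals[, condition]),
              mean_voxel_bf = mean(map$values[map$mask]),
              rd_high = het$rd_high, rd_low = het$rd_low, fd = het$fd,
              modality = modality_count(pdf))
  if (!is.null(anat)) {
    if (is.null(dmap)) dmap <- endocardial_distance_map(anat, map)
    out$transmural <- transmural_profile(map, dmap)
  }
  out
}

#' Run a configured experiment over a seeded ensemble
#'
#' Expands the configuration into its condition grid, simulates the ensemble
#' once per seed set (geometry shared across conditions), and computes the
#' per-condition heterogeneity metrics. A failing condition is recorded with
#' its error message without aborting the grid.
#'
#' @param config a `coro_experiment_config`
#' @param spec a `coro_ensemble_spec`
#' @param table human-scaled `coro_morphometry`
#' @param anat a `coro_anatomy`
#' @param transmural include transmural profiles (needs a distance map;
#'   slower)
#' @param ... passed to [simulate_ensemble()]
#' @return list: `config`, `ensemble`, `metrics` (per condition), `summary`
#'   data frame
#' @export
run_experiment <- function(config, spec, table, anat, transmural = FALSE, ...) {
  conds <- config_conditions(config)
  ens <- simulate_ensemble(spec, table, anat, conditions = conds, ...)
  dmap <- if (transmural) {
    endocardial_distance_map(anat, ens$grid)
  } else NULL
  metrics <- lapply(names(conds), function(cn) {
    tryCatch(condition_metrics(ens, cn, anat = if (transmural) anat,
                               dmap = dmap),
             error = function(e) list(error = conditionMessage(e)))
  })
  names(metrics) <- names(conds)
  ok <- !vapply(metrics, function(m) !is.null(m$error), logical(1))
  summary <- data.frame(
    condition = names(conds),
    total_bf = vapply(metrics, function(m) m$total_bf %||% NA_real_, 0),
    mean_voxel_bf = vapply(metrics, function(m) m$mean_voxel_bf %||% NA_real_, 0),
    rd_high = vapply(metrics, function(m) m$rd_high %||% NA_real_, 0),
    fd = vapply(metrics, function(m) m$fd %||% NA_real_, 0),
    modality = vapply(metrics, function(m) as.numeric(m$modality %||% NA), 0),
    row.names = NULL)
  list(config = config, ensemble = ens, metrics = metrics, summary = summary,
       failed = names(conds)[!ok])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
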