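# Steady-state network hemodynamics on a coronary tree.
#
# Units: SI internally (Pa, m^3/s, Pa.s/m^3); interfaces use mmHg and mm^3/s
# (1 mmHg = 133.322 Pa, 1 m^3/s = 1e9 mm^3/s).

M3S_PER_MM3S <- 1e-9

#' Pressure boundary conditions
#'
#' Fixed inlet (ostium) and shared terminal (order-6 outlet) pressures. The
#' control condition is 100 mmHg at the inlet and 20 mmHg at every terminal.
#'
#' @param inlet_pressure inlet pressure, mmHg
#' @param terminal_pressure terminal pressure, mmHg
#' @return object of class `coro_boundary`
#' @export
pressure_boundary <- function(inlet_pressure = 100, terminal_pressure = 20) {
  if (!(inlet_pressure > terminal_pressure)) {
    stop("inlet_pressure: must exceed terminal_pressure (",
         inlet_pressure, " <= ", terminal_pressure, ")")
  }
  structure(list(inlet_pressure = inlet_pressure,
                 terminal_pressure = terminal_pressure),
            class = "coro_boundary")
}

# Downstream equivalent resistance per segment (SI), by reverse level order:
# series along chains, parallel (harmonic) at bifurcations.
downstream_resistance <- function(tree) {
  seg <- tree$seg
  n <- nrow(seg)
  ch <- tree_children(tree)
  depth <- tree_depths(tree)
  rdown <- numeric(n)
  for (d in sort(unique(depth), decreasing = TRUE)) {
    i <- which(depth == d)
    c1 <- ch$ch1[i]; c2 <- ch$ch2[i]
    sub <- numeric(length(i))
    both <- !is.na(c1) & !is.na(c2)
    one <- !is.na(c1) & is.na(c2)
    sub[both] <- 1 / (1 / rdown[c1[both]] + 1 / rdown[c2[both]])
    sub[one] <- rdown[c1[one]]
    rdown[i] <- seg$resistance[i] + sub
  }
  rdown
}

#' Equivalent resistance of a tree
#'
#' Series/parallel reduction of all segment Poiseuille resistances from the
#' terminals to the root, i.e. the total resistance between the inlet and the
#' common terminal pressure node.
#'
#' @param tree a `coro_tree`
#' @return resistance in Pa.s/m^3
#' @export
equivalent_resistance <- function(tree) {
  downstream_resistance(tree)[which(tree$seg$parent == 0L)]
}

#' Solve steady-state pressures and flows
#'
#' Imposes the pressure boundary conditions and propagates flow from the root:
#' the total inflow is `(P_in - P_term) / R_eq`; at every bifurcation the flow
#' splits inversely to the daughters' downstream equivalent resistances; node
#' pressures follow the per-segment Poiseuille drop `dP = R * Q`. The solution
#' satisfies flow conservation at every node and fixes every terminal node at
#' the terminal pressure exactly.
#'
#' @param tree a `coro_tree`
#' @param boundary a `coro_boundary`
#' @return object of class `coro_flow`: `node_pressures` (mmHg, indexed by
#'   segment distal node; attribute `inlet` holds the inlet node pressure),
#'   `segment_flows` (mm^3/s), `total_inflow` (mm^3/s)
#' @export
solve_flow <- function(tree, boundary = pressure_boundary()) {
  seg <- tree$seg
  n <- nrow(seg)
  ch <- tree_children(tree)
  depth <- tree_depths(tree)
  rdown <- numeric(n)   # equivalent resistance of segment + its sub-tree
  rsub <- numeric(n)    # downstream (sub-tree only) part, kept separately
  for (d in sort(unique(depth), decreasing = TRUE)) {
    i <- which(depth == d)
    c1 <- ch$ch1[i]; c2 <- ch$ch2[i]
    sub <- numeric(length(i))
    both <- !is.na(c1) & !is.na(c2)
    one <- !is.na(c1) & is.na(c2)
    sub[both] <- 1 / (1 / rdown[c1[both]] + 1 / rdown[c2[both]])
    sub[one] <- rdown[c1[one]]
    rsub[i] <- sub
    rdown[i] <- seg$resistance[i] + sub
  }
  p_in <- boundary$inlet_pressure * PA_PER_MMHG
  p_term <- boundary$terminal_pressure * PA_PER_MMHG

  # propagate the drop-to-terminal multiplicatively (delta_dist =
  # delta_prox * rsub / rdown): avoids the catastrophic cancellation of
  # p_dist - p_term at deep nodes and conserves flow to machine precision
  q <- numeric(n)       # m^3/s
  delta <- numeric(n)   # p_dist - p_term, Pa
  for (d in sort(unique(depth))) {
    i <- which(depth == d)
    d_prox <- if (d == 0L) rep(p_in - p_term, length(i)) else delta[seg$parent[i]]
    q[i] <- d_prox / rdown[i]
    delta[i] <- d_prox * (rsub[i] / rdown[i])
  }
  p_dist <- p_term + delta   # exactly p_term at terminals (rsub = 0)

  structure(list(
    node_pressures = structure(p_dist / PA_PER_MMHG,
                               inlet = boundary$inlet_pressure),
    segment_flows = q / M3S_PER_MM3S,
    total_inflow = q[which(seg$parent == 0L)] / M3S_PER_MM3S,
    boundary = boundary), class = "coro_flow")
}

#' Total terminal outflow of a solution
#'
#' Sum of flows through the terminal (order-6 outlet) segments; by
#' conservation this equals the root inflow.
#'
#' @param solution a `coro_flow`
#' @param tree the `coro_tree` it was solved on
#' @return outflow in mm^3/s
#' @export
total_terminal_outflow <- function(solution, tree) {
  sum(solution$segment_flows[terminal_ids(tree)])
}

#' Export a flow solution as a per-segment CSV
#' @param solution a `coro_flow`
#' @param tree the solved `coro_tree`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_flow_csv <- function(solution, tree, path) {
  df <- data.frame(id = tree$seg$id,
                   order = tree$seg$order,
                   Q_mm3_s = solution$segment_flows,
                   P_distal_mmHg = as.numeric(solution$node_pressures))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.coro_flow <- function(x, ...) {
  cat("Steady-state flow solution: inlet ", attr(x$node_pressures, "inlet"),
      " mmHg, terminals ", x$boundary$terminal_pressure, " mmHg, total inflow ",
      format(x$total_inflow, digits = 5), " mm^3/s\n", sep = "")
  invisible(x)
}
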