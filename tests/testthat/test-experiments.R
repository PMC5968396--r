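test_that("stenosis replaces one radius and its resistance only", {
  tab <- test_table()
  tree <- assemble_tree("LAD", tab, seed = 6)
  id <- select_lad_stenosis_segment(tree)
  expect_true(id %in% tree$trunk_ids)
  # identity when the radius is unchanged
  expect_identical(stenose_segment(tree, id, tree$seg$radius[id])$seg, tree$seg)
  # halving the radius multiplies that resistance by exactly 16
  t2 <- stenose_segment(tree, id, tree$seg$radius[id] / 2)
  expect_equal(t2$seg$resistance[id], tree$seg$resistance[id] * 16)
  expect_equal(t2$seg$resistance[-id], tree$seg$resistance[-id])
  expect_equal(t2$seg$radius[-id], tree$seg$radius[-id])
  # severe stenosis ratio: (1.53 / 0.01)^4
  t3 <- stenose_segment(manual_tree(0L, 10, 1.53), 1L, 0.01)
  expect_equal(t3$seg$resistance[1] / segment_resistance(10, 1.53, 3.6e-3),
               (1.53 / 0.01)^4, tolerance = 1e-9)
  expect_equal((1.53 / 0.01)^4 / 1e8, 5.48, tolerance = 0.001)
  expect_error(stenose_segment(tree, 0L, 1), "segment_id")
  expect_error(stenose_segment(tree, id, -1), "new_radius")
})

test_that("order blocking hits exactly the sub-tree roots", {
  tab <- test_table()
  tree <- assemble_tree("RCA", tab, seed = 8)
  for (o in c(6L, 8L, 10L)) {
    # oracle: walk every edge and count entries into order-o sub-trees
    cnt <- 0L
    for (i in seq_len(nrow(tree$seg))) {
      p <- tree$seg$parent[i]
      if (tree$seg$order[i] == o && (p == 0L || tree$seg$order[p] > o)) {
        cnt <- cnt + 1L
      }
    }
    tb <- block_order(tree, o, 0.9)
    mod <- which(tb$seg$radius != tree$seg$radius)
    expect_equal(length(mod), cnt)
    expect_equal(tb$seg$radius[mod], tree$seg$radius[mod] * 0.1)
    expect_true(all(tree$seg$order[mod] == o))
  }
  # order 6 blocking reduces every terminal
  tb6 <- block_order(tree, 6L, 0.9)
  expect_equal(which(tb6$seg$radius != tree$seg$radius), terminal_ids(tree))
  # tiny fraction -> tree approaches identity
  tb0 <- block_order(tree, 7L, 1e-9)
  expect_equal(tb0$seg$resistance, tree$seg$resistance, tolerance = 1e-7)
  expect_error(block_order(tree, 11L, 0.9), "order")
  expect_error(block_order(tree, 7L, 1.2), "reduction_fraction")
})

test_that("total outflow is monotone in any single radius", {
  tab <- test_table()
  tree <- assemble_tree("RCA", tab, seed = 14)
  q0 <- solve_flow(tree)$total_inflow
  set.seed(1)
  for (id in sample(nrow(tree$seg), 5)) {
    shr <- stenose_segment(tree, id, tree$seg$radius[id] * 0.5)
    expect_lt(solve_flow(shr)$total_inflow, q0)
  }
})

test_that("a pressure condition reuses the control geometry voxel-for-voxel", {
  tab <- test_table()
  anat <- ventricle_anatomy()
  ens <- simulate_ensemble(ensemble_spec(3, 7), tab, anat,
                           conditions = list(control = list(),
                                             P100 = cond_pressure(100),
                                             P200 = cond_pressure(200)))
  # control and the explicit 100 mmHg sweep entry are identical
  expect_identical(ens$deposits$control, ens$deposits$P100)
  # sweep linearity: totals scale exactly with the pressure drop
  expect_equal(ens$totals[, "P200"] / ens$totals[, "P100"], rep(180 / 80, 3),
               tolerance = 1e-12)
  # relative-flow structure (hence RD and FD) is pressure-invariant
  m100 <- ensemble_map(ens, "P100"); m200 <- ensemble_map(ens, "P200")
  expect_equal(relative_flow_pdf(m200)$d, relative_flow_pdf(m100)$d,
               tolerance = 1e-12)
  h100 <- heterogeneity(m100); h200 <- heterogeneity(m200)
  expect_equal(h200$fd, h100$fd, tolerance = 1e-9)
})

test_that("ensemble runs are deterministic under the base seed", {
  tab <- test_table()
  anat <- ventricle_anatomy()
  e1 <- simulate_ensemble(ensemble_spec(2, 123), tab, anat)
  e2 <- simulate_ensemble(ensemble_spec(2, 123), tab, anat)
  expect_identical(e1$deposits, e2$deposits)
  expect_identical(e1$totals, e2$totals)
  j1 <- jsonlite::toJSON(condition_metrics(e1, "control"), auto_unbox = TRUE,
                         digits = NA)
  j2 <- jsonlite::toJSON(condition_metrics(e2, "control"), auto_unbox = TRUE,
                         digits = NA)
  expect_identical(j1, j2)
})

test_that("experiment configs validate and expand into condition grids", {
  expect_error(experiment_config("pressure_sweep", pressures = c(10, 100)),
               "inlet_pressure")
  expect_error(experiment_config("stenosis", stenosis_radii = c(1, -1)),
               "stenosis_radii")
  expect_error(experiment_config("block_order", fractions = 1.5), "fractions")
  cfg <- experiment_config("combined", combined_pressures = c(30, 100),
                           combined_orders = c(6, 10), fractions = 0.9)
  conds <- coroflow:::config_conditions(cfg)
  expect_equal(length(conds), 4L)
  expect_true(all(grepl("^SN(6|10)_f0.9_P(30|100)$", names(conds))))
})

test_that("run_experiment summarizes a small stenosis grid", {
  tab <- test_table()
  anat <- ventricle_anatomy()
  cfg <- experiment_config("stenosis", stenosis_radii = c(0.25, 0.01))
  res <- run_experiment(cfg, ensemble_spec(4, 55), tab, anat)
  expect_equal(nrow(res$summary), 3L)
  expect_equal(res$summary$condition, c("control", "r0.25", "r0.01"))
  expect_length(res$failed, 0)
  # constricting the LAD trunk can only reduce total flow, monotonically
  expect_true(all(diff(res$summary$total_bf) < 0))
})

test_that("the CLI runs, validates and reports usage errors", {
  out <- withr::local_tempdir()
  expect_equal(suppressMessages(
    coroflow_cli(c("control", "--n-instances", "2", "--seed", "1",
                   "--out-dir", out, "--log-level", "quiet"))), 0L)
  expect_true(file.exists(file.path(out, "metrics.json")))
  expect_true(file.exists(file.path(out, "bf_map.nii.gz")))
  met <- jsonlite::read_json(file.path(out, "metrics.json"))
  expect_true(is.numeric(met$fd))
  # invalid inlet pressure: exit 2 with a message naming the field
  expect_message(
    st <- coroflow_cli(c("sweep", "--pressures", "10", "--out-dir", out)),
    "inlet_pressure")
  expect_equal(st, 2L)
  expect_message(st2 <- coroflow_cli("frobnicate"), "unknown subcommand")
  expect_equal(st2, 2L)
  expect_equal(suppressMessages(coroflow_cli(character(0))), 2L)
})
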