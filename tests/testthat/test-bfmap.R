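empty_grid <- function(d = c(4, 4, 4)) {
  voxel_grid(array(0, d), origin = c(0, 0, 0), spacing = c(1, 1, 1))
}

test_that("voxelization deposits, conserves and averages", {
  g <- empty_grid()
  # one deposit of q lands in exactly one voxel
  m1 <- voxelize(list(list(idx = 7L, flow = 5)), g)
  expect_equal(sum(m1$values > 0), 1L)
  expect_equal(m1$values[7], 5)
  # mean over instances: disjoint single-voxel deposits of q give q/2 each
  m2 <- voxelize(list(list(idx = 7L, flow = 5), list(idx = 9L, flow = 5)), g)
  expect_equal(m2$values[7], 2.5)
  expect_equal(m2$values[9], 2.5)
  # conservation: total voxel flow = mean over instances of total outflow
  dep <- list(list(idx = c(1L, 5L), flow = c(2, 3)),
              list(idx = 4L, flow = 7))
  m3 <- voxelize(dep, g)
  expect_equal(sum(m3$values), mean(c(5, 7)))
  expect_error(voxelize(list(), g), "empty")
})

test_that("instance deposits land in the voxel holding each terminal", {
  tab <- test_table()
  anat <- ventricle_anatomy()
  inst <- generate_instance(tab, anat, seed = 31)
  grid <- tissue_grid(anat)
  dep <- bf_deposits(inst, grid)
  tot <- inst$rca$flow$total_inflow + inst$lad$flow$total_inflow
  expect_equal(sum(dep$flow), tot, tolerance = 1e-9)
  m <- voxelize(list(dep), grid)
  expect_equal(sum(m$values), tot, tolerance = 1e-9)
  # mask keeps every voxel that received flow
  expect_true(all(m$mask[dep$idx]))
})

test_that("histograms bin masked values with exact counts", {
  g <- empty_grid(c(3, 3, 1))
  g$values[] <- 2
  h <- bf_histogram(g, 10)
  expect_equal(sum(h$counts), 9L)
  expect_equal(h$sd, 0)
  expect_equal(max(h$counts), 9L)   # constant values occupy a single bin
  # two-delta mixture: exact counts in the extreme bins
  g$values[] <- c(rep(1, 4), rep(9, 5))
  h2 <- bf_histogram(g, 4)
  expect_equal(h2$counts[1], 4L)
  expect_equal(h2$counts[4], 5L)
  expect_equal(sum(h2$counts), 9L)
  expect_equal(h2$mean, mean(g$values))
  expect_error(bf_histogram(g, 0), "n_bins")
})

test_that("relative-flow PDF has unit mean and the closed-form dispersions", {
  g <- empty_grid(c(4, 4, 2))
  g$values[] <- 3.5
  p <- relative_flow_pdf(g)
  expect_equal(p$mean, 1, tolerance = 1e-12)
  expect_equal(p$rd, 0)
  expect_true(all(p$d == 1))
  # half the voxels at 2a, half at 0: d in {2, 0}, RD = 1
  g$values[] <- rep(c(2, 0), each = 16)
  p2 <- relative_flow_pdf(g)
  expect_equal(sort(unique(p2$d)), c(0, 2))
  expect_equal(p2$rd, 1)
  # arbitrary positive field: mean exactly 1, density integrates to 1
  set.seed(8); g$values[] <- rexp(32)
  p3 <- relative_flow_pdf(g)
  expect_equal(p3$mean, 1, tolerance = 1e-9)
  expect_equal(sum(p3$density * diff(p3$breaks)), 1, tolerance = 1e-9)
  g$values[] <- 0
  expect_error(relative_flow_pdf(g), "zero")
})

test_that("coarsening sums blocks, tracks masses, conserves flow", {
  g <- empty_grid(c(4, 4, 4))
  set.seed(5); g$values[] <- runif(64)
  expect_equal(coarsen(g, c(1, 1, 1))$values, g$values)
  c2 <- coarsen(g, c(1, 1, 2))
  expect_equal(dim(c2$values), c(4L, 4L, 2L))
  expect_equal(sum(c2$values), sum(g$values), tolerance = 1e-12)
  expect_true(all(c2$mass == 2))
  expect_equal(c2$values[1, 1, 1], g$values[1, 1, 1] + g$values[1, 1, 2])
  # uniform field: values double, RD stays zero
  g$values[] <- 1
  cu <- coarsen(g, c(1, 1, 2))
  expect_true(all(cu$values == 2))
  expect_equal(relative_dispersion(cu), 0)
  # non-divisible extents truncate (and report) trailing voxels
  g3 <- empty_grid(c(5, 4, 4))
  expect_message(c3 <- coarsen(g3, c(2, 1, 1)), "truncated")
  expect_equal(dim(c3$values), c(2L, 4L, 4L))
})

test_that("fractal dimension inverts the RD scaling relation", {
  expect_equal(fractal_dimension(0.4, 0.4, 2), 1)
  expect_equal(fractal_dimension(0.30, 0.27, 2), 1 - log(0.9) / log(2))
  expect_equal(fractal_dimension(0.30, 0.27, 2), 1.152, tolerance = 1e-3)
  # forward-inverse round trip exact to 1e-12
  for (D in c(1.0, 1.14, 1.5)) {
    for (ratio in c(2, 8)) {
      rd_low <- 0.37 * ratio^(1 - D)
      expect_equal(fractal_dimension(0.37, rd_low, ratio), D, tolerance = 1e-12)
    }
  }
  expect_error(fractal_dimension(0, 1, 2), "rd_high")
  expect_error(fractal_dimension(1, 1, 1), "mass_ratio")
})

test_that("the convergence fit recovers exponential-decay parameters", {
  sizes <- c(10, 25, 50, 100, 200, 400)
  y <- 1.14 + 0.3 * exp(-sizes / 60)
  fit <- fd_convergence_fit(sizes, y)
  expect_equal(fit$A, 1.14, tolerance = 1e-6)
  expect_equal(fit$B, 0.3, tolerance = 1e-5)
  expect_equal(fit$tau, 60, tolerance = 1e-3)
  # constant series: asymptote is the constant, amplitude ~ 0
  fitc <- fd_convergence_fit(sizes, rep(1.2, 6))
  expect_equal(fitc$A, 1.2, tolerance = 1e-9)
  expect_equal(fitc$B, 0, tolerance = 1e-8)
  # monotone-decreasing data: asymptote cannot exceed the minimum by much
  yd <- 1.1 + 1 / sizes
  fitd <- fd_convergence_fit(sizes, yd)
  expect_lte(fitd$A, min(yd) + 0.05)
  expect_error(fd_convergence_fit(c(1, 2, 3), c(1, 2, 3)), "sizes")
})

test_that("transmural layering partitions the ventricle totals", {
  anat <- shell_anatomy(a = 10, b = 16)
  grid <- tissue_grid(anat, spacing = 1)
  dm <- endocardial_distance_map(anat, grid)
  # all flow in one voxel at distance ~1.5 -> everything in the sub-endo layer
  idx <- which(grid$mask & dm$distance >= 1.4 & dm$distance <= 1.6)[1]
  grid$values[idx] <- 42
  tp <- transmural_profile(grid, dm)
  expect_equal(tp$LV$flow[tp$LV$layer == 1], 42)
  expect_equal(sum(tp$LV$flow), 42)
  # uniform unit field: layer totals equal layer voxel counts, which track
  # the analytic spherical shell volumes within voxelization error
  grid$values[] <- as.numeric(grid$mask)
  tp2 <- transmural_profile(grid, dm)
  expect_equal(sum(tp2$LV$flow), sum(grid$mask))
  shell_vol <- function(k) 4 / 3 * pi * ((10 + k + 1)^3 - (10 + k)^3)
  for (k in 0:4) {
    expect_equal(tp2$LV$flow[tp2$LV$layer == k], shell_vol(k), tolerance = 0.08)
  }
})

test_that("modality counting finds well-separated modes once", {
  set.seed(2)
  h1 <- hist(rnorm(20000), breaks = 60, plot = FALSE)
  expect_equal(modality_count(h1$counts), 1L)
  h2 <- hist(c(rnorm(10000, -4), rnorm(10000, 4)), breaks = 80, plot = FALSE)
  expect_equal(modality_count(h2$counts), 2L)
  # uniform histogram: the plateau counts once
  expect_equal(modality_count(rep(7, 50)), 1L)
})

test_that("NIfTI voxel maps round-trip values and spacing", {
  g <- empty_grid(c(6, 5, 4))
  set.seed(11); g$values[] <- round(runif(120) * 500)
  g$spacing <- c(0.5, 0.5, 5)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_bf_map(g, path)
  back <- load_external_bf_map(path)
  expect_equal(dim(back$values), dim(g$values))
  expect_equal(as.numeric(back$values), as.numeric(g$values))
  expect_equal(back$spacing, g$spacing)
  expect_true(all(back$mask))
  # thresholding: a voxel above 600 leaves the mask
  g$values[3, 3, 2] <- 700
  write_bf_map(g, path)
  b2 <- load_external_bf_map(path, threshold_range = c(0, 600))
  expect_false(b2$mask[3, 3, 2])
  expect_equal(sum(!b2$mask), 1L)
})
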