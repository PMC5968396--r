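test_that("branching angles follow the law-of-cosines construction", {
  # symmetric daughters -> equal angles
  th <- branching_angles(1, 1, 0.5, 0.8, 0.5, 0.8)
  expect_equal(th[["theta_L"]], th[["theta_R"]])
  # frozen case: Qp=1, rp=1, QL=QR=0.5, rL=rR=2^(-1/3)
  # oracle: |u_d| = 0.5 * 2^(2/3); cos = |u_p| / (2 |u_d|)
  th <- branching_angles(1, 1, 0.5, 2^(-1/3), 0.5, 2^(-1/3))
  expect_equal(th[["theta_L"]], acos(1 / (2 * 0.5 * 2^(2/3))))
  expect_equal(th[["theta_L"]], 0.889, tolerance = 0.001)
  # straight-continuation limit: one daughter vanishes
  th0 <- branching_angles(1, 1, 1, 1, 1e-12, 0.5)
  expect_equal(th0[["theta_L"]], 0, tolerance = 1e-6)
  # the as-printed convention puts the vanishing branch at 90 degrees instead
  thp <- branching_angles(1, 1, 1, 1, 1e-12, 0.5, convention = "printed")
  expect_equal(thp[["theta_L"]], pi / 2, tolerance = 1e-6)
  expect_error(branching_angles(0, 1, 1, 1, 1, 1), "Qp")
})

test_that("self-avoidance vector weights and filters contributors", {
  xc <- c(0, 0, 0); Ls <- 2
  # one contributor at distance Ls: weight 1/(1+1) = 0.5, direction x_i -> x_c
  v <- self_avoidance_vector(xc, rbind(c(-Ls, 0, 0)), radii = 1, L_s = Ls)
  expect_equal(v, c(0.5, 0, 0))
  # distant contributor decays toward zero
  v_far <- self_avoidance_vector(xc, rbind(c(-1e5, 0, 0)), radii = 1, L_s = Ls)
  expect_lt(sqrt(sum(v_far^2)), 1e-9)
  # symmetric contributors cancel
  v_sym <- self_avoidance_vector(xc, rbind(c(-3, 0, 0), c(3, 0, 0)),
                                 radii = c(1, 1), L_s = Ls)
  expect_equal(v_sym, c(0, 0, 0))
  # contributors smaller than both daughters are excluded
  v_small <- self_avoidance_vector(xc, rbind(c(-Ls, 0, 0)), radii = 0.05,
                                   L_s = Ls, r_min = 0.2)
  expect_equal(v_small, c(0, 0, 0))
  # coincident node is skipped rather than dividing by zero
  v0 <- self_avoidance_vector(xc, rbind(xc), radii = 1, L_s = Ls)
  expect_equal(v0, c(0, 0, 0))
})

test_that("boundary avoidance decays as exp(-d/2L)", {
  half <- anatomy(walls = list(w = plane_wall(c(0, 0, 0), c(0, 0, 1))),
                  regions = list(t = c(w = 1L)))
  L <- 3
  expect_equal(boundary_avoidance_vector(c(0, 0, 2 * L), half, L),
               c(0, 0, exp(-1)))
  expect_equal(boundary_avoidance_vector(c(5, 5, 1e-15), half, L)[3], 1,
               tolerance = 1e-6)
  expect_lt(boundary_avoidance_vector(c(0, 0, 50 * L), half, L)[3], 1e-10)
})

test_that("combined direction mixes normalized inputs", {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  expect_equal(combined_direction(2 * e1, 5 * e1), e1)
  v <- combined_direction(e1, e2)
  expect_equal(v, c(0.5, 0.5, 0))
  expect_equal(sqrt(sum(v^2)), sqrt(2) / 2)
  expect_equal(combined_direction(e1, c(0, 0, 0)), 0.5 * e1)
  expect_equal(combined_direction(c(0, 0, 0), c(0, 0, 0), s_p = e2), e2)
  expect_error(combined_direction(c(0, 0, 0), c(0, 0, 0)), "parent")
})

test_that("branching plane normal is the normalized double cross product", {
  nb <- branching_plane_normal(c(1, 0, 0), c(0, 1, 0))
  expect_equal(nb, c(-1, 0, 0))
  for (s in 1:5) {
    set.seed(s)
    sp <- rnorm(3); vd <- rnorm(3)
    nb <- branching_plane_normal(sp, vd)
    expect_equal(sum(nb * vd), 0, tolerance = 1e-12)
    expect_equal(sqrt(sum(nb^2)), 1, tolerance = 1e-12)
  }
  # parallel inputs fall back deterministically to a unit vector
  nb <- branching_plane_normal(c(0, 0, 1), c(0, 0, 2))
  expect_equal(sqrt(sum(nb^2)), 1, tolerance = 1e-12)
  expect_equal(sum(nb * c(0, 0, 1)), 0, tolerance = 1e-12)
})

test_that("axis-angle rotation is orthonormal and composes angles", {
  set.seed(3)
  for (k in 1:5) {
    v <- rnorm(3); ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 0, pi)
    vr <- rotate_about_axis(v, ax, th)
    expect_equal(sqrt(sum(vr^2)), sqrt(sum(v^2)), tolerance = 1e-12)
  }
  # children rotated +thL / -thR about one axis subtend thL + thR
  vd <- c(0, 0, 1); nb <- c(1, 0, 0)
  ch <- assign_child_positions(c(0, 0, 0), vd, nb, 0.5, 0.7, 2, 3)
  ang <- acos(sum(ch$v_L * ch$v_R))
  expect_equal(ang, 1.2, tolerance = 1e-12)
  expect_equal(sqrt(sum((ch$x_L)^2)), 2, tolerance = 1e-12)
  expect_equal(sqrt(sum((ch$x_R)^2)), 3, tolerance = 1e-12)
  # zero angles: both children along v_d
  ch0 <- assign_child_positions(c(1, 1, 1), vd, nb, 0, 0, 2, 3)
  expect_equal(ch0$x_L, c(1, 1, 3))
  expect_equal(ch0$x_R, c(1, 1, 4))
})

test_that("repair walks violating points back into tissue", {
  anat <- slab_anatomy(thick = 4)
  prm <- avoidance_params()
  # already inside: unchanged, zero iterations
  r0 <- repair_position(c(0, 0, 2), anat, L = 1, prm)
  expect_true(r0$success)
  expect_equal(r0$iterations, 0L)
  expect_equal(r0$position, c(0, 0, 2))
  # one step outside: re-enters within a few iterations
  r1 <- repair_position(c(0, 0, -0.04), anat, L = 1, prm)
  expect_true(r1$success)
  expect_lt(r1$iterations, 10L)
  expect_true(inside_tissue(r1$position, anat))
  # far beyond the 200 * L/20 = 10 L reach: failure status, no error
  sph <- sphere_anatomy(10)
  r2 <- repair_position(c(30, 0, 0), sph, L = 1, prm)
  expect_false(r2$success)
})

test_that("placement engines agree and satisfy the geometric contracts", {
  tab <- test_table()
  anat <- ventricle_anatomy()
  tr1 <- assemble_tree("RCA", tab, seed = 3)
  tr2 <- assemble_tree("RCA", tab, seed = 3)
  g_cpp <- generate_geometry(tr1, anat, tab, engine = "cpp")
  g_r <- generate_geometry(tr2, anat, tab, engine = "r")
  expect_equal(nrow(g_cpp$seg), nrow(g_r$seg))
  expect_lt(max(abs(g_cpp$pos - g_r$pos)), 1e-6)
  # determinism: rerun is identical
  g_rep <- generate_geometry(assemble_tree("RCA", tab, seed = 3), anat, tab)
  expect_identical(g_cpp$pos, g_rep$pos)
  # every retained node lies in (or on) tissue
  expect_true(all(inside_tissue(g_cpp$pos, anat)))
  # unrepaired, non-trunk segments keep their sampled length exactly
  free <- which(!g_cpp$repaired & !g_cpp$preplaced & g_cpp$seg$parent > 0L)
  dd <- sqrt(rowSums((g_cpp$pos[free, ] -
                        g_cpp$pos[g_cpp$seg$parent[free], ])^2))
  expect_lt(max(abs(dd - g_cpp$seg$length[free])), 1e-6)
  # regression guard: under the default fixture few terminals are pruned
  expect_lt(attr(g_cpp, "pruned_terminal_fraction"), 0.2)
  # re-solved flows satisfy conservation on the placed tree
  sol <- g_cpp$flow
  expect_equal(total_terminal_outflow(sol, g_cpp), sol$total_inflow,
               tolerance = 1e-9)
})

test_that("trunks are laid inside tissue within the length bounds", {
  tab <- test_table()
  anat <- ventricle_anatomy()
  inst <- generate_instance(tab, anat, seed = 17)
  for (tr in inst[c("rca", "lad")]) {
    expect_true(all(inside_tissue(tr$pos[tr$trunk_ids, ], anat)))
  }
  # LCX trunk follows the left epicardium from its LAD attachment
  lad <- inst$lad
  expect_true(all(inside_tissue(lad$pos[lad$lcx_trunk, ], anat)))
})
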