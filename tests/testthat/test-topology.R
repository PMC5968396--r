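test_that("segment resistance follows the Poiseuille law", {
  # mu = 3.6e-3 Pa.s, L = 10 mm, r = 1.53 mm -> ~1.67e7 Pa.s/m^3
  expect_equal(segment_resistance(10, 1.53, 3.6e-3),
               8 * 3.6e-3 * 0.01 / (pi * 1.53e-3^4))
  expect_equal(segment_resistance(10, 1.53, 3.6e-3) / 1e7, 1.67, tolerance = 0.01)
  expect_equal(segment_resistance(0, 1, 3.6e-3), 0)
  # r^-4 scaling: doubling the radius divides resistance by exactly 16
  expect_equal(segment_resistance(5, 2, 3.6e-3),
               segment_resistance(5, 1, 3.6e-3) / 16)
  expect_error(segment_resistance(5, 0, 3.6e-3), "radius")
  expect_error(segment_resistance(-1, 1, 3.6e-3), "length")
})

test_that("element sampling respects the segments-per-element law", {
  tab <- test_table()
  set.seed(7)
  e1 <- sample_element(8, tab)
  set.seed(7)
  e2 <- sample_element(8, tab)
  expect_identical(e1, e2)
  expect_true(all(e1$segment_lengths > 0))
  expect_equal(e1$radius, tab$order_stats$mean_radius[tab$order_stats$order == 8])
  # degenerate ratio 1 -> always exactly one segment
  t1 <- tab; t1$order_stats$segments_per_element[2] <- 1
  set.seed(1)
  expect_true(all(replicate(50, length(sample_element(7, t1)$segment_lengths)) == 1))
  # law of large numbers: mean count within 5% of the configured ratio
  set.seed(42)
  ks <- replicate(10000, length(sample_element(10, tab)$segment_lengths))
  expect_equal(mean(ks), 3.5, tolerance = 0.05)
  expect_error(sample_element(5, tab), "order")
})

test_that("a forced-cascade connectivity yields the closed-form binary tree", {
  tab <- cascade_morphometry()
  tree <- assemble_tree("RCA", tab, seed = 1)
  # depth 5 from SN 11 to SN 6: 2^5 = 32 terminals, 2^6 - 1 = 63 segments
  expect_equal(length(terminal_ids(tree)), 32L)
  expect_equal(nrow(tree$seg), 63L)
  expect_equal(sort(unique(tree$seg$order)), 6:11)
  validate_tree(tree)
  expect_equal(sum(tree$seg$order == 6), 32L)
})

test_that("assembled trees satisfy the structural invariants", {
  tab <- test_table()
  for (s in 1:4) {
    rca <- assemble_tree("RCA", tab, seed = s)
    lad <- assemble_tree("LAD", tab)
    expect_silent(validate_tree(rca))
    expect_silent(validate_tree(lad))
    # recomputed Strahler orders (leaves = 6) reproduce the labels exactly
    expect_identical(strahler_orders(rca), rca$seg$order)
    expect_identical(strahler_orders(lad), lad$seg$order)
    expect_equal(rca$seg$order[1], 11L)
    # trunk length bounds
    expect_gte(total_trunk_length(rca), 120); expect_lte(total_trunk_length(rca), 192)
    expect_gte(total_trunk_length(lad), 100); expect_lte(total_trunk_length(lad), 160)
    # LCX sub-tree: order 10, its own bounded trunk, attached on the LAD trunk
    expect_false(is.na(lad$lcx_root))
    expect_equal(lad$seg$order[lad$lcx_root], 10L)
    expect_true(lad$seg$parent[lad$lcx_root] %in% lad$trunk_ids)
    lcx_len <- sum(lad$seg$length[lad$lcx_trunk])
    expect_gte(lcx_len, 100); expect_lte(lcx_len, 160)
  }
})

test_that("identical seeds reproduce byte-identical topologies", {
  tab <- test_table()
  t1 <- assemble_tree("LAD", tab, seed = 99)
  t2 <- assemble_tree("LAD", tab, seed = 99)
  expect_identical(t1$seg, t2$seg)
  expect_identical(as_segment_table(t1), as_segment_table(t2))
  t3 <- assemble_tree("LAD", tab, seed = 100)
  expect_false(identical(t1$seg, t3$seg))
})

test_that("total trunk length is additive over the trunk chain", {
  tr <- manual_tree(parent = c(0), length = 150, radius = 1)
  expect_equal(total_trunk_length(tr), 150)
  tr3 <- manual_tree(parent = c(0, 1, 2), length = c(50, 60, 40), radius = 1)
  tr3$trunk_ids <- 1:3
  expect_equal(total_trunk_length(tr3), 150)
})

test_that("pruning removes exactly the distal sub-tree", {
  tab <- test_table()
  tree <- assemble_tree("RCA", tab, seed = 12)
  n0 <- nrow(tree$seg)
  term0 <- length(terminal_ids(tree))
  # pruning a terminal removes exactly that segment
  t1 <- prune_subtree(tree, terminal_ids(tree)[5])
  expect_equal(nrow(t1$seg), n0 - 1L)
  # pruning one daughter of a bifurcation leaves a serial continuation
  jn <- which(tabulate(tree$seg$parent[tree$seg$parent > 0], n0) == 2L)[10]
  kids <- which(tree$seg$parent == jn)
  # oracle: terminal count drops by the terminals under the pruned node
  sub <- coroflow:::descendant_ids(tree, kids[1])
  sub_term <- sum(sub %in% terminal_ids(tree))
  t2 <- prune_subtree(tree, kids[1])
  expect_equal(length(terminal_ids(t2)), term0 - sub_term)
  expect_equal(nrow(t2$seg), n0 - length(sub))
  # the junction now passes through: one child
  nch <- tabulate(t2$seg$parent[t2$seg$parent > 0], nrow(t2$seg))
  expect_true(any(nch == 1L))
  expect_error(prune_subtree(tree, which(tree$seg$parent == 0L)), "root")
})

test_that("edge-list export round-trips through CSV", {
  tab <- test_table()
  tree <- assemble_tree("RCA", tab, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tree_csv(tree, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(tree$seg))
  expect_equal(back$L_mm, tree$seg$length)
  expect_equal(back$order, tree$seg$order)
})
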