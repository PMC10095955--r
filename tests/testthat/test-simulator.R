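test_that("seeding builds the minimal three-celled apical packet", {
  set.seed(1)
  t3 <- seed_tissue(simulation_params(n_initial_cells = 3))
  expect_equal(nrow(t3$cells), 3)
  expect_equal(sum(t3$cells$cell_class == "AC_wedge"), 1)
  expect_equal(sum(t3$cells$cell_class == "trapezoid"), 2)
  expect_true(all(t3$cells$packet_member))
  expect_error(seed_tissue(simulation_params(n_initial_cells = 2)),
               "invalid-parameter")
})

test_that("a seeded tissue has one AC, tiles its domain and does not overlap", {
  set.seed(2)
  tis <- seed_tissue(simulation_params(n_initial_cells = 40))
  expect_equal(nrow(tis$cells), 40)
  expect_equal(sum(tis$cells$cell_class == "AC_wedge"), 1)
  areas <- vapply(tis$polygons, poly_area, numeric(1))
  expect_equal(sum(areas), poly_area(tis$domain), tolerance = 1e-6)
  # exhaustive pairwise intersection with the independent clipping oracle
  ids <- names(tis$polygons)
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      ov <- oracle_convex_intersection_area(tis$polygons[[i]],
                                            tis$polygons[[j]])
      expect_lt(ov / areas[i], 1e-6)
    }
  }
  # apex point sits on the AC boundary
  acp <- tis$polygons[[as.character(fernquant:::ac_id(tis))]]
  d <- min(sqrt((acp[, 1] - tis$apex_point[1])^2 +
                (acp[, 2] - tis$apex_point[2])^2))
  expect_lt(d, 1e-6)
})

test_that("anticlinal division halves a square cell", {
  tis <- toy_square_tissue()
  p <- simulation_params()
  res <- apply_division(tis, 1L, "anticlinal", p)
  a <- vapply(res$tissue$polygons[as.character(c(res$event$daughter1,
                                                 res$event$daughter2))],
              poly_area, numeric(1))
  expect_equal(unname(a), c(50, 50), tolerance = 1)
  expect_equal(sum(a), 100, tolerance = 1e-6)
})

test_that("oblique division gives the apex daughter the wedge fraction", {
  set.seed(3)
  p <- simulation_params(n_initial_cells = 3, wedge_fraction = 0.4,
                         mean_cell_area = 200 / 3)
  tis <- seed_tissue(p)   # AC + two trapezoids in a 200 um^2 domain
  acid <- fernquant:::ac_id(tis)
  ac_area <- poly_area(tis$polygons[[as.character(acid)]])
  res <- apply_division(tis, acid, "oblique", p)
  new_ac <- res$tissue$cells$cell_id[res$tissue$cells$cell_class == "AC_wedge"]
  a <- poly_area(res$tissue$polygons[[as.character(new_ac)]])
  expect_equal(a, 0.4 * ac_area, tolerance = 0.01 * ac_area)
  # sibling is a trapezoid packet member
  sib <- setdiff(c(res$event$daughter1, res$event$daughter2), new_ac)
  expect_equal(res$tissue$cells$cell_class[res$tissue$cells$cell_id == sib],
               "trapezoid")
  expect_true(res$tissue$cells$packet_member[res$tissue$cells$cell_id == sib])
})

test_that("oblique divisions are only legal on the AC and vice versa", {
  tis <- toy_square_tissue()
  p <- simulation_params()
  expect_error(apply_division(tis, 1L, "oblique", p), "orientation-violation")
  expect_error(apply_division(tis, 2L, "periclinal", p),
               "orientation-violation")
})

test_that("the packet grammar runs 2 -> 3 -> 5 cells", {
  set.seed(4)
  p <- simulation_params(n_initial_cells = 3)
  tis <- seed_tissue(p)
  # oblique in the AC: two daughters, a new smaller AC beside a trapezoid
  r1 <- apply_division(tis, fernquant:::ac_id(tis), "oblique", p)
  expect_equal(nrow(r1$event), 1)
  expect_equal(sum(r1$tissue$cells$cell_class == "AC_wedge"), 1)
  # periclinal in the fresh trapezoid: the two-celled packet becomes a
  # newly established three-celled packet around the new AC
  new_ac <- fernquant:::ac_id(r1$tissue)
  sib <- setdiff(c(r1$event$daughter1, r1$event$daughter2), new_ac)
  r2 <- apply_division(r1$tissue, sib, "periclinal", p)
  packet2 <- r2$tissue$cells$cell_id[r2$tissue$cells$packet_member]
  nbrs <- fernquant:::adjacency_neighbours(r2$tissue$adjacency, new_ac)
  core <- fernquant:::packet_core_ids(r2$tissue, 2L)
  expect_equal(length(core), 3)
  expect_true(new_ac %in% core)
})

test_that("a full 48-hr packet round yields five packet cells", {
  set.seed(5)
  p <- simulation_params(n_initial_cells = 3)
  tis <- seed_tissue(p)
  traps <- tis$cells$cell_id[tis$cells$cell_class == "trapezoid"]
  r1 <- apply_division(tis, fernquant:::ac_id(tis), "oblique", p)
  r2 <- apply_division(r1$tissue, traps[1], "periclinal", p)
  packet <- r2$tissue$cells$cell_id[r2$tissue$cells$packet_member]
  expect_equal(length(packet), 5)
  expect_equal(sum(r2$tissue$cells$cell_class == "AC_wedge"), 1)
})

test_that("a null 48-hr step leaves the tissue unchanged", {
  p <- simulation_params(seed = 6, n_initial_cells = 30, p_div_ac = 0,
                         p_div_centre = 0, p_div_outside = 0,
                         growth_centre = 1, growth_outside = 1,
                         growth_cv = 0)
  sim <- simulate_gametophyte(p)
  expect_equal(nrow(sim$t48$cells), nrow(sim$t0$cells))
  expect_true(all(sim$lineage$parent_id == sim$lineage$daughter_id))
  expect_equal(nrow(sim$events), 0)
  a0 <- vapply(sim$t0$polygons, poly_area, numeric(1))
  a48 <- vapply(sim$t48$polygons[names(a0)], poly_area, numeric(1))
  expect_equal(a48, a0, tolerance = 0.006)
})

test_that("division fractions converge to the generating probabilities", {
  hits <- 0L; tot <- 0L
  for (s in 1:10) {
    p <- simulation_params(seed = 100 + s, p_div_outside = 0.15)
    sim <- simulate_gametophyte(p)
    out <- sim$growth[sim$growth$region == "outside", ]
    hits <- hits + sum(out$divided)
    tot <- tot + nrow(out)
  }
  se <- sqrt(0.15 * 0.85 / tot)
  expect_lt(abs(hits / tot - 0.15), 3 * se)
})

test_that("division events conserve area within one percent", {
  sim <- cached_sim(seed = 7, n = 60)$sim
  g <- sim$growth
  ev <- sim$events
  for (k in seq_len(nrow(ev))) {
    ds <- c(ev$daughter1[k], ev$daughter2[k])
    a_d <- sum(vapply(sim$t48$polygons[as.character(ds)], poly_area,
                      numeric(1)))
    row <- g[g$cell_id == ev$parent_id[k], ]
    grown <- row$area0_um2 * row$realized_factor
    expect_lt(abs(a_d - grown) / row$area0_um2, 0.01)
  }
})

test_that("the AC persists through repeated rounds", {
  p <- simulation_params(seed = 8, n_initial_cells = 40)
  sim <- simulate_gametophyte(p, n_steps = 3)
  expect_equal(sum(sim$t48$cells$cell_class == "AC_wedge"), 1)
  validate_tissue(sim$t48)
})

test_that("lineages are well formed", {
  sim <- cached_sim(seed = 7, n = 60)$sim
  lin <- sim$lineage
  # every t48 cell has exactly one ancestor
  expect_false(any(duplicated(lin$daughter_id)))
  expect_setequal(lin$daughter_id, sim$t48$cells$cell_id)
  # ancestors have 1 or 2 daughters
  nd <- table(lin$parent_id)
  expect_true(all(nd %in% 1:2))
  expect_setequal(as.integer(names(nd)), sim$t0$cells$cell_id)
})

test_that("identical seeds reproduce identical tissues", {
  p <- simulation_params(seed = 9, n_initial_cells = 40)
  s1 <- simulate_gametophyte(p)
  s2 <- simulate_gametophyte(p)
  expect_identical(s1$t48$cells, s2$t48$cells)
  expect_identical(s1$t48$polygons, s2$t48$polygons)
  expect_identical(s1$lineage, s2$lineage)
})
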