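toy_adjacency <- function() {
  # packet {1,2,3}; neighbours 4..10; second ring 11, 12
  data.frame(
    id1 = c(1L, 1L, 2L, 2L, 3L, 3L, 1L, 4L, 5L),
    id2 = c(4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L))
}

test_that("the centre group is the packet plus one adjacency ring", {
  all_ids <- 1:20
  grp <- define_centre_group(all_ids, ac_id = 1L, adjacency = toy_adjacency(),
                             ring = 1L, packet_ids = c(1L, 2L, 3L))
  expect_setequal(grp$centre_ids_t0, 1:10)
  expect_equal(length(grp$centre_ids_t0), 10)
  expect_setequal(grp$outside_ids_t0, 11:20)
  grp0 <- define_centre_group(all_ids, 1L, toy_adjacency(), ring = 0L,
                              packet_ids = c(1L, 2L, 3L))
  expect_setequal(grp0$centre_ids_t0, 1:3)
  expect_error(define_centre_group(all_ids, ac_id = 99L, toy_adjacency()),
               "not a known cell id")
})

test_that("trichomes are excluded from both groups", {
  grp <- define_centre_group(1:20, 1L, toy_adjacency(), ring = 1L,
                             packet_ids = c(1L, 2L, 3L),
                             trichome_ids = c(10L, 15L))
  expect_false(10L %in% grp$centre_ids_t0)
  expect_false(15L %in% grp$outside_ids_t0)
  expect_setequal(grp$excluded_ids, c(10L, 15L))
})

test_that("group propagation follows the lineage exactly", {
  grp <- define_centre_group(1:6, 1L, toy_adjacency(), ring = 0L,
                             packet_ids = c(1L, 2L, 3L))
  ident <- data.frame(parent_id = 1:6, daughter_id = 1:6)
  g1 <- propagate_group(grp, ident)
  expect_setequal(g1$centre_ids_t48, g1$centre_ids_t0)
  # one centre cell divides: the t48 centre grows by one
  split <- rbind(ident[-2, ], data.frame(parent_id = 2L,
                                         daughter_id = c(20L, 21L)))
  g2 <- propagate_group(grp, split)
  expect_equal(length(g2$centre_ids_t48), length(g2$centre_ids_t0) + 1)
  expect_setequal(g2$centre_ids_t48, c(1L, 3L, 20L, 21L))
  # missing lineage is flagged and dropped
  expect_warning(propagate_group(grp, ident[-1, ]), "no lineage")
})

test_that("percentage divided is the exact ratio formula", {
  div <- stats::setNames(c(rep(TRUE, 4), rep(FALSE, 6)), 1:10)
  expect_equal(pct_divided(1:10, div), 40)
  expect_equal(pct_divided(5:10, div), 0)
  expect_warning(v <- pct_divided(integer(0), div), "empty group")
  expect_true(is.na(v))
})

test_that("relative total area follows the 48/0 formula", {
  grp <- structure(list(centre_ids_t0 = 1:2, outside_ids_t0 = 3:4,
                        centre_ids_t48 = c(10L, 11L, 12L),
                        outside_ids_t48 = 3:4),
                   class = "fq_group")
  meas0 <- data.frame(cell_id = 1:4, area_um2 = c(400, 600, 500, 500))
  meas48 <- data.frame(cell_id = c(10L, 11L, 12L, 3L, 4L),
                       area_um2 = c(700, 500, 370, 500, 500))
  expect_equal(relative_total_area(grp, meas0, meas48, "centre"), 157)
  expect_equal(relative_total_area(grp, meas0, meas48, "outside"), 100)
  meas0$area_um2[1:2] <- 0
  expect_error(relative_total_area(grp, meas0, meas48, "centre"),
               "zero total area")
})

test_that("per-cell relative growth sums daughters first", {
  lin <- data.frame(parent_id = c(1L, 2L, 2L), daughter_id = c(1L, 20L, 21L))
  meas0 <- data.frame(cell_id = 1:2, area_um2 = c(100, 100))
  meas48 <- data.frame(cell_id = c(1L, 20L, 21L), area_um2 = c(100, 60, 80))
  g <- relative_cell_growth(1:2, lin, meas0, meas48)
  expect_equal(unname(g[1]), 0)
  expect_equal(unname(g[2]), 0.4)
  expect_warning(g2 <- relative_cell_growth(3L, lin, meas0, meas48),
                 "no lineage")
  expect_true(is.na(g2[["3"]]))
})

test_that("relative growth matches the simulator ledger within 2%", {
  cs <- cached_sim(seed = 3, n = 60)
  sim <- cs$sim
  meas0 <- fernquant:::tissue_truth_table(sim$t0)
  meas48 <- fernquant:::tissue_truth_table(sim$t48)
  g <- relative_cell_growth(meas0$cell_id, sim$lineage, meas0, meas48)
  ledger <- sim$growth$realized_factor - 1
  expect_equal(unname(g[as.character(sim$growth$cell_id)]), ledger,
               tolerance = 0.02)
})

test_that("the Student t-test matches the closed-form pooled computation", {
  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  res <- student_t_two_tailed(x, y)
  # independent oracle: pooled-variance formula plus the t distribution
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  df <- length(x) + length(y) - 2
  p_hand <- 2 * pt(-abs(t_hand), df)
  expect_equal(res$t, t_hand)
  expect_equal(res$p, p_hand)
  expect_equal(res$df, df)
  # identical samples
  same <- student_t_two_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # swapping flips the sign of t, p unchanged
  swapped <- student_t_two_tailed(y, x)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  expect_error(student_t_two_tailed(1, c(1, 2)), "at least 2")
})

test_that("constant samples with equal means give t = 0, p = 1", {
  res <- student_t_two_tailed(c(2, 2, 2), c(2, 2, 2))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_warning(r2 <- student_t_two_tailed(c(2, 2, 2), c(3, 3, 3)),
                 "zero variance")
  expect_equal(r2$p, 0)
})

test_that("the value map palette is bit-exact", {
  pal <- value_palette(c(0, 0.5, 1, 2, -1))
  expect_equal(pal[1, ], c(r = 0, g = 0, b = 1))
  expect_equal(pal[3, ], c(r = 1, g = 0, b = 0))
  expect_equal(pal[4, ], c(r = 1, g = 0, b = 0))     # clipped above vmax
  expect_equal(pal[5, ], c(r = 0, g = 0, b = 1))     # clipped below vmin
  # midpoint from the documented formula
  expect_equal(unname(pal[2, ]), c(round(255 * 0.5) / 255, 0,
                                   round(255 * 0.5) / 255))
  mask <- matrix(0L, 5, 5); mask[2:3, 2:3] <- 1L
  img <- render_value_map(mask, c(`1` = 0), 0, 700)
  expect_equal(img[2, 2, ], c(0, 0, 1))
  img2 <- render_value_map(mask, c(`1` = 900), 0, 700)
  expect_equal(img2[2, 2, ], c(1, 0, 0))
  expect_error(render_value_map(mask, c(`1` = 1), 5, 5), "vmin")
  expect_warning(render_value_map(mask, c(`2` = 1), 0, 1), "grey")
})

test_that("group statistics are invariant to record order and relabelling", {
  div <- stats::setNames(c(TRUE, TRUE, FALSE, FALSE, FALSE), 1:5)
  expect_equal(pct_divided(c(5, 3, 1), div), pct_divided(c(1, 3, 5), div))
  grp <- structure(list(centre_ids_t0 = 1:2, outside_ids_t0 = 3:5,
                        centre_ids_t48 = 1:2, outside_ids_t48 = 3:5),
                   class = "fq_group")
  meas0 <- data.frame(cell_id = 1:5, area_um2 = c(10, 20, 30, 40, 50))
  expect_equal(relative_total_area(grp, meas0, meas0[5:1, ], "centre"), 100)
})

test_that("group totals agree when aggregated through per-cell growth", {
  cs <- cached_sim(seed = 3, n = 60)
  sim <- cs$sim
  meas0 <- fernquant:::tissue_truth_table(sim$t0)
  meas48 <- fernquant:::tissue_truth_table(sim$t48)
  centre <- sim$t0$cells$cell_id[sim$t0$cells$region == "centre"]
  grp <- structure(list(centre_ids_t0 = centre,
                        outside_ids_t0 = setdiff(meas0$cell_id, centre)),
                   class = "fq_group")
  grp <- propagate_group(grp, sim$lineage)
  direct <- relative_total_area(grp, meas0, meas48, "centre")
  g <- relative_cell_growth(centre, sim$lineage, meas0, meas48)
  a0 <- stats::setNames(meas0$area_um2, meas0$cell_id)[as.character(centre)]
  via_growth <- 100 * sum(a0 * (1 + g)) / sum(a0)
  expect_equal(direct, via_growth, tolerance = 1e-9)
})
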