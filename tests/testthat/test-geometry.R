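test_that("polygon area and centroid match hand computations", {
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  expect_equal(poly_area(sq), 4)
  expect_equal(poly_centroid(sq), c(1, 1))
  tri <- cbind(c(0, 3, 0), c(0, 0, 4))
  expect_equal(poly_area(tri), 6)
  circ <- fernquant:::circle_polygon(c(0, 0), 10, 256)
  expect_equal(poly_area(circ), pi * 100, tolerance = 1e-3)
})

test_that("area-calibrated chord splits honour the requested fraction", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  for (frac in c(0.5, 0.3, 0.62)) {
    sp <- split_polygon(sq, c(0, 1), frac, ref_point = c(0, 5))
    expect_equal(poly_area(sp$ref_side), 100 * frac, tolerance = 1e-6)
    expect_equal(poly_area(sp$ref_side) + poly_area(sp$other), 100,
                 tolerance = 1e-6)
    # ref-side daughter contains the reference x-range
    expect_lt(min(sp$ref_side[, 1]), 1e-9)
  }
  # oblique direction still conserves area
  sp <- split_polygon(sq, c(1, 1), 0.4, ref_point = c(0, 10))
  expect_equal(poly_area(sp$ref_side), 40, tolerance = 1e-6)
})

test_that("point-in-polygon agrees with geometry", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_true(point_in_polygon(c(5, 5), sq))
  expect_false(point_in_polygon(c(15, 5), sq))
  expect_false(point_in_polygon(c(-1, -1), sq))
})

test_that("shared-edge adjacency finds touching cells only", {
  # 2x2 block of 10x10 squares plus one far square
  mk <- function(x0, y0) cbind(c(x0, x0 + 10, x0 + 10, x0),
                               c(y0, y0, y0 + 10, y0 + 10))
  polys <- list(`1` = mk(0, 0), `2` = mk(10, 0), `3` = mk(0, 10),
                `4` = mk(10, 10), `5` = mk(100, 100))
  adj <- polygon_adjacency(polys)
  pairs <- paste(adj$id1, adj$id2)
  expect_setequal(pairs, c("1 2", "1 3", "2 4", "3 4"))
  expect_equal(adj$shared_um[adj$id1 == 1 & adj$id2 == 2], 10)
  # ring helper
  expect_setequal(fernquant:::adjacency_ring(adj, 1L, 1L), c(1L, 2L, 3L))
  expect_setequal(fernquant:::adjacency_ring(adj, 1L, 2L), c(1L, 2L, 3L, 4L))
})
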