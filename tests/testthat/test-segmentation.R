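test_that("Gaussian pre-smoothing behaves like a smoothing kernel", {
  img <- matrix(runif(400), 20, 20)
  expect_identical(preprocess_smooth(img, 0), img)
  const <- matrix(0.4, 30, 30)
  expect_equal(preprocess_smooth(const, 2), const, tolerance = 1e-6)
  impulse <- matrix(0, 41, 41); impulse[21, 21] <- 1
  sm <- preprocess_smooth(impulse, 2)
  expect_equal(sum(sm), 1, tolerance = 1e-3)
  expect_error(preprocess_smooth(array(0, c(3, 3, 3)), 1), "2D")
})

test_that("h-minima markers find one basin per cell on a clean render", {
  set.seed(21)
  p <- simulation_params(n_initial_cells = 3)
  tis <- seed_tissue(p)
  r <- render_image_pair(tis, tis, p,
                         noise = list(gaussian_sd = 0, poisson_scale = 0))
  sm <- preprocess_smooth(r$image0, 1)
  mask <- foreground_mask(sm)
  h <- 0.1 * diff(range(sm[mask]))
  mk <- extract_markers(sm, h, mask)
  expect_equal(max(mk), 3)
})

test_that("h-minima suppression respects the barrier height", {
  # two basins of depth 0.5 separated by a barrier of height 0.3
  f <- matrix(0.8, 30, 60)
  f[, 10:20] <- 0.3
  f[, 40:50] <- 0.3
  f[, 28:32] <- 0.6   # saddle between the basins
  mask <- matrix(TRUE, 30, 60)
  # flood-fill oracle: below the saddle the basins are two components
  below <- f < 0.55
  comp <- EBImage::bwlabel(below * 1)
  expect_equal(max(comp), 2)
  mk <- extract_markers(f, h = 0.15, mask = mask)
  expect_equal(max(mk), 2)
  # h above the basin depth suppresses everything except the global floor
  mk2 <- extract_markers(f, h = 0.45, mask = mask)
  expect_lte(max(mk2), 2)
  expect_warning(extract_markers(f, h = 0.6, mask = mask), "dynamic range")
})

test_that("degenerate images produce warnings, not crashes", {
  const <- matrix(0.5, 20, 20)
  expect_warning(fg <- foreground_mask(const), "degenerate")
  expect_warning(mk <- extract_markers(const, 0.1, matrix(TRUE, 20, 20)),
                 "dynamic range")
  expect_equal(max(mk), 0)
  expect_error(watershed_segment(const, mk), "empty markers")
})

test_that("watershed with one marker floods the whole foreground", {
  set.seed(22)
  p <- simulation_params(n_initial_cells = 3)
  tis <- seed_tissue(p)
  r <- render_image_pair(tis, tis, p,
                         noise = list(gaussian_sd = 0, poisson_scale = 0))
  sm <- preprocess_smooth(r$image0, 1)
  mask <- foreground_mask(sm)
  mk <- matrix(0L, nrow(sm), ncol(sm))
  seedpx <- which(mask)[1000]
  mk[seedpx] <- 1L
  lm <- watershed_segment(sm, mk, pixel_size = p$pixel_size, mask = mask,
                          min_region = 1)
  expect_equal(sort(unique(lm$labels[mask])), 1L)
})

test_that("noise-free renders segment with per-cell IoU at least 0.95", {
  r <- cached_render(seed = 1, n = 60)
  seg <- segment_image(r$image0, r$pixel_size)
  iou <- label_iou(seg$labels, r$labels0)
  expect_gte(min(iou$iou), 0.95)
  expect_equal(length(seg$label_areas), length(unique(r$labels0[r$labels0 > 0])))
})

test_that("default-noise renders of a ~100-cell tissue reach mean IoU 0.90", {
  cs <- cached_sim(seed = 31, n = 100)
  set.seed(310)
  r <- render_image_pair(cs$sim$t0, cs$sim$t48, cs$params)
  seg <- segment_image(r$image48, cs$params$pixel_size)
  iou <- label_iou(seg$labels, r$labels48)
  expect_gte(mean(iou$iou), 0.90)
})

test_that("segmentation is deterministic", {
  r <- cached_render(seed = 1, n = 60)
  s1 <- segment_image(r$image0, r$pixel_size)
  s2 <- segment_image(r$image0, r$pixel_size)
  expect_identical(s1$labels, s2$labels)
})

test_that("cell measurements convert pixels to physical units", {
  lab <- matrix(0L, 20, 20)
  lab[2:11, 2:11] <- 1L   # 100 px
  lm <- segmentation_labelmap(lab, pixel_size = 0.5)
  meas <- measure_cells(lm)
  expect_equal(meas$area_um2, 25)
  expect_false(meas$is_trichome)
  meas2 <- measure_cells(lm, trichome_ids = 1L)
  expect_true(meas2$is_trichome)
  empty <- segmentation_labelmap(matrix(0L, 5, 5), 1)
  expect_warning(m0 <- measure_cells(empty), "no labels")
  expect_equal(nrow(m0), 0)
})

test_that("measured ground-truth label areas match polygon areas within 2%", {
  r <- cached_render(seed = 1, n = 60)
  sim <- cached_sim(seed = 1, n = 60)$sim
  lm <- segmentation_labelmap(r$labels0, r$pixel_size)
  meas <- measure_cells(lm)
  for (k in seq_len(nrow(meas))) {
    a_poly <- oracle_shoelace(sim$t0$polygons[[as.character(meas$cell_id[k])]])
    expect_lt(abs(meas$area_um2[k] - a_poly) / a_poly, 0.02)
  }
})

test_that("no pixel carries two labels and areas stay within the frame", {
  r <- cached_render(seed = 1, n = 60)
  seg <- segment_image(r$image0, r$pixel_size)
  expect_lte(sum(seg$label_areas) * r$pixel_size^2,
             prod(dim(seg$labels)) * r$pixel_size^2)
  expect_equal(sum(seg$label_areas), sum(seg$labels > 0))
})
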