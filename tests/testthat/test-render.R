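test_that("a noise-free 3-cell render has exactly three labels", {
  set.seed(11)
  p <- simulation_params(n_initial_cells = 3)
  sim_t0 <- seed_tissue(p)
  r <- render_image_pair(sim_t0, sim_t0, p,
                         noise = list(gaussian_sd = 0, poisson_scale = 0))
  expect_setequal(unique(as.vector(r$labels0[r$labels0 > 0])),
                  sim_t0$cells$cell_id)
  expect_equal(length(unique(r$labels0[r$labels0 > 0])), 3)
})

test_that("label masks agree with point-in-polygon assignment", {
  r <- cached_render(seed = 1, n = 60)
  sim <- cached_sim(seed = 1, n = 60)$sim
  lab <- r$labels0
  H <- nrow(lab)
  px <- r$pixel_size
  fg <- which(lab > 0)
  set.seed(99)
  pick <- sample(fg, 2000)
  ok <- 0L
  for (idx in pick) {
    row <- (idx - 1L) %% H + 1L
    col <- (idx - 1L) %/% H + 1L
    pt <- c(r$origin[1] + (col - 0.5) * px, r$origin[2] + (H - row + 0.5) * px)
    if (point_in_polygon(pt, sim$t0$polygons[[as.character(lab[idx])]])) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok / length(pick), 0.995)
})

test_that("mask pixel areas match polygon shoelace areas within 2%", {
  r <- cached_render(seed = 1, n = 60)
  sim <- cached_sim(seed = 1, n = 60)$sim
  px2 <- r$pixel_size^2
  counts <- table(r$labels0[r$labels0 > 0])
  for (id in names(sim$t0$polygons)) {
    a_poly <- oracle_shoelace(sim$t0$polygons[[id]])
    a_mask <- as.integer(counts[[id]]) * px2
    expect_lt(abs(a_mask - a_poly) / a_poly, 0.02)
  }
})

test_that("a too-small field of view raises a render error", {
  cs <- cached_sim(seed = 1, n = 60)
  expect_error(render_image_pair(cs$sim$t0, cs$sim$t48, cs$params,
                                 fov = c(30, 30)),
               "field of view")
})

test_that("TIFF round trips preserve labels and intensities", {
  r <- cached_render(seed = 1, n = 60)
  fl <- tempfile(fileext = ".tif")
  write_label_tiff(r$labels0, fl)
  expect_identical(read_label_tiff(fl), r$labels0)
  fi <- tempfile(fileext = ".tif")
  write_intensity_tiff(r$image0, fi)
  back <- read_intensity_tiff(fi)
  expect_lt(max(abs(back - r$image0)), 1 / 65535 + 1e-9)
})

test_that("simulation outputs are written in the documented layout", {
  cs <- cached_sim(seed = 1, n = 60)
  r <- cached_render(seed = 1, n = 60)
  dir <- tempfile()
  write_simulation_outputs(cs$sim, r, dir)
  expect_true(all(file.exists(file.path(dir,
    c("t0.tif", "t48.tif", "t0_labels.tif", "t48_labels.tif",
      "lineage_truth.csv", "tissue_t0.csv", "tissue_t48.csv",
      "params.yaml")))))
  tt <- read.csv(file.path(dir, "tissue_t0.csv"))
  expect_true(all(c("cell_id", "cell_class", "region", "area_um2",
                    "centroid_x", "centroid_y") %in% names(tt)))
  expect_equal(nrow(tt), nrow(cs$sim$t0$cells))
})
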