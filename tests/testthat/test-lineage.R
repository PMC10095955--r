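test_that("frame registration recovers constructed translations", {
  m <- matrix(0L, 60, 60)
  m[20:40, 25:45] <- 1L
  expect_equal(unname(register_frames(m, m)), c(0L, 0L))
  shifted <- fernquant:::shift_matrix(m, 5L, -3L)
  expect_equal(unname(register_frames(shifted, m)), c(-5L, 3L))
  expect_error(register_frames(m, matrix(0L, 60, 60)), "registration error")
})

test_that("weak registration on noise masks is flagged", {
  set.seed(41)
  a <- matrix(as.integer(runif(3600) < 0.05), 60, 60)
  b <- matrix(as.integer(runif(3600) < 0.05), 60, 60)
  expect_warning(register_frames(a, b), "weak")
})

test_that("identical masks give an identity lineage with no divisions", {
  r <- cached_render(seed = 1, n = 60)
  lin <- match_overlap(r$labels0, r$labels0)
  expect_true(all(lin$assignments$parent_id == lin$assignments$daughter_id))
  expect_length(lin$unmatched_t48, 0)
  div <- classify_divided(lin)
  expect_false(any(div))
})

test_that("a constructed split yields exactly two daughters", {
  m0 <- matrix(0L, 40, 40)
  m0[5:35, 5:35] <- 7L
  m48 <- matrix(0L, 40, 40)
  m48[5:35, 5:19] <- 21L
  m48[5:35, 20:35] <- 22L
  lin <- match_overlap(m0, m48)
  expect_setequal(lin$assignments$daughter_id, c(21L, 22L))
  expect_true(all(lin$assignments$parent_id == 7L))
  div <- classify_divided(lin)
  expect_true(div[["7"]])
})

test_that("division calls follow the two-daughter rule", {
  asg <- data.frame(parent_id = c(1L, 1L, 2L, 3L),
                    daughter_id = c(10L, 11L, 12L, 13L))
  div <- classify_divided(asg, parent_ids = c(1L, 2L, 3L, 4L))
  expect_true(div[["1"]])
  expect_false(div[["2"]])
  expect_false(div[["3"]])
  expect_true(is.na(div[["4"]]))
})

test_that("similarity-registered overlap tracking recovers the ground-truth lineage", {
  for (s in 1:4) {
    cs <- cached_sim(seed = s, n = 60)
    set.seed(s + 500)
    r <- render_image_pair(cs$sim$t0, cs$sim$t48, cs$params,
                           noise = list(gaussian_sd = 0, poisson_scale = 0))
    lin <- suppressWarnings(track_pair(r$labels0, r$labels48))
    expect_equal(lineage_accuracy(lin, cs$sim$lineage), 1)
  }
})

test_that("assignments are invariant to label renumbering", {
  cs <- cached_sim(seed = 2, n = 60)
  r <- cached_render(seed = 2, n = 60)
  perm <- sample(1000:2000, length(unique(r$labels48[r$labels48 > 0])))
  relab <- r$labels48
  ids <- sort(unique(r$labels48[r$labels48 > 0]))
  map <- stats::setNames(perm, ids)
  relab[relab > 0] <- map[as.character(relab[relab > 0])]
  lin1 <- suppressWarnings(track_pair(r$labels0, r$labels48))
  lin2 <- suppressWarnings(track_pair(r$labels0, relab))
  back <- stats::setNames(ids, perm)
  expect_equal(lin1$assignments$parent_id, lin2$assignments$parent_id)
  expect_equal(lin1$assignments$daughter_id,
               unname(back[as.character(lin2$assignments$daughter_id)]))
})

test_that("the division overlay uses the documented palette", {
  m0 <- matrix(0L, 10, 10)
  m0[2:5, 2:5] <- 1L
  m0[7:9, 7:9] <- 2L
  div <- c(`1` = TRUE, `2` = FALSE)
  img <- division_overlay(m0, div)
  expect_equal(img[3, 3, ], c(1, 0, 0))              # divided: red
  expect_equal(img[8, 8, ], c(0, 200 / 255, 0))      # not divided: green
  expect_equal(img[1, 1, ], c(0, 0, 0))              # background: black
  # pixel counts per colour equal label areas
  expect_equal(sum(img[, , 1] == 1 & img[, , 2] == 0), sum(m0 == 1))
  expect_equal(sum(img[, , 2] == 200 / 255), sum(m0 == 2))
  expect_warning(img2 <- division_overlay(m0, div[1]), "grey")
  expect_equal(img2[8, 8, ], c(0.5, 0.5, 0.5))
})
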