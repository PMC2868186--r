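test_that("detector-threshold segmentation recovers the phantom organ within 2%", {
  ph <- pancake_phantom(jitter = 0, vignette = 0, noise = 6)
  seg <- threshold_segment(ph$truth$ideal_volume, "red", 0.45,
                           min_component_voxels = 20)
  truth_n <- sum(ph$truth$label_volume == 1L)
  expect_lt(abs(sum(seg) - truth_n) / truth_n, 0.02)
  expect_error(threshold_segment(ph$truth$ideal_volume, "mauve", 0.5),
               "unknown detector")
})

test_that("all-background volumes segment to empty; min size 1 is a no-op filter", {
  v <- array(245, dim = c(2, 10, 10, 3))
  expect_false(any(threshold_segment(v, "red", 0.3)))
  set.seed(5)
  v2 <- array(sample(0:255, 2 * 10 * 10 * 3, replace = TRUE),
              dim = c(2, 10, 10, 3))
  raw <- step_otf(feature_detect(v2, "red"), 0.45) == 255
  dim(raw) <- dim(v2)[1:3]
  got <- threshold_segment(v2, "red", 0.45, min_component_voxels = 1,
                           exclude_background = FALSE)
  expect_equal(got, raw, ignore_attr = TRUE)
})

test_that("small components are removed at the requested connectivity", {
  m <- array(FALSE, dim = c(1, 9, 9))
  m[1, 2:4, 2:4] <- TRUE        # 9 voxels
  m[1, 8, 8] <- TRUE            # singleton
  m[1, 7, 7] <- TRUE            # diagonal neighbour of the singleton
  lab26 <- label_components(m, 26)
  expect_equal(attr(lab26, "n_components"), 2L)   # diagonals connect
  lab6 <- label_components(m, 6)
  expect_equal(attr(lab6, "n_components"), 3L)    # face-only: they split
})

test_that("label interpolation reproduces labelled sections and interpolates shape", {
  d10 <- make_disc(64, 10)
  d20 <- make_disc(64, 20)
  sparse <- list("1" = d10, "5" = d20)
  out <- interpolate_labels(sparse, 1:5)
  expect_identical(matrix(out[1, , ], 64, 64), d10)
  expect_identical(matrix(out[5, , ], 64, 64), d20)
  # halfway between r = 10 and r = 20 discs: disc of r = 15 +- 1 px
  mid <- matrix(out[3, , ], 64, 64)
  expect_true(all(mid[make_disc(64, 14)]))
  expect_false(any(mid[!make_disc(64, 16)]))
  # monotone under nesting: every interpolated section contains the smaller
  # disc and stays inside the larger
  for (z in 2:4) {
    m <- matrix(out[z, , ], 64, 64)
    expect_true(all(m[d10]))
    expect_true(all(d20[m]))
  }
})

test_that("constant, single-section and out-of-bracket interpolation copy masks", {
  d <- make_disc(32, 8)
  expect_identical(matrix(interpolate_labels(list("1" = d, "3" = d), 2)[1, , ],
                          32, 32), d)
  expect_identical(matrix(interpolate_labels(list("4" = d), 4)[1, , ], 32, 32),
                   d)
  out <- interpolate_labels(list("3" = d, "5" = make_disc(32, 10)), 1:7)
  expect_identical(matrix(out[1, , ], 32, 32), d)                 # before
  expect_identical(matrix(out[7, , ], 32, 32), make_disc(32, 10)) # after
  expect_error(interpolate_labels(list(), 1:3), "no labelled sections")
})

test_that("nearest-section interpolation copies the closer labelled mask", {
  d10 <- make_disc(32, 5); d20 <- make_disc(32, 12)
  out <- interpolate_labels(list("1" = d10, "10" = d20), 1:10,
                            method = "nearest")
  expect_identical(matrix(out[3, , ], 32, 32), d10)
  expect_identical(matrix(out[8, , ], 32, 32), d20)
})

test_that("blood-pool exclusion removes exactly the strongly red voxels", {
  set.seed(9)
  vol <- array(85L, dim = c(10, 10, 10, 3))     # achromatic: f_R = 1/3
  idx <- cbind(sample(1:10, 200, TRUE), sample(1:10, 200, TRUE),
               sample(1:10, 200, TRUE))
  idx <- unique(idx)[1:100, ]
  for (k in seq_len(nrow(idx))) vol[idx[k, 1], idx[k, 2], idx[k, 3], ] <-
      c(230L, 10L, 10L)                          # f_R = 0.92
  mask <- array(TRUE, dim = c(10, 10, 10))
  tissue <- exclude_blood_pool(mask, vol, 0.5)
  expect_equal(sum(tissue), 1000 - nrow(idx))
  # T_blood = 1: the strict threshold never fires, mask unchanged
  expect_equal(exclude_blood_pool(mask, vol, 1), mask)
  empty <- array(FALSE, dim = c(10, 10, 10))
  expect_false(any(exclude_blood_pool(empty, vol, 0.5)))
})

test_that("merging masks is first-wins with overlap accounting", {
  a <- array(FALSE, dim = c(1, 4, 4)); a[1, 1:2, ] <- TRUE
  b <- array(FALSE, dim = c(1, 4, 4)); b[1, 2:3, ] <- TRUE
  lv <- suppressMessages(merge_labels(list(a, b), c("top", "mid")))
  expect_equal(lv$overlap_voxels, 4L)
  expect_true(all(lv$labels[1, 2, ] == 1L))    # contested row goes to 'top'
  expect_true(all(lv$labels[1, 3, ] == 2L))
  expect_equal(unname(lv$name_table), c("top", "mid"))
  expect_error(merge_labels(list(a, b), c("x", "x")), "duplicate")
  empty <- merge_labels(list(), character(0))
  expect_equal(sum(empty$labels), 0)
  # disjoint masks: no overlap
  c2 <- array(FALSE, dim = c(1, 4, 4)); c2[1, 4, ] <- TRUE
  lv2 <- merge_labels(list(a, c2), c("top", "bottom"))
  expect_equal(lv2$overlap_voxels, 0L)
})

test_that("masks round-trip through per-section PNG files", {
  d <- make_disc(32, 9)
  dir <- withr::local_tempdir()
  write_masks(list("4" = d, "7" = !d), "ovary", dir)
  back <- read_masks("ovary", dir)
  expect_identical(names(back), c("4", "7"))
  expect_identical(back[["4"]], d)
  expect_identical(back[["7"]], !d)
})
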