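test_that("axis-aligned nearest reformat reproduces the stored section bit-exactly", {
  ph <- pancake_phantom(jitter = 0)
  v <- ph$truth$ideal_volume
  k <- 3L
  pl <- mpr_plane(origin_mm = c((k - 1) * 0.04, 0, 0),
                  normal_mm = c(1, 0, 0), u_mm = c(0, 1, 0),
                  extent_mm = c(143, 143) * 0.0156, spacing_mm = 0.0156)
  img <- extract_plane(v, pl, spacing_um = c(40, 15.6, 15.6),
                       interpolation = "nearest")
  expect_equal(as.numeric(img), as.numeric(v[k, , , ]))
  # idempotence: reformatting the reformat at k = 1 returns it again
  v1 <- array(img, dim = c(1, dim(img)))
  pl1 <- mpr_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                   c(143, 143) * 0.0156, 0.0156)
  img2 <- extract_plane(v1, pl1, spacing_um = c(40, 15.6, 15.6),
                        interpolation = "nearest")
  expect_equal(img2, img, ignore_attr = TRUE)
})

test_that("any plane through a constant volume is constant", {
  v <- array(77L, dim = c(10, 12, 14, 3))
  pl <- mpr_plane(c(0.05, 0.05, 0.02), c(1, 0, -1) / sqrt(2), c(0, 1, 0),
                  c(0.04, 0.04), 0.005)
  img <- extract_plane(v, pl, spacing_um = c(10, 10, 10),
                       interpolation = "trilinear")
  expect_true(all(img == 77))
})

test_that("a tilted plane through a linear ramp matches the closed form within one level", {
  nz <- 20; ny <- 20; nx <- 40
  ramp <- array(0L, dim = c(nz, ny, nx, 3))
  for (x in seq_len(nx)) {
    ramp[, , x, ] <- as.integer(round((x - 1) * 255 / (nx - 1)))
  }
  nrm <- c(1, 0, -1) / sqrt(2)
  u <- c(0, 1, 0)
  pl <- mpr_plane(c(0.05, 0, 0), nrm, u, extent_mm = c(0.1, 0.12),
                  spacing_mm = 0.01)
  img <- extract_plane(ramp, pl, spacing_um = c(10, 10, 10),
                       interpolation = "trilinear")
  vax <- c(nrm[2] * u[3] - nrm[3] * u[2], nrm[3] * u[1] - nrm[1] * u[3],
           nrm[1] * u[2] - nrm[2] * u[1])
  ij <- expand.grid(i = 0:(dim(img)[1] - 1), j = 0:(dim(img)[2] - 1))
  x_mm <- ij$i * 0.01 * u[3] + ij$j * 0.01 * vax[3]
  closed <- pmin(pmax(x_mm / 0.01 * 255 / (nx - 1), 0), 255)
  expect_lt(max(abs(img[cbind(ij$i + 1, ij$j + 1, 1)] - closed)), 1)
})

test_that("out-of-volume plane samples are background-filled with a warning", {
  v <- array(10L, dim = c(4, 4, 4, 3))
  pl <- mpr_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.2, 0.2), 0.04)
  expect_warning(img <- extract_plane(v, pl, spacing_um = c(10, 10, 10),
                                      background = c(245, 245, 245)),
                 "outside")
  expect_true(any(img == 245))
})

test_that("plane axes must be orthonormal", {
  expect_error(mpr_plane(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0), c(1, 1), 0.1),
               "unit")
  expect_error(mpr_plane(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 1), 0.1),
               "orthogonal")
})

test_that("linear distances work in physical units", {
  expect_equal(linear_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(linear_distance(c(0, 0, 0), c(0, 3, 4)), 5)
  p1 <- voxel_to_mm(c(1, 1, 1), c(40, 15.6, 15.6))
  p2 <- voxel_to_mm(c(11, 1, 1), c(40, 15.6, 15.6))
  expect_equal(linear_distance(p1, p2), 0.4)
  # symmetry and triangle inequality on random triples
  set.seed(12)
  for (k in 1:20) {
    a <- runif(3); b <- runif(3); c <- runif(3)
    expect_equal(linear_distance(a, b), linear_distance(b, a))
    expect_lte(linear_distance(a, c),
               linear_distance(a, b) + linear_distance(b, c) + 1e-12)
  }
})

test_that("cross-sectional areas are pixel counts times pixel area", {
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(cross_section_area(m, 0.0156^2), 100 * 0.0156^2)
  expect_equal(cross_section_area(matrix(FALSE, 5, 5), 1), 0)
  # rasterized disc of r = 0.5 mm at 15.6 um pixels vs pi r^2
  n <- 80
  px <- 0.0156
  ctr <- (n + 1) / 2
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, `+`)) * px
  disc <- d <= 0.5
  expect_lt(abs(cross_section_area(disc, px^2) - pi * 0.25) / (pi * 0.25),
            0.02)
})

test_that("bone ratios reproduce the published percentages and ratios", {
  bi <- bone_inputs()
  tg <- bone_ratios(bi$femur_tg, bi$tibia_tg, bi$body_tg)
  ctrl <- bone_ratios(bi$femur_ctrl, bi$tibia_ctrl, bi$body_ctrl)
  expect_equal(tg$femur_over_body_pct, 13)
  expect_equal(tg$tibia_over_body_pct, 20)
  expect_equal(ctrl$femur_over_body_pct, 15)
  expect_equal(ctrl$tibia_over_body_pct, 18)
  expect_equal(round(tg$tibia_femur_ratio, 1), 1.5)
  expect_equal(round(ctrl$tibia_femur_ratio, 1), 1.2)
  excess <- percent_difference(tg$tibia_femur_ratio, ctrl$tibia_femur_ratio,
                               "higher")
  expect_equal(as.numeric(excess), 24)
  expect_equal(attr(excess, "unrounded"), 23.6, tolerance = 0.05)
  expect_equal(bone_ratios(5, 5)$tibia_femur_ratio, 1)
  expect_error(bone_ratios(-1, 5), "positive")
  # cortical-area-to-length index
  br <- bone_ratios(11.46, 17.26, body_length_mm = NULL,
                    femur_cortical_mm2 = 1.35, tibia_cortical_mm2 = 0.74)
  expect_equal(br$femur_cortical_over_length_mm, 1.35 / 11.46)
  expect_equal(br$tibia_cortical_over_length_mm, 0.74 / 17.26)
})
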