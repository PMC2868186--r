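test_that("region volume is voxel count times voxel volume, additive over disjoint masks", {
  one <- array(FALSE, dim = c(3, 3, 3)); one[1, 1, 1] <- TRUE
  expect_equal(region_volume(one, c(40, 15.6, 15.6)), 15.6^2 * 40 / 1e9)
  expect_equal(region_volume(array(FALSE, dim = c(2, 2, 2)), c(1, 1, 1)), 0)
  a <- array(FALSE, dim = c(4, 4, 4)); a[1:2, , ] <- TRUE
  b <- array(FALSE, dim = c(4, 4, 4)); b[3, 2, 1] <- TRUE
  sp <- c(40, 15.6, 15.6)
  expect_equal(region_volume(a | b, sp),
               region_volume(a, sp) + region_volume(b, sp))
  expect_error(region_volume(array(2, dim = c(2, 2)), sp), "binary")
})

test_that("the phantom sphere volume is recovered within 2% from its label mask", {
  ph <- sphere_phantom(radius_mm = 1, noise = 0)
  v <- region_volume(ph$truth$label_volume == 1L, c(40, 15.6, 15.6))
  expect_lt(abs(v - 4 / 3 * pi) / (4 / 3 * pi), 0.02)
})

test_that("normalization reproduces the published organ table at printed precision", {
  tb <- table1_inputs()
  for (animal in c("tg", "ctrl")) {
    vols <- tb[[paste0("volumes_", animal)]]
    st <- normalize_stats(vols, tb[[paste0("weight_", animal)]])
    expect_equal(st$volume_per_weight, tb[[paste0("per_weight_", animal)]],
                 tolerance = 1e-3)
    expect_true(all(abs(st$volume_per_weight -
                          tb[[paste0("per_weight_", animal)]]) <= 1e-3))
    expect_true(all(abs(st$volume_per_brain -
                          tb[[paste0("per_brain_", animal)]]) <= 1e-3))
    expect_equal(st$volume_per_brain[st$organ == "brain"], 1)
  }
})

test_that("normalization scales and validates as expected", {
  st <- normalize_stats(c(brain = 100, heart = 50), weight_g = 10)
  st2 <- normalize_stats(c(brain = 100, heart = 150), weight_g = 10)
  expect_equal(st2$volume_per_weight[2], 3 * st$volume_per_weight[2])
  expect_equal(normalize_stats(c(brain = 100, x = 0), 5)$volume_per_weight[2],
               0)
  expect_error(normalize_stats(c(heart = 50), 10), "brain")
  expect_equal(normalize_stats(c(heart = 50), 10,
                               brain_volume_mm3 = 100)$volume_per_brain, 0.5)
  expect_error(normalize_stats(c(brain = 100), 0), "weight_g")
})

test_that("percent differences match the published comparisons at printed rounding", {
  thin <- percent_difference(84, 502, "thinner")
  expect_equal(as.numeric(thin), 83)
  expect_equal(attr(thin, "unrounded"), 83.266932, tolerance = 1e-6)
  high <- percent_difference(13.625, 9.706, "higher")
  expect_equal(as.numeric(high), 40)
  expect_equal(as.numeric(percent_difference(5, 5, "higher")), 0)
  # the two modes are complementary: thinner(a,b) = 100 (1 - a/b)
  expect_equal(attr(percent_difference(84, 502, "thinner"), "unrounded"),
               100 * (1 - 84 / 502))
  expect_error(percent_difference(1, 0, "higher"), "> 0")
})

test_that("fractional vascularization counts vessels over the enclosing region", {
  region <- array(TRUE, dim = c(10, 10, 10))
  vessels <- array(FALSE, dim = c(10, 10, 10)); vessels[1:5, 1:5, 1] <- TRUE
  expect_equal(fraction_vascularized(region, vessels), 2.5)
  none <- array(FALSE, dim = c(10, 10, 10))
  expect_equal(fraction_vascularized(region, none), 0)
  expect_equal(fraction_vascularized(none, vessels), 100)  # all-vessel region
  expect_error(fraction_vascularized(none, none), "empty")
})

test_that("layer thickness is run length times pixel size with oblique correction", {
  li <- matrix(0L, 60, 60)
  li[11:20, ] <- 1L; li[21:40, ] <- 2L; li[41:55, ] <- 3L
  prof <- layer_thickness(li, start = c(1, 30), direction = c(1, 0),
                          layers = c(epidermis = 1, dermis = 2,
                                     hypodermis = 3),
                          pixel_size_um = 15.6)
  expect_equal(prof$thickness_um, c(10, 20, 15) * 15.6)
  # 45-degree ray: sqrt(2) step correction over a 10 px band
  diag <- layer_thickness(li, c(11, 1), c(1, 1), c(epidermis = 1), 15.6)
  expect_equal(diag$thickness_um, 10 * sqrt(2) * 15.6)
  # single-layer image: full ray length
  uni <- matrix(1L, 20, 20)
  full <- layer_thickness(uni, c(1, 5), c(1, 0), c(only = 1), 10)
  expect_equal(full$pixels, 20L)
  expect_error(layer_thickness(li, c(1, 30), c(1, 0), c(fat = 9)),
               "not crossed")
})

test_that("the inconsistent published epidermis comparison is reportable under both denominators", {
  # thinner-than-transgenic: 14.5% of 407, 17.0% of 348; the 16% figure in
  # print matches neither exactly, so both are surfaced unrounded
  a <- percent_difference(348, 407, "thinner", digits = 1)
  b <- percent_difference(407, 348, "higher", digits = 1)
  expect_equal(as.numeric(a), 14.5)
  expect_equal(as.numeric(b), 17.0)
})
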