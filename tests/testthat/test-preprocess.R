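test_that("flat-field correction: uniform reference is identity, zero tile stays zero", {
  set.seed(1)
  tile <- array(sample(0:255, 20 * 20 * 3, replace = TRUE), dim = c(20, 20, 3))
  wr <- array(200, dim = c(20, 20, 3))
  expect_equal(flatfield_correct(tile, wr), tile, ignore_attr = TRUE)
  # idempotence under a uniform reference
  expect_equal(flatfield_correct(flatfield_correct(tile, wr), wr), tile,
               ignore_attr = TRUE)
  zt <- array(0, dim = c(20, 20, 3))
  expect_equal(flatfield_correct(zt, wr), zt, ignore_attr = TRUE)
  expect_error(flatfield_correct(tile, wr[1:10, , , drop = FALSE]),
               "same shape")
  wr0 <- wr; wr0[1, 1, 1] <- 0
  expect_warning(flatfield_correct(tile, wr0), "floor")
})

test_that("flat-field correction inverts the phantom's vignetting within one level", {
  ph <- pancake_phantom(jitter = 0, vignette = 0.1)
  th <- ph$truth$tile_shape
  sec <- array(ph$truth$ideal_volume[3, , , ], dim = c(144, 144, 3))
  for (t in ph$tiles[[3]]) {
    corr <- flatfield_correct(t$img, ph$white_ref)
    o <- t$origin
    ideal <- sec[o[1]:(o[1] + th[1] - 1), o[2]:(o[2] + th[2] - 1), ,
                 drop = FALSE]
    expect_lte(max(abs(corr - ideal)), 1)
  }
})

test_that("stitching a jitter-free noiseless phantom reproduces the ideal section exactly", {
  ph <- pancake_phantom(jitter = 0, vignette = 0, noise = 0)
  for (z in c(1L, 4L)) {
    st <- stitch_section(ph$tiles[[z]], ph$meta)
    expect_equal(dim(st), c(144L, 144L, 3L))
    expect_equal(as.numeric(st),
                 as.numeric(ph$truth$ideal_volume[z, , , ]))
  }
})

test_that("a 1 x 1 grid returns the single tile unchanged", {
  ph <- generate_phantom(phantom_spec(
    c(2, 50, 50),
    list(phantom_organ("a", c(0.02, 0.38, 0.38), c(0.02, 0.2, 0.2),
                       c(200, 40, 40))),
    tile_grid = c(1, 1), vignette_strength = 0, seed = 1))
  st <- stitch_section(ph$tiles[[1]], ph$meta)
  expect_equal(as.numeric(st), as.numeric(ph$tiles[[1]][[1]]$img))
})

test_that("refinement recovers injected integer tile jitters exactly on specimen-bearing sections", {
  # jitter is only identifiable where the overlap zones contain specimen
  # content; sections cutting pure embedding compound carry no signal
  ph <- pancake_phantom(jitter = 3, vignette = 0.1)
  for (z in pancake_informative_sections()) {
    tl <- lapply(ph$tiles[[z]], function(t) {
      t$img <- flatfield_correct(t$img, ph$white_ref)
      t
    })
    st <- stitch_section(tl, ph$meta, refine = TRUE)
    expect_identical(attr(st, "offsets"),
                     unname(ph$truth$tile_offsets[[z]]))
  }
})

test_that("missing tiles are reported by grid position", {
  ph <- pancake_phantom(jitter = 0)
  expect_error(stitch_section(ph$tiles[[1]][-2], ph$meta), "row 1, col 2")
})

test_that("stack alignment recovers injected per-section shifts exactly", {
  ph <- pancake_phantom(jitter = 0, vignette = 0, noise = 0)
  sec <- array(ph$truth$ideal_volume[3, , , ], dim = c(144, 144, 3))
  injected <- rbind(c(0, 0), c(2, -3), c(-1, 1), c(4, 0))
  secs <- list(sec)
  for (k in 2:4) {
    secs[[k]] <- shift_rgb(secs[[k - 1]], injected[k, 1], injected[k, 2])
  }
  al <- align_stack(secs)
  expect_equal(unname(al$shifts), injected, ignore_attr = TRUE)
  expect_false(any(al$flagged))
  # identical sections: all shifts zero
  al0 <- align_stack(list(sec, sec, sec))
  expect_true(all(al0$shifts == 0))
  # single section: unchanged
  al1 <- align_stack(list(sec))
  expect_equal(unname(al1$shifts), matrix(0L, 1, 2))
  expect_equal(as.numeric(al1$volume[1, , , ]), as.numeric(sec))
  expect_error(align_stack(list()), "nonempty")
})

test_that("alignment shifts of a reversed stack are the negated reversal", {
  ph <- pancake_phantom(jitter = 0, vignette = 0, noise = 0)
  sec <- array(ph$truth$ideal_volume[3, , , ], dim = c(144, 144, 3))
  secs <- list(sec, shift_rgb(sec, 2, -3), shift_rgb(sec, 5, 1))
  fwd <- align_stack(secs)$shifts
  rev_ <- align_stack(rev(secs))$shifts
  # pairwise displacements reverse and change sign
  expect_equal(unname(rev_[2:3, ]), unname(-fwd[3:2, ]))
})

test_that("implausibly large estimated shifts are flagged, not applied", {
  ph <- pancake_phantom(jitter = 0, vignette = 0, noise = 0)
  sec <- array(ph$truth$ideal_volume[3, , , ], dim = c(144, 144, 3))
  al <- align_stack(list(sec, shift_rgb(sec, 12, 0)), cap = 5)
  expect_true(al$flagged[2])
  expect_equal(unname(al$shifts[2, ]), c(0L, 0L))
})

test_that("stitch then align on a clean phantom reproduces the ideal volume bit-exactly", {
  ph <- pancake_phantom(jitter = 0, vignette = 0, noise = 0)
  secs <- lapply(seq_along(ph$tiles), function(z)
    stitch_section(ph$tiles[[z]], ph$meta))
  al <- align_stack(secs)
  expect_equal(as.numeric(al$volume), as.numeric(ph$truth$ideal_volume))
  expect_true(all(al$shifts == 0))
})

test_that("stitched stacks round-trip through the on-disk layout", {
  ph <- pancake_phantom(jitter = 0, vignette = 0, noise = 0)
  secs <- lapply(seq_along(ph$tiles), function(z)
    stitch_section(ph$tiles[[z]], ph$meta))
  al <- align_stack(secs)
  dir <- withr::local_tempdir()
  write_stitched(al, dir)
  back <- read_stitched(dir)
  expect_equal(back$volume, al$volume, ignore_attr = TRUE)
  expect_equal(unname(as.matrix(back$shifts)), unname(al$shifts))
})
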