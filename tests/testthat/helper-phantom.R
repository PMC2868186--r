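# Shared fixtures, built in code.

# centred disc mask on an n x n grid
make_disc <- function(n, r) {
  ctr <- (n + 1) / 2
  sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, `+`)) <= r
}

# translate an RGB image, filling with the embedding colour
shift_rgb <- function(img, dy, dx, bg = c(245, 245, 245)) {
  d <- dim(img)
  out <- array(0, dim = d)
  for (c in 1:3) out[, , c] <- bg[c]
  ys <- max(1, 1 + dy):min(d[1], d[1] + dy)
  xs <- max(1, 1 + dx):min(d[2], d[2] + dx)
  out[ys, xs, ] <- img[ys - dy, xs - dx, ]
  out
}

# small flat ("pancake") phantom: a red disc-like ellipsoid crossing every
# tile-overlap zone of the interior sections (2..7); the first and last
# sections cut outside the organ and show only embedding compound. Canvas
# dimensions are divisible by 4 so two pyramid levels halve exactly.
pancake_phantom <- function(seed = 7, jitter = 3, vignette = 0.1,
                            noise = 0) {
  spec <- phantom_spec(
    canvas_size = c(8, 144, 144),
    organs = list(phantom_organ("liver", c(0.14, 1.1, 1.1),
                                c(0.11, 0.85, 0.85), c(200, 40, 40),
                                rgb_noise_sd = noise)),
    voxel_spacing = c(40, 15.6, 15.6),
    tile_grid = c(2, 2), overlap_fraction = 0.2,
    vignette_strength = vignette, tile_jitter_px = jitter, seed = seed)
  generate_phantom(spec)
}

# sections of the pancake phantom whose tile-overlap zones contain specimen
# content (jitter is only recoverable where the images constrain it)
pancake_informative_sections <- function() 2:7

# sphere phantom at the instrument's native spacing; radius in mm
sphere_phantom <- function(radius_mm = 1, seed = 11, jitter = 0,
                           vignette = 0.1, noise = 6,
                           margin_mm = 0.35) {
  sp_um <- c(40, 15.6, 15.6)
  ext <- 2 * (radius_mm + margin_mm)
  dims <- ceiling(ext * 1000 / sp_um) + 1
  ctr <- (dims - 1) * sp_um / 2000
  spec <- phantom_spec(
    canvas_size = dims,
    organs = list(phantom_organ("sphere", ctr, rep(radius_mm, 3),
                                c(200, 40, 40), rgb_noise_sd = noise)),
    voxel_spacing = sp_um, tile_grid = c(2, 2), overlap_fraction = 0.2,
    vignette_strength = vignette, tile_jitter_px = jitter, seed = seed)
  generate_phantom(spec)
}

# printed morphometry inputs used across the quantification tests: organ
# volumes (mm^3), gross weights (g) and the published normalized ratios
table1_inputs <- function() {
  list(
    volumes_tg = c(brain = 579.65, heart = 351.52, kidney = 606.98,
                   spleen = 105.01, thymus = 32.11, pituitary = 2.71,
                   adrenal = 7.07, pericardial_fat = 17.82),
    volumes_ctrl = c(brain = 639.20, heart = 366.87, kidney = 541.59,
                     spleen = 125.98, thymus = 27.93, pituitary = 2.49,
                     adrenal = 6.84, pericardial_fat = 109.31),
    weight_tg = 25.8, weight_ctrl = 37.8,
    per_weight_tg = c(22.467, 13.625, 23.526, 4.070, 1.244, 0.105, 0.274,
                      0.690),
    per_weight_ctrl = c(16.910, 9.706, 14.328, 3.332, 0.739, 0.066, 0.181,
                        2.892),
    per_brain_tg = c(1.0, 0.606, 1.047, 0.181, 0.055, 0.005, 0.012, 0.031),
    per_brain_ctrl = c(1.0, 0.574, 0.847, 0.197, 0.044, 0.004, 0.011,
                       0.171))
}

# published bone measurements (mm)
bone_inputs <- function() {
  list(femur_tg = 11.46, tibia_tg = 17.26, body_tg = 87.6,
       femur_ctrl = 12.41, tibia_ctrl = 15.12, body_ctrl = 83.8)
}
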