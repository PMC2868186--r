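# Internal helpers shared across modules.

# Round half away from zero (commercial rounding). Used for all 8-bit
# quantization and for reported percentages, where R's round-half-to-even
# would disagree with values printed to a fixed precision.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Clip to the 8-bit range and quantize.
clip8 <- function(x) {
  pmin(pmax(round_half_up(x), 0), 255)
}

# Validate an RGB array: numeric, last dimension 3, 8-bit integral values.
# Returns the array with dims guaranteed; 2D images are (y, x, 3), volumes
# (z, y, x, 3).
check_rgb <- function(x, name = "volume") {
  if (!is.array(x) || !is.numeric(x)) {
    stop(name, " must be a numeric array with a trailing RGB channel dimension")
  }
  d <- dim(x)
  if (d[length(d)] != 3L) {
    stop(name, " must have a trailing channel dimension of length 3 (R, G, B)")
  }
  rng <- range(x)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255 || any(x != floor(x))) {
    stop(name, " must contain 8-bit values (integers in 0..255); ",
         "the colour-ratio formulas assume Imax = 255")
  }
  x
}

check_binary_mask <- function(x, name = "mask") {
  if (is.logical(x)) return(x)
  if (is.numeric(x) && all(x %in% c(0, 1))) {
    y <- x == 1
    dim(y) <- dim(x)
    return(y)
  }
  stop(name, " must be a logical (binary) array")
}

# Extract one channel of an RGB array as an array one dimension lower.
channel_of <- function(x, i) {
  d <- dim(x)
  nd <- length(d)
  idx <- c(list(x), rep(list(quote(expr = )), nd - 1L), list(i))
  out <- do.call(`[`, idx)
  dim(out) <- d[-nd]
  out
}

# ITU-R BT.601 luminance, used for registration.
luminance <- function(img) {
  0.299 * channel_of(img, 1L) + 0.587 * channel_of(img, 2L) +
    0.114 * channel_of(img, 3L)
}

# Replicate a scalar-per-voxel array across the 3 colour channels.
rep_channels <- function(x) {
  array(rep(as.vector(x), 3L), dim = c(dim(x), 3L))
}

# Promote a single 2D RGB image (y, x, 3) to a one-section volume
# (1, y, x, 3); volumes pass through.
as_volume <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(1L, d)
  } else if (length(d) != 4L) {
    stop("expected an RGB image (y, x, 3) or volume (z, y, x, 3)")
  }
  x
}
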