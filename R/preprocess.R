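#' Acquisition metadata
#'
#' Geometry and animal metadata of a tiled block-face acquisition. Defaults
#' match the target instrument: 1036 x 1360 px tiles in a 4 x 6 grid with at
#' least 15% overlap, 15.6 um in-plane pixels, 40 um sections.
#'
#' @param tile_grid tiles per section as (rows, cols).
#' @param overlap_fraction minimum fractional tile overlap, in `[0, 1)`.
#' @param pixel_size_um in-plane pixel size, um.
#' @param section_thickness_um section (z) thickness, um.
#' @param tile_shape_px tile shape (height, width) in px.
#' @param n_sections number of sections, or `NULL` if unknown.
#' @param animal list with `weight_g`, `body_length_mm`, `label`.
#' @return an object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(tile_grid = c(4L, 6L),
                             overlap_fraction = 0.15,
                             pixel_size_um = 15.6,
                             section_thickness_um = 40,
                             tile_shape_px = c(1036L, 1360L),
                             n_sections = NULL,
                             animal = list(weight_g = NA_real_,
                                           body_length_mm = NA_real_,
                                           label = NA_character_)) {
  if (pixel_size_um <= 0 || section_thickness_um <= 0) {
    stop("pixel_size_um and section_thickness_um must be positive")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)")
  }
  structure(list(tile_grid = as.integer(tile_grid),
                 overlap_fraction = overlap_fraction,
                 pixel_size_um = pixel_size_um,
                 section_thickness_um = section_thickness_um,
                 tile_shape_px = as.integer(tile_shape_px),
                 n_sections = if (is.null(n_sections)) NULL
                              else as.integer(n_sections),
                 animal = animal),
            class = "acquisition_meta")
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf("acquisition: %d x %d tiles of %d x %d px, overlap >= %g%%\n",
              x$tile_grid[1], x$tile_grid[2], x$tile_shape_px[1],
              x$tile_shape_px[2], 100 * x$overlap_fraction))
  cat(sprintf("voxel: %g x %g x %g um (dz, dy, dx)\n",
              x$section_thickness_um, x$pixel_size_um, x$pixel_size_um))
  if (!is.null(x$n_sections)) cat(sprintf("sections: %d\n", x$n_sections))
  invisible(x)
}

# Voxel spacing (dz, dy, dx) in um from acquisition metadata.
meta_spacing <- function(meta) {
  c(meta$section_thickness_um, meta$pixel_size_um, meta$pixel_size_um)
}

#' White-card flat-field correction
#'
#' Compensates the nonuniform illumination of a tile by dividing out the
#' white-card reference pattern, per channel:
#' `out = clip(round(tile * mean(white_c) / white), 0, 255)`.
#' Normalizing by the channel mean of the reference makes a spatially uniform
#' reference a no-op.
#'
#' @param tile 8-bit RGB tile image (y, x, 3).
#' @param white_ref white-card reference image, same shape as `tile`.
#' @param floor minimum admissible reference value; darker reference pixels
#'   are clamped up to it with a warning (default 1).
#' @return corrected 8-bit RGB tile.
#' @export
flatfield_correct <- function(tile, white_ref, floor = 1) {
  tile <- check_rgb(tile, "tile")
  white_ref <- check_rgb(white_ref, "white_ref")
  if (!identical(dim(tile), dim(white_ref))) {
    stop("tile and white_ref must have the same shape")
  }
  if (any(white_ref < floor)) {
    warning("white reference contains pixels below the floor (", floor,
            "); clamping")
    white_ref <- pmax(white_ref, floor)
    dim(white_ref) <- dim(tile)
  }
  out <- tile
  for (c in 1:3) {
    w <- channel_of(white_ref, c)
    out[, , c] <- channel_of(tile, c) * (mean(w) / w)
  }
  clip8(out)
}

# Match score between two equally shaped luminance patches: normalized
# cross-correlation where defined; for structureless (constant) patches an
# intensity-agreement score slightly below 1, so an exact structured match
# always wins and flat-on-flat ties resolve toward the smallest shift.
patch_score <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (sa > 0 && sb > 0) return(stats::cor(as.vector(a), as.vector(b)))
  1 - mean(abs(a - b)) / 255 - 1e-9
}

#' Composite the tiles of one section into a stitched image
#'
#' Tiles are placed at their nominal grid positions (from per-tile `origin`
#' metadata when present, otherwise from the grid geometry and overlap in
#' `meta`) and blended by linear feathering across the overlap zones. With
#' `refine = TRUE`, each tile's position is first refined by an integer-pixel
#' translation that maximizes the normalized cross-correlation against its
#' already-placed left (or top) neighbour within the overlap zone, which
#' recovers small stage-repositioning jitters.
#'
#' @param tiles list of tiles, each a list with `row`, `col`, the 8-bit RGB
#'   `img`, and optionally a nominal `origin` (y, x; 1-based).
#' @param meta an [acquisition_meta()].
#' @param refine refine tile placement by cross-correlation (default FALSE).
#' @param search_radius maximum refinement shift per axis, px (default 5).
#' @param background fill colour for canvas pixels no tile covers (possible
#'   at the borders when refined tiles move inward).
#' @return stitched 8-bit RGB image with attributes `origins` (placed tile
#'   origins, one row per tile in `tiles` order), `nominal_origins`, and
#'   `offsets` (= placed - nominal, the recovered jitters).
#' @export
stitch_section <- function(tiles, meta, refine = FALSE, search_radius = 5L,
                           background = c(245, 245, 245)) {
  nr <- meta$tile_grid[1]; nc <- meta$tile_grid[2]
  idx <- matrix(NA_integer_, nr, nc)
  for (i in seq_along(tiles)) idx[tiles[[i]]$row, tiles[[i]]$col] <- i
  if (anyNA(idx)) {
    m <- which(is.na(idx), arr.ind = TRUE)[1, ]
    stop(sprintf("missing tile at row %d, col %d", m[1], m[2]))
  }
  td <- dim(tiles[[idx[1, 1]]]$img)
  th <- td[1]; tw <- td[2]

  nominal <- matrix(0L, length(tiles), 2L)
  have_origin <- all(vapply(tiles, function(t) !is.null(t$origin), logical(1)))
  step_y <- as.integer(round_half_up(th * (1 - meta$overlap_fraction)))
  step_x <- as.integer(round_half_up(tw * (1 - meta$overlap_fraction)))
  for (i in seq_along(tiles)) {
    t <- tiles[[i]]
    nominal[i, ] <- if (have_origin) as.integer(t$origin) else
      c(1L + (t$row - 1L) * step_y, 1L + (t$col - 1L) * step_x)
  }

  # effective grid steps (from supplied origins when available), which set
  # both the overlap width and the feather width
  uy <- sort(unique(nominal[, 1])); ux <- sort(unique(nominal[, 2]))
  if (length(uy) > 1L) step_y <- min(diff(uy))
  if (length(ux) > 1L) step_x <- min(diff(ux))

  placed <- nominal
  if (refine && length(tiles) > 1L) {
    ov_y <- th - max(1L, step_y)   # available overlap widths
    ov_x <- tw - max(1L, step_x)
    lums <- lapply(tiles, function(t) luminance(t$img))
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (r == 1L && cc == 1L) next           # anchor tile
      i <- idx[r, cc]
      nb <- if (cc > 1L) idx[r, cc - 1L] else idx[r - 1L, cc]
      best <- -Inf; best_s <- c(0L, 0L)
      # candidates ordered by |shift| so flat ties prefer the nominal position
      sr <- as.integer(search_radius)
      cand <- expand.grid(sy = -sr:sr, sx = -sr:sr)
      cand <- cand[order(abs(cand$sy) + abs(cand$sx)), ]
      for (k in seq_len(nrow(cand))) {
        s <- c(cand$sy[k], cand$sx[k])
        ot <- nominal[i, ] + s
        on <- placed[nb, ]
        y0 <- max(ot[1], on[1]); y1 <- min(ot[1], on[1]) + th - 1L
        x0 <- max(ot[2], on[2]); x1 <- min(ot[2], on[2]) + tw - 1L
        if (y1 < y0 || x1 < x0) next
        a <- lums[[nb]][(y0 - on[1] + 1L):(y1 - on[1] + 1L),
                        (x0 - on[2] + 1L):(x1 - on[2] + 1L)]
        b <- lums[[i]][(y0 - ot[1] + 1L):(y1 - ot[1] + 1L),
                       (x0 - ot[2] + 1L):(x1 - ot[2] + 1L)]
        sc <- patch_score(a, b)
        if (sc > best) { best <- sc; best_s <- s }
      }
      if (abs(best_s[1]) >= ov_y || abs(best_s[2]) >= ov_x) {
        warning(sprintf(
          "tile (%d, %d): refinement shift (%d, %d) exceeds the overlap; using nominal position",
          r, cc, best_s[1], best_s[2]))
        best_s <- c(0L, 0L)
      }
      placed[i, ] <- nominal[i, ] + best_s
    }
  }

  # composite on a canvas expanded to hold every placed tile, then crop/pad
  # back to the nominal extent so output dimensions depend only on the grid
  # geometry, not on the recovered jitters
  H <- max(nominal[, 1]) + th - 1L
  W <- max(nominal[, 2]) + tw - 1L
  y_min <- min(placed[, 1], 1L); x_min <- min(placed[, 2], 1L)
  He <- max(max(placed[, 1]) + th - 1L, H) - y_min + 1L
  We <- max(max(placed[, 2]) + tw - 1L, W) - x_min + 1L
  feather_y <- max(1L, th - step_y)
  feather_x <- max(1L, tw - step_x)
  ramp <- function(n, f) pmin(pmin(seq_len(n), rev(seq_len(n))), f) / f
  w2 <- outer(ramp(th, feather_y), ramp(tw, feather_x))

  acc <- array(0, dim = c(He, We, 3L))
  wacc <- matrix(0, He, We)
  for (i in seq_along(tiles)) {
    ys <- (placed[i, 1] - y_min + 1L):(placed[i, 1] - y_min + th)
    xs <- (placed[i, 2] - x_min + 1L):(placed[i, 2] - x_min + tw)
    for (c in 1:3) {
      acc[ys, xs, c] <- acc[ys, xs, c] + w2 * tiles[[i]]$img[, , c]
    }
    wacc[ys, xs] <- wacc[ys, xs] + w2
  }
  out <- array(0, dim = c(H, W, 3L))
  ys <- seq_len(H) - y_min + 1L
  xs <- seq_len(W) - x_min + 1L
  wcrop <- wacc[ys, xs]
  covered <- wcrop > 0
  for (c in 1:3) {
    ch <- matrix(background[c], H, W)
    a <- acc[ys, xs, c]
    ch[covered] <- a[covered] / wcrop[covered]
    out[, , c] <- ch
  }
  out <- clip8(out)
  structure(out, origins = placed, nominal_origins = nominal,
            offsets = placed - nominal, canvas_origin = c(y_min, x_min))
}

# Integer-pixel translation estimate between two equally shaped real images:
# the peak of the circular cross-correlation of the mean-subtracted images
# (matched filter, computed by FFT). Correlation plateaus arise when one
# structure nests inside the other (any placement of the smaller inside the
# larger scores the same), so among near-maximal entries the smallest shift
# wins. Returns the displacement d = (dy, dx) of b relative to a, i.e. b is
# a with its content translated by +d; aligning b onto a means translating
# it by -d.
phase_correlate <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  r <- Re(fft(fft(a - mean(a)) * Conj(fft(b - mean(b))), inverse = TRUE))
  rmax <- max(r)
  tol <- 1e-6 * max(abs(r))
  cand <- which(r >= rmax - tol, arr.ind = TRUE) - 1L
  n <- dim(a)
  for (j in 1:2) {
    w <- cand[, j] > n[j] %/% 2
    cand[w, j] <- cand[w, j] - n[j]
  }
  best <- which.min(abs(cand[, 1]) + abs(cand[, 2]))
  -as.integer(cand[best, ])  # the peak sits at minus the displacement of b
}

#' Align a stack of stitched sections by integer-pixel translation
#'
#' Corrects the small stage-repositioning misalignments between consecutive
#' sections: each section is registered to its predecessor by FFT
#' cross-correlation of the mean-subtracted luminance channel (a matched
#' filter; ties from nested structures resolve to the smallest shift), the
#' estimated displacements are accumulated, and every section is placed on a
#' common padded canvas so no data is cropped. Padding is filled with the
#' background colour so that the balanced detector still classifies it as
#' embedding compound. Sections with no structure at all (uniform luminance)
#' carry no registration signal and keep a zero shift.
#'
#' @param sections list of 8-bit RGB section images of equal size, or a
#'   (z, y, x, 3) volume.
#' @param cap maximum plausible per-pair displacement, px; estimates beyond
#'   it are flagged and not applied (default 50).
#' @param background canvas fill colour (default the embedding white
#'   245, 245, 245).
#' @return an object of class `stitched_stack`: list with `volume`
#'   (z, y, x, 3 array), `shifts` (per-section estimated displacement
#'   relative to the previous section; row 1 is (0, 0)), `cumulative`, and
#'   logical `flagged`.
#' @export
align_stack <- function(sections, cap = 50L, background = c(245, 245, 245)) {
  if (is.array(sections) && length(dim(sections)) == 4L) {
    v <- sections
    sections <- lapply(seq_len(dim(v)[1]), function(z)
      array(v[z, , , ], dim = dim(v)[-1]))
  }
  if (!is.list(sections) || length(sections) == 0L) {
    stop("sections must be a nonempty list of RGB images")
  }
  n <- length(sections)
  d0 <- dim(sections[[1]])
  lums <- lapply(sections, luminance)
  shifts <- matrix(0L, n, 2L, dimnames = list(NULL, c("dy", "dx")))
  flagged <- logical(n)
  for (k in seq_len(n)[-1]) {
    if (sd(lums[[k - 1L]]) == 0 || sd(lums[[k]]) == 0) {
      next   # a structureless (uniform) section carries no registration signal
    }
    d <- phase_correlate(lums[[k - 1L]], lums[[k]])
    if (max(abs(d)) > cap) {
      flagged[k] <- TRUE
      d <- c(0L, 0L)
    }
    shifts[k, ] <- d
  }
  cum <- apply(shifts, 2L, cumsum)
  if (n == 1L) cum <- matrix(cum, 1L, 2L)
  # correction moves each section by -cumulative displacement
  corr <- -cum
  y0 <- min(corr[, 1]); x0 <- min(corr[, 2])
  H <- d0[1] + max(corr[, 1]) - y0
  W <- d0[2] + max(corr[, 2]) - x0
  vol <- array(0, dim = c(n, H, W, 3L))
  for (c in 1:3) vol[, , , c] <- background[c]
  for (k in seq_len(n)) {
    ys <- (corr[k, 1] - y0 + 1L):(corr[k, 1] - y0 + d0[1])
    xs <- (corr[k, 2] - x0 + 1L):(corr[k, 2] - x0 + d0[2])
    vol[k, ys, xs, ] <- sections[[k]]
  }
  structure(list(volume = vol, shifts = shifts, cumulative = cum,
                 flagged = flagged),
            class = "stitched_stack")
}
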