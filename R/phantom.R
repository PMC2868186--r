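#' Describe one ellipsoidal organ of a synthetic phantom
#'
#' @param name organ name (unique within a phantom).
#' @param center_mm ellipsoid centre as (z, y, x) in mm.
#' @param semiaxes_mm semi-axis lengths (z, y, x) in mm, all positive.
#' @param mean_rgb mean colour as an 8-bit (R, G, B) triple.
#' @param rgb_noise_sd standard deviation of i.i.d. Gaussian colour noise per
#'   channel inside the organ (8-bit scale; 0 disables noise).
#' @return an object of class `phantom_organ`.
#' @export
phantom_organ <- function(name, center_mm, semiaxes_mm, mean_rgb,
                          rgb_noise_sd = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            length(center_mm) == 3L, length(semiaxes_mm) == 3L,
            length(mean_rgb) == 3L, length(rgb_noise_sd) == 1L)
  if (any(semiaxes_mm <= 0)) stop("all semi-axes must be positive")
  if (any(mean_rgb < 0 | mean_rgb > 255)) stop("mean_rgb must be in 0..255")
  if (rgb_noise_sd < 0) stop("rgb_noise_sd must be nonnegative")
  structure(list(name = name, center_mm = as.numeric(center_mm),
                 semiaxes_mm = as.numeric(semiaxes_mm),
                 mean_rgb = as.numeric(mean_rgb),
                 rgb_noise_sd = as.numeric(rgb_noise_sd)),
            class = "phantom_organ")
}

#' Specify a synthetic tiled block-face acquisition
#'
#' The phantom emulates what the instrument sees: colored ellipsoidal organs
#' frozen in a bright achromatic embedding block, sectioned at a fixed
#' thickness and photographed as an overlapping tile grid per section, with
#' radially symmetric vignetting in every tile and (optionally) an integer
#' stage-repositioning jitter per tile. Defaults follow the acquisition
#' geometry of the instrument this package targets: 15.6 um in-plane pixels
#' and 40 um sections, with at least 15% overlap between adjacent tiles.
#'
#' @param canvas_size voxel grid size (nz, ny, nx).
#' @param organs list of [phantom_organ()] objects; every ellipsoid must lie
#'   inside the physical canvas.
#' @param voxel_spacing (dz, dy, dx) in um.
#' @param background_rgb colour of the embedding compound (achromatic white).
#' @param tile_grid tiles per section as (rows, cols).
#' @param overlap_fraction minimum fractional overlap between adjacent tiles,
#'   in `[0, 1)`.
#' @param vignette_strength relative strength s of the per-tile radial gain
#'   `1 - s * (r / r_max)^2`, in `[0, 1)`. The gain field is normalized to
#'   unit mean so that white-card flat-field correction is unbiased.
#' @param tile_jitter_px maximum absolute integer jitter (px) applied to each
#'   tile's crop window; the first tile of each section anchors the frame and
#'   carries no jitter.
#' @param tile_noise_sd standard deviation of additive sensor noise applied
#'   per tile pixel and channel after vignetting (default 0).
#' @param seed integer seed; identical specs with identical seeds generate
#'   bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(canvas_size, organs,
                         voxel_spacing = c(40, 15.6, 15.6),
                         background_rgb = c(245, 245, 245),
                         tile_grid = c(2, 2),
                         overlap_fraction = 0.15,
                         vignette_strength = 0.1,
                         tile_jitter_px = 0L,
                         tile_noise_sd = 0,
                         seed = 1L) {
  stopifnot(length(canvas_size) == 3L, length(voxel_spacing) == 3L,
            length(background_rgb) == 3L, length(tile_grid) == 2L)
  canvas_size <- as.integer(canvas_size)
  if (any(canvas_size < 1L)) stop("canvas_size must be positive")
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)")
  }
  if (vignette_strength < 0 || vignette_strength >= 1) {
    stop("vignette_strength must be in [0, 1)")
  }
  if (tile_jitter_px < 0) stop("tile_jitter_px must be nonnegative")
  if (!is.list(organs) || (length(organs) > 0 &&
      !all(vapply(organs, inherits, logical(1), "phantom_organ")))) {
    stop("organs must be a list of phantom_organ objects")
  }
  nm <- vapply(organs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("organ names must be unique")
  # physical extent spanned by voxel centres, in mm
  extent_mm <- (canvas_size - 1L) * voxel_spacing / 1000
  for (o in organs) {
    if (any(o$center_mm - o$semiaxes_mm < 0) ||
        any(o$center_mm + o$semiaxes_mm > extent_mm)) {
      stop("organ '", o$name, "' does not lie inside the canvas")
    }
  }
  structure(list(canvas_size = canvas_size,
                 voxel_spacing = as.numeric(voxel_spacing),
                 organs = organs,
                 background_rgb = as.numeric(background_rgb),
                 tile_grid = as.integer(tile_grid),
                 overlap_fraction = overlap_fraction,
                 vignette_strength = vignette_strength,
                 tile_jitter_px = as.integer(tile_jitter_px),
                 tile_noise_sd = as.numeric(tile_noise_sd),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Rasterize an ellipsoid by voxel-centre sampling
#'
#' A voxel belongs to the ellipsoid when its centre lies inside it
#' (centre sampling, consistent with whole-voxel volumetry).
#'
#' @param dims voxel grid size (nz, ny, nx).
#' @param spacing_um voxel spacing (dz, dy, dx) in um.
#' @param center_mm,semiaxes_mm ellipsoid centre and semi-axes, (z, y, x) mm.
#' @return logical array of dimension `dims`.
#' @export
ellipsoid_mask <- function(dims, spacing_um, center_mm, semiaxes_mm) {
  sp <- spacing_um / 1000
  qz <- (((seq_len(dims[1]) - 1) * sp[1] - center_mm[1]) / semiaxes_mm[1])^2
  qy <- (((seq_len(dims[2]) - 1) * sp[2] - center_mm[2]) / semiaxes_mm[2])^2
  qx <- (((seq_len(dims[3]) - 1) * sp[3] - center_mm[3]) / semiaxes_mm[3])^2
  q <- outer(outer(qz, qy, `+`), qx, `+`)
  q <= 1
}

# Tile geometry shared by the generator and the stitcher: tile shape and
# nominal 1-based origins along one axis, given grid count n and minimum
# overlap o. Tiles are spread evenly, which keeps every pairwise overlap at
# least o of the tile extent.
tile_layout_1d <- function(extent, n, o) {
  if (n == 1L) return(list(tile = as.integer(extent), origins = 1L))
  tile <- as.integer(min(extent, ceiling(extent / (n - (n - 1) * o))))
  repeat {
    origins <- 1L +
      as.integer(round_half_up((seq_len(n) - 1) * (extent - tile) / (n - 1)))
    if (tile >= extent || tile - max(diff(origins)) >= o * tile) break
    tile <- tile + 1L   # absorb integer rounding so min overlap stays >= o
  }
  if (any(diff(origins) > tile)) {
    stop("tiles cannot cover the section: overlap too small for this grid")
  }
  list(tile = as.integer(tile), origins = origins)
}

# Unit-mean radial vignetting gain field for a tile of shape (h, w).
vignette_field <- function(h, w, strength) {
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  r2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
  g <- 1 - strength * r2 / max(r2)
  g / mean(g)
}

#' Generate a synthetic tiled block-face acquisition with ground truth
#'
#' Builds the ideal colour volume (organs rasterized into the embedding
#' background, with per-organ colour noise), then cuts each section into a
#' jittered, vignetted tile set exactly as the instrument would record it,
#' together with a white-card reference image and the full ground truth
#' needed to validate every downstream step: the label volume, analytic
#' ellipsoid volumes, the true per-tile jitters and the vignetting field.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `cryo_phantom` with elements:
#' \describe{
#'   \item{tiles}{per-section list of tiles, each a list with `row`, `col`,
#'     nominal `origin` (y, x; 1-based) and the 8-bit RGB `img`.}
#'   \item{white_ref}{white-card image (tile shape, RGB), carrying the same
#'     vignetting as every tile.}
#'   \item{truth}{ground truth: `label_volume`, `name_table`,
#'     `analytic_volumes` (mm^3), `tile_offsets` (per section, per tile
#'     (dy, dx) jitter), `vignette_field`, `ideal_volume`,
#'     `nominal_origins`, `tile_shape`.}
#'   \item{meta}{an [acquisition_meta()] describing the phantom acquisition.}
#'   \item{spec}{the input spec.}
#' }
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$canvas_size
  nz <- d[1]; ny <- d[2]; nx <- d[3]

  labels <- array(0L, dim = d)
  for (i in seq_along(spec$organs)) {
    o <- spec$organs[[i]]
    inside <- ellipsoid_mask(d, spec$voxel_spacing, o$center_mm, o$semiaxes_mm)
    labels[inside & labels == 0L] <- i   # first-wins for overlapping organs
  }

  ideal <- array(0, dim = c(d, 3L))
  for (c in 1:3) ideal[, , , c] <- spec$background_rgb[c]
  for (i in seq_along(spec$organs)) {
    o <- spec$organs[[i]]
    sel <- labels == i
    n <- sum(sel)
    if (n == 0L) next
    for (c in 1:3) {
      v <- rep(o$mean_rgb[c], n)
      if (o$rgb_noise_sd > 0) v <- v + rnorm(n, sd = o$rgb_noise_sd)
      ch <- ideal[, , , c]
      ch[sel] <- v
      ideal[, , , c] <- ch
    }
  }
  ideal <- clip8(ideal)

  ly <- tile_layout_1d(ny, spec$tile_grid[1], spec$overlap_fraction)
  lx <- tile_layout_1d(nx, spec$tile_grid[2], spec$overlap_fraction)
  th <- ly$tile; tw <- lx$tile
  gain <- vignette_field(th, tw, spec$vignette_strength)
  white_level <- 200   # card reflectance level; keeps the gain peak below 255
  white_ref <- clip8(array(white_level * rep(gain, 3L), dim = c(th, tw, 3L)))
  brightest <- max(c(spec$background_rgb,
                     vapply(spec$organs, function(o) max(o$mean_rgb),
                            numeric(1))))
  if (brightest * max(gain) > 255.5) {
    warning("tile highlights saturate at the vignette gain peak (",
            round(brightest * max(gain)), " > 255); ",
            "flat-field recovery will be lossy there")
  }

  j <- spec$tile_jitter_px
  tiles <- vector("list", nz)
  offsets <- vector("list", nz)
  gain3 <- array(rep(gain, 3L), dim = c(th, tw, 3L))
  for (z in seq_len(nz)) {
    sec <- array(ideal[z, , , ], dim = c(ny, nx, 3L))
    if (j > 0L) {   # pad so jittered crops always stay inside
      pad <- array(0, dim = c(ny + 2L * j, nx + 2L * j, 3L))
      for (c in 1:3) pad[, , c] <- spec$background_rgb[c]
      pad[j + seq_len(ny), j + seq_len(nx), ] <- sec
      sec <- pad
    }
    ts <- list()
    om <- matrix(0L, nrow = spec$tile_grid[1] * spec$tile_grid[2], ncol = 2L,
                 dimnames = list(NULL, c("dy", "dx")))
    k <- 0L
    for (r in seq_len(spec$tile_grid[1])) {
      for (cc in seq_len(spec$tile_grid[2])) {
        k <- k + 1L
        jit <- c(0L, 0L)
        if (j > 0L && !(r == 1L && cc == 1L)) {
          jit <- c(sample(-j:j, 1L), sample(-j:j, 1L))
        }
        y0 <- ly$origins[r] + jit[1] + j
        x0 <- lx$origins[cc] + jit[2] + j
        crop <- sec[y0:(y0 + th - 1L), x0:(x0 + tw - 1L), , drop = FALSE]
        img <- crop * gain3
        if (spec$tile_noise_sd > 0) {
          img <- img + rnorm(length(img), sd = spec$tile_noise_sd)
        }
        ts[[k]] <- list(row = r, col = cc,
                        origin = c(ly$origins[r], lx$origins[cc]),
                        img = clip8(img))
        om[k, ] <- jit
      }
    }
    tiles[[z]] <- ts
    offsets[[z]] <- om
  }

  nm <- vapply(spec$organs, `[[`, character(1), "name")
  av <- vapply(spec$organs, function(o) 4 / 3 * pi * prod(o$semiaxes_mm),
               numeric(1))
  names(av) <- nm
  meta <- acquisition_meta(tile_grid = spec$tile_grid,
                           overlap_fraction = spec$overlap_fraction,
                           pixel_size_um = spec$voxel_spacing[3],
                           section_thickness_um = spec$voxel_spacing[1],
                           tile_shape_px = c(th, tw),
                           n_sections = nz)
  structure(list(tiles = tiles, white_ref = white_ref,
                 truth = list(label_volume = labels,
                              name_table = stats::setNames(nm, seq_along(nm)),
                              analytic_volumes = av,
                              tile_offsets = offsets,
                              vignette_field = gain,
                              ideal_volume = ideal,
                              nominal_origins = list(y = ly$origins,
                                                     x = lx$origins),
                              tile_shape = c(th, tw)),
                 meta = meta, spec = spec),
            class = "cryo_phantom")
}

#' Relative error of voxel-count volumes against analytic ellipsoid volumes
#'
#' For each organ, compares the whole-voxel count of the ground-truth label
#' volume (times the voxel volume) to the closed-form ellipsoid volume
#' 4/3 pi abc. Used as the rasterization oracle for volumetry.
#'
#' @param truth the `truth` element of a [generate_phantom()] result.
#' @param spacing_um voxel spacing (dz, dy, dx) in um.
#' @return named numeric vector of relative errors, one per organ.
#' @export
rasterized_volume_error <- function(truth, spacing_um) {
  if (is.null(truth$label_volume)) stop("truth has no label volume")
  av <- truth$analytic_volumes
  if (length(av) == 0L) return(stats::setNames(numeric(0), character(0)))
  voxvol <- prod(spacing_um) / 1e9   # mm^3
  out <- numeric(length(av))
  for (i in seq_along(av)) {
    cnt <- sum(truth$label_volume == i)
    if (cnt == 0L) stop("organ '", names(av)[i], "' absent from label volume")
    out[i] <- abs(cnt * voxvol - av[i]) / av[i]
  }
  stats::setNames(out, names(av))
}
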