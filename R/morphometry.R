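#' Define a multiplanar-reformatting plane
#'
#' A sampling plane in physical (mm) coordinates, axis order (z, y, x): the
#' image row axis is `u`, the column axis `v = normal x u`, and samples lie
#' at `origin + (i-1) * spacing_mm * u + (j-1) * spacing_mm * v`.
#'
#' @param origin_mm plane origin (z, y, x), mm.
#' @param normal_mm unit plane normal (z, y, x).
#' @param u_mm unit in-plane row axis, orthogonal to the normal.
#' @param extent_mm physical extent (along u, along v), mm.
#' @param spacing_mm sample spacing, mm.
#' @return an object of class `mpr_plane` (with the derived `v` axis).
#' @export
mpr_plane <- function(origin_mm, normal_mm, u_mm, extent_mm, spacing_mm) {
  stopifnot(length(origin_mm) == 3L, length(normal_mm) == 3L,
            length(u_mm) == 3L, length(extent_mm) == 2L)
  if (spacing_mm <= 0) stop("spacing_mm must be positive")
  nlen <- sqrt(sum(normal_mm^2)); ulen <- sqrt(sum(u_mm^2))
  if (abs(nlen - 1) > 1e-8 || abs(ulen - 1) > 1e-8) {
    stop("normal and u must be unit vectors")
  }
  if (abs(sum(normal_mm * u_mm)) > 1e-8) {
    stop("u must be orthogonal to the normal")
  }
  v <- c(normal_mm[2] * u_mm[3] - normal_mm[3] * u_mm[2],
         normal_mm[3] * u_mm[1] - normal_mm[1] * u_mm[3],
         normal_mm[1] * u_mm[2] - normal_mm[2] * u_mm[1])
  structure(list(origin_mm = as.numeric(origin_mm),
                 normal = as.numeric(normal_mm), u = as.numeric(u_mm),
                 v = v, extent_mm = as.numeric(extent_mm),
                 spacing_mm = spacing_mm),
            class = "mpr_plane")
}

# Trilinear (or nearest) sampling of one channel at physical points.
# pts: n x 3 matrix of (z, y, x) in mm; ch: 3D array; spacing_mm: (dz,dy,dx).
sample_channel <- function(ch, pts, spacing_mm, interpolation, background) {
  d <- dim(ch)
  g <- sweep(pts, 2L, spacing_mm, `/`) + 1   # continuous 1-based grid coords
  if (interpolation == "nearest") {
    iz <- round_half_up(g[, 1]); iy <- round_half_up(g[, 2])
    ix <- round_half_up(g[, 3])
    inb <- iz >= 1 & iz <= d[1] & iy >= 1 & iy <= d[2] & ix >= 1 & ix <= d[3]
    out <- rep(background, nrow(pts))
    out[inb] <- ch[cbind(iz[inb], iy[inb], ix[inb])]
    return(list(values = out, oob = sum(!inb)))
  }
  ok <- g[, 1] >= 1 & g[, 1] <= d[1] & g[, 2] >= 1 & g[, 2] <= d[2] &
        g[, 3] >= 1 & g[, 3] <= d[3]
  # cell corner: points on the far face (or a singleton axis) interpolate
  # from the last cell with fractional weight 0 toward a clamped far index
  z0 <- pmax(pmin(floor(g[, 1]), d[1] - 1), 1)
  y0 <- pmax(pmin(floor(g[, 2]), d[2] - 1), 1)
  x0 <- pmax(pmin(floor(g[, 3]), d[3] - 1), 1)
  fz <- g[, 1] - z0; fy <- g[, 2] - y0; fx <- g[, 3] - x0
  z1 <- pmin(z0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); x1 <- pmin(x0 + 1, d[3])
  out <- rep(background, nrow(pts))
  if (any(ok)) {
    c000 <- ch[cbind(z0[ok], y0[ok], x0[ok])]
    c001 <- ch[cbind(z0[ok], y0[ok], x1[ok])]
    c010 <- ch[cbind(z0[ok], y1[ok], x0[ok])]
    c011 <- ch[cbind(z0[ok], y1[ok], x1[ok])]
    c100 <- ch[cbind(z1[ok], y0[ok], x0[ok])]
    c101 <- ch[cbind(z1[ok], y0[ok], x1[ok])]
    c110 <- ch[cbind(z1[ok], y1[ok], x0[ok])]
    c111 <- ch[cbind(z1[ok], y1[ok], x1[ok])]
    wz <- fz[ok]; wy <- fy[ok]; wx <- fx[ok]
    out[ok] <-
      (1 - wz) * ((1 - wy) * ((1 - wx) * c000 + wx * c001) +
                  wy * ((1 - wx) * c010 + wx * c011)) +
      wz * ((1 - wy) * ((1 - wx) * c100 + wx * c101) +
            wy * ((1 - wx) * c110 + wx * c111))
  }
  list(values = out, oob = sum(!ok))
}

#' Extract an arbitrarily oriented digital section (multiplanar reformat)
#'
#' Samples the colour volume over the plane's grid. Samples falling outside
#' the volume are filled with the background colour and counted in a warning
#' (planes through a bone axis commonly exit the block). An axis-aligned
#' plane with nearest interpolation at native spacing reproduces the stored
#' section bit-exactly.
#'
#' @param volume 8-bit RGB volume (z, y, x, 3).
#' @param plane an [mpr_plane()].
#' @param spacing_um voxel spacing of the volume (dz, dy, dx), um.
#' @param interpolation `"nearest"` or `"trilinear"`.
#' @param background fill colour for out-of-volume samples.
#' @return 8-bit RGB image of the reformatted section.
#' @export
extract_plane <- function(volume, plane, spacing_um = c(40, 15.6, 15.6),
                          interpolation = c("nearest", "trilinear"),
                          background = c(245, 245, 245)) {
  interpolation <- match.arg(interpolation)
  volume <- check_rgb(volume)
  stopifnot(inherits(plane, "mpr_plane"))
  sp_mm <- spacing_um / 1000
  ni <- max(1L, as.integer(floor(plane$extent_mm[1] / plane$spacing_mm)) + 1L)
  nj <- max(1L, as.integer(floor(plane$extent_mm[2] / plane$spacing_mm)) + 1L)
  ij <- expand.grid(i = seq_len(ni) - 1L, j = seq_len(nj) - 1L)
  pts <- matrix(plane$origin_mm, nrow(ij), 3L, byrow = TRUE) +
    outer(ij$i * plane$spacing_mm, plane$u) +
    outer(ij$j * plane$spacing_mm, plane$v)
  out <- array(0, dim = c(ni, nj, 3L))
  oob <- 0L
  for (c in 1:3) {
    ch <- array(volume[, , , c], dim = dim(volume)[1:3])
    s <- sample_channel(ch, pts, sp_mm, interpolation, background[c])
    out[, , c] <- matrix(s$values, ni, nj)
    oob <- max(oob, s$oob)
  }
  if (oob > 0L) {
    warning(oob, " plane sample(s) fell outside the volume; ",
            "filled with background")
  }
  clip8(out)
}

#' Euclidean distance between two physical points
#'
#' Points are (z, y, x) in mm; convert voxel indices first with
#' [voxel_to_mm()].
#'
#' @param p1,p2 physical points (z, y, x), mm.
#' @return distance in mm.
#' @export
linear_distance <- function(p1, p2) {
  stopifnot(length(p1) == 3L, length(p2) == 3L,
            all(is.finite(p1)), all(is.finite(p2)))
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
}

#' Convert 1-based voxel indices to physical mm coordinates
#'
#' @param idx voxel index (z, y, x), 1-based.
#' @param spacing_um voxel spacing (dz, dy, dx), um.
#' @return physical point (z, y, x) in mm (voxel centres; voxel 1 at 0).
#' @export
voxel_to_mm <- function(idx, spacing_um = c(40, 15.6, 15.6)) {
  (as.numeric(idx) - 1) * spacing_um / 1000
}

#' Cross-sectional area of a binary mask on a reformatted plane
#'
#' @param mask_plane binary image (the cortical-bone mask on a transverse
#'   plane).
#' @param pixel_area_mm2 area of one plane pixel, mm^2.
#' @return area in mm^2.
#' @export
cross_section_area <- function(mask_plane, pixel_area_mm2) {
  mask_plane <- check_binary_mask(mask_plane, "mask_plane")
  if (pixel_area_mm2 <= 0) stop("pixel_area_mm2 must be positive")
  sum(mask_plane) * pixel_area_mm2
}

#' Bone morphometry ratios
#'
#' Bone lengths normalized by body length (nose to base of tail), the
#' tibia-to-femur length ratio, and optionally the cortical-area-to-length
#' ratios that index bone growth.
#'
#' @param femur_mm,tibia_mm bone lengths, mm.
#' @param body_length_mm body length, mm, or `NULL` to skip body
#'   normalization.
#' @param femur_cortical_mm2,tibia_cortical_mm2 optional mid-diaphyseal
#'   cortical areas, mm^2.
#' @return a list of class `bone_report`: `femur_length_mm`,
#'   `tibia_length_mm`, `tibia_femur_ratio`, and when inputs allow,
#'   `femur_over_body_pct`, `tibia_over_body_pct` (rounded to whole percent,
#'   unrounded values in `*_unrounded`), and `cortical_over_length_mm`
#'   per bone.
#' @examples
#' bone_ratios(11.46, 17.26, 87.6)
#' @export
bone_ratios <- function(femur_mm, tibia_mm, body_length_mm = NULL,
                        femur_cortical_mm2 = NULL, tibia_cortical_mm2 = NULL) {
  if (femur_mm <= 0 || tibia_mm <= 0) stop("bone lengths must be positive")
  out <- list(femur_length_mm = femur_mm, tibia_length_mm = tibia_mm,
              tibia_femur_ratio = tibia_mm / femur_mm)
  if (!is.null(body_length_mm)) {
    if (body_length_mm <= 0) stop("body_length_mm must be positive")
    out$body_length_mm <- body_length_mm
    out$femur_over_body_pct_unrounded <- 100 * femur_mm / body_length_mm
    out$tibia_over_body_pct_unrounded <- 100 * tibia_mm / body_length_mm
    out$femur_over_body_pct <- round_half_up(out$femur_over_body_pct_unrounded)
    out$tibia_over_body_pct <- round_half_up(out$tibia_over_body_pct_unrounded)
  }
  if (!is.null(femur_cortical_mm2)) {
    out$femur_cortical_mm2 <- femur_cortical_mm2
    out$femur_cortical_over_length_mm <- femur_cortical_mm2 / femur_mm
  }
  if (!is.null(tibia_cortical_mm2)) {
    out$tibia_cortical_mm2 <- tibia_cortical_mm2
    out$tibia_cortical_over_length_mm <- tibia_cortical_mm2 / tibia_mm
  }
  class(out) <- "bone_report"
  out
}

#' @export
print.bone_report <- function(x, ...) {
  cat(sprintf("femur %.2f mm, tibia %.2f mm, tibia/femur %.3f\n",
              x$femur_length_mm, x$tibia_length_mm, x$tibia_femur_ratio))
  if (!is.null(x$body_length_mm)) {
    cat(sprintf("over body length %.1f mm: femur %d%%, tibia %d%%\n",
                x$body_length_mm, as.integer(x$femur_over_body_pct),
                as.integer(x$tibia_over_body_pct)))
  }
  invisible(x)
}
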