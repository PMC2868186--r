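#' Bricked multiresolution colour-volume pyramid
#'
#' A whole-animal cryo-imaging volume is far larger than workstation memory,
#' so it is stored as a resolution pyramid of independently addressable
#' bricks: coarse levels give subsampled whole-volume views, and any region
#' of any level — in particular full-resolution crops — can be read without
#' touching the rest of the volume. Level L+1 is the 2x2x2 box-filter mean of
#' level L per channel (edge blocks averaged over the voxels available),
#' rounded half-up to 8 bit; a box filter is used rather than decimation so
#' that structures near the voxel scale (fine vessels) attenuate instead of
#' aliasing.
#'
#' @param volume 8-bit RGB volume (z, y, x, 3).
#' @param spacing_um native voxel spacing (dz, dy, dx), um; level L has
#'   spacing `spacing_um * 2^L`.
#' @param n_levels number of levels including the native one; clamped with a
#'   warning if it exceeds what the volume supports.
#' @param brick_shape brick (chunk) shape in voxels, (z, y, x).
#' @return an object of class `cryo_pyramid`.
#' @export
build_pyramid <- function(volume, spacing_um = c(40, 15.6, 15.6),
                          n_levels = 1L, brick_shape = c(64L, 256L, 256L)) {
  volume <- check_rgb(volume)
  if (length(dim(volume)) != 4L) stop("volume must be (z, y, x, 3)")
  if (n_levels < 1L) stop("n_levels must be >= 1")
  max_levels <- 1L + floor(log2(min(dim(volume)[1:3])))
  if (n_levels > max_levels) {
    warning("n_levels clamped to ", max_levels)
    n_levels <- max_levels
  }
  levels <- vector("list", n_levels)
  cur <- volume
  for (L in seq_len(n_levels)) {
    levels[[L]] <- bricked_level(cur, brick_shape)
    if (L < n_levels) cur <- downsample_box2(cur)
  }
  structure(list(levels = levels, spacing_um = as.numeric(spacing_um),
                 brick_shape = as.integer(brick_shape)),
            class = "cryo_pyramid")
}

# 2x2x2 box-filter downsampling of a (z, y, x, 3) volume. Axes are averaged
# separably over pairs (an odd trailing voxel averages only itself), which
# equals the mean over each (partial) 2x2x2 block; quantization happens once
# at the end, round-half-up.
downsample_box2 <- function(volume) {
  pair_mean <- function(a, axis) {
    d <- dim(a)
    n <- d[axis]
    lo <- seq(1L, n, by = 2L)
    hi <- pmin(lo + 1L, n)
    odd <- hi == lo      # trailing unpaired voxel: average over itself
    ix <- function(i) {
      idx <- rep(list(quote(expr = )), length(d))
      idx[[axis]] <- i
      do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    }
    out <- (ix(lo) + ix(hi)) / 2
    if (any(odd)) {
      idx <- rep(list(quote(expr = )), length(d))
      idx[[axis]] <- which(odd)
      sel <- function(b) do.call(`[`, c(list(b), idx, list(drop = FALSE)))
      asn <- function(b, v) do.call(`[<-`, c(list(b), idx, list(v)))
      out <- asn(out, sel(ix(lo)))
    }
    out
  }
  clip8(pair_mean(pair_mean(pair_mean(volume, 1L), 2L), 3L))
}

# Split a (z, y, x, 3) array into a brick list addressed by brick-grid index.
bricked_level <- function(volume, brick_shape) {
  d <- dim(volume)[1:3]
  nb <- pmax(1L, as.integer(ceiling(d / brick_shape)))
  bricks <- vector("list", prod(nb))
  for (bz in seq_len(nb[1])) for (by in seq_len(nb[2])) for (bx in seq_len(nb[3])) {
    zr <- ((bz - 1L) * brick_shape[1] + 1L):min(bz * brick_shape[1], d[1])
    yr <- ((by - 1L) * brick_shape[2] + 1L):min(by * brick_shape[2], d[2])
    xr <- ((bx - 1L) * brick_shape[3] + 1L):min(bx * brick_shape[3], d[3])
    k <- brick_key(c(bz, by, bx), nb)
    bricks[[k]] <- volume[zr, yr, xr, , drop = FALSE]
  }
  list(dims = d, n_bricks = nb, bricks = bricks)
}

brick_key <- function(b, nb) {
  (b[3] - 1L) * nb[1] * nb[2] + (b[2] - 1L) * nb[1] + b[1]
}

#' Read a region of a pyramid level
#'
#' Returns exactly the requested voxels, assembled from only the bricks the
#' region intersects. Indices are 1-based R index vectors per axis; an empty
#' index vector yields a zero-size volume (no error). Out-of-bounds indices
#' are an error — nothing is clamped silently.
#'
#' @param pyr a [build_pyramid()] result.
#' @param level pyramid level, 1 = native resolution.
#' @param z,y,x index vectors into the level's grid; `NULL` means the full
#'   axis.
#' @return 8-bit RGB array of dimension (length(z), length(y), length(x), 3).
#' @export
read_region <- function(pyr, level, z = NULL, y = NULL, x = NULL) {
  stopifnot(inherits(pyr, "cryo_pyramid"))
  if (level < 1L || level > length(pyr$levels)) stop("no such level: ", level)
  lv <- pyr$levels[[level]]
  d <- lv$dims
  ax <- list(z = z, y = y, x = x)
  for (i in 1:3) {
    if (is.null(ax[[i]])) ax[[i]] <- seq_len(d[i])
    ax[[i]] <- as.integer(ax[[i]])
    if (length(ax[[i]]) > 0 && (min(ax[[i]]) < 1L || max(ax[[i]]) > d[i])) {
      stop("requested ", names(ax)[i], " indices fall outside the level (1..",
           d[i], ")")
    }
  }
  out <- array(0L, dim = c(unname(lengths(ax)), 3L))
  if (any(lengths(ax) == 0L)) return(out)
  bs <- pyr$brick_shape
  bz <- sort(unique((ax$z - 1L) %/% bs[1] + 1L))
  by <- sort(unique((ax$y - 1L) %/% bs[2] + 1L))
  bx <- sort(unique((ax$x - 1L) %/% bs[3] + 1L))
  for (iz in bz) for (iy in by) for (ix in bx) {
    br <- lv$bricks[[brick_key(c(iz, iy, ix), lv$n_bricks)]]
    z_in <- ax$z >= (iz - 1L) * bs[1] + 1L & ax$z <= min(iz * bs[1], d[1])
    y_in <- ax$y >= (iy - 1L) * bs[2] + 1L & ax$y <= min(iy * bs[2], d[2])
    x_in <- ax$x >= (ix - 1L) * bs[3] + 1L & ax$x <= min(ix * bs[3], d[3])
    if (!any(z_in) || !any(y_in) || !any(x_in)) next
    out[z_in, y_in, x_in, ] <- br[ax$z[z_in] - (iz - 1L) * bs[1],
                                  ax$y[y_in] - (iy - 1L) * bs[2],
                                  ax$x[x_in] - (ix - 1L) * bs[3], ,
                                  drop = FALSE]
  }
  out
}

#' @export
print.cryo_pyramid <- function(x, ...) {
  cat("multiresolution colour volume,", length(x$levels), "level(s)\n")
  for (L in seq_along(x$levels)) {
    d <- x$levels[[L]]$dims
    sp <- x$spacing_um * 2^(L - 1)
    cat(sprintf("  level %d: %d x %d x %d voxels at %g x %g x %g um\n",
                L, d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  }
  invisible(x)
}

#' Persist / load a pyramid as a chunked on-disk store
#'
#' Lays the pyramid out as one directory per level containing one raw
#' 8-bit file per brick (`b{z}_{y}_{x}.raw`, channel-last voxel order) and a
#' JSON metadata file with dimensions, brick shape and spacing — a minimal
#' chunked multiresolution store readable by standard array tooling.
#'
#' @param pyr a [build_pyramid()] result.
#' @param dir target / source directory.
#' @return `write_pyramid` the directory (invisibly); `read_pyramid` a
#'   `cryo_pyramid`.
#' @export
write_pyramid <- function(pyr, dir) {
  stopifnot(inherits(pyr, "cryo_pyramid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(n_levels = length(pyr$levels),
               spacing_um = pyr$spacing_um,
               brick_shape = pyr$brick_shape,
               dims = lapply(pyr$levels, `[[`, "dims"),
               n_bricks = lapply(pyr$levels, `[[`, "n_bricks"))
  jsonlite::write_json(meta, file.path(dir, "pyramid.json"),
                       auto_unbox = TRUE, digits = NA)
  for (L in seq_along(pyr$levels)) {
    lv <- pyr$levels[[L]]
    ld <- file.path(dir, sprintf("level%d", L))
    dir.create(ld, showWarnings = FALSE)
    nb <- lv$n_bricks
    for (bz in seq_len(nb[1])) for (by in seq_len(nb[2])) for (bx in seq_len(nb[3])) {
      br <- lv$bricks[[brick_key(c(bz, by, bx), nb)]]
      con <- file(file.path(ld, sprintf("b%d_%d_%d.raw", bz, by, bx)), "wb")
      writeBin(as.integer(br), con, size = 1L)
      close(con)
    }
  }
  invisible(dir)
}

#' @rdname write_pyramid
#' @export
read_pyramid <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "pyramid.json"),
                              simplifyVector = TRUE)
  bs <- as.integer(meta$brick_shape)
  # jsonlite simplifies a list of equal-length vectors to a matrix
  row_of <- function(x, L) {
    if (is.matrix(x)) as.integer(x[L, ]) else as.integer(x[[L]])
  }
  levels <- vector("list", meta$n_levels)
  for (L in seq_len(meta$n_levels)) {
    d <- row_of(meta$dims, L)
    nb <- row_of(meta$n_bricks, L)
    bricks <- vector("list", prod(nb))
    for (bz in seq_len(nb[1])) for (by in seq_len(nb[2])) for (bx in seq_len(nb[3])) {
      bd <- c(min(bz * bs[1], d[1]) - (bz - 1L) * bs[1],
              min(by * bs[2], d[2]) - (by - 1L) * bs[2],
              min(bx * bs[3], d[3]) - (bx - 1L) * bs[3], 3L)
      con <- file(file.path(dir, sprintf("level%d", L),
                            sprintf("b%d_%d_%d.raw", bz, by, bx)), "rb")
      v <- readBin(con, integer(), n = prod(bd), size = 1L, signed = FALSE)
      close(con)
      bricks[[brick_key(c(bz, by, bx), nb)]] <- array(v, dim = bd)
    }
    levels[[L]] <- list(dims = d, n_bricks = nb, bricks = bricks)
  }
  structure(list(levels = levels, spacing_um = as.numeric(meta$spacing_um),
                 brick_shape = bs),
            class = "cryo_pyramid")
}
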