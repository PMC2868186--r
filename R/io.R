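# Reading and writing the on-disk layout: 8-bit RGB TIFF tiles named
# s{section:04d}_r{row}_c{col}.tif plus white_ref.tif, stitched sections as
# sec{0001}.tif with a JSON shift sidecar, and per-section binary PNG masks
# named {organ}_s{section:04d}.png.

img_to_unit <- function(img) img / 255
unit_to_img <- function(u) clip8(u * 255)

#' Write / read a phantom acquisition as TIFF tiles with sidecars
#'
#' `write_tiles()` lays a [generate_phantom()] result out exactly as an
#' acquisition run would: one 8-bit RGB TIFF per tile
#' (`s0001_r1_c2.tif`), the white-card reference (`white_ref.tif`), the
#' ground-truth label volume as one grayscale PNG per section under
#' `labels/`, and a JSON sidecar (`truth.json`) with analytic volumes, true
#' tile offsets, nominal origins and a spec echo. `read_tiles()` loads the
#' tile set and metadata back.
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir target / source directory.
#' @return `write_tiles` the directory, invisibly; `read_tiles` a list with
#'   `tiles`, `white_ref`, `meta`, `sidecar`.
#' @export
write_tiles <- function(phantom, dir) {
  stopifnot(inherits(phantom, "cryo_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (z in seq_along(phantom$tiles)) {
    for (t in phantom$tiles[[z]]) {
      tiff::writeTIFF(img_to_unit(t$img),
                      file.path(dir, sprintf("s%04d_r%d_c%d.tif",
                                             z, t$row, t$col)),
                      bits.per.sample = 8L)
    }
  }
  tiff::writeTIFF(img_to_unit(phantom$white_ref),
                  file.path(dir, "white_ref.tif"), bits.per.sample = 8L)
  lab_dir <- file.path(dir, "labels")
  dir.create(lab_dir, showWarnings = FALSE)
  lv <- phantom$truth$label_volume
  for (z in seq_len(dim(lv)[1])) {
    png::writePNG(matrix(lv[z, , ], dim(lv)[2], dim(lv)[3]) / 255,
                  file.path(lab_dir, sprintf("labels_s%04d.png", z)))
  }
  sidecar <- list(
    analytic_volumes_mm3 = as.list(phantom$truth$analytic_volumes),
    name_table = as.list(phantom$truth$name_table),
    tile_offsets = lapply(phantom$truth$tile_offsets, function(m)
      unname(apply(m, 1L, as.list))),
    nominal_origins = phantom$truth$nominal_origins,
    tile_shape = phantom$truth$tile_shape,
    meta = unclass(phantom$meta),
    spec = list(canvas_size = phantom$spec$canvas_size,
                voxel_spacing = phantom$spec$voxel_spacing,
                overlap_fraction = phantom$spec$overlap_fraction,
                tile_grid = phantom$spec$tile_grid,
                vignette_strength = phantom$spec$vignette_strength,
                tile_jitter_px = phantom$spec$tile_jitter_px,
                seed = phantom$spec$seed))
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_tiles
#' @export
read_tiles <- function(dir) {
  files <- list.files(dir, pattern = "^s\\d{4}_r\\d+_c\\d+\\.tif$")
  if (length(files) == 0L) stop("no tile images found in ", dir)
  info <- regmatches(files, regexec("^s(\\d{4})_r(\\d+)_c(\\d+)\\.tif$", files))
  sidecar <- NULL
  sc_path <- file.path(dir, "truth.json")
  if (file.exists(sc_path)) {
    sidecar <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  }
  sections <- sort(unique(as.integer(vapply(info, `[`, character(1), 2L))))
  tiles <- vector("list", max(sections))
  for (k in seq_along(files)) {
    z <- as.integer(info[[k]][2])
    r <- as.integer(info[[k]][3])
    cc <- as.integer(info[[k]][4])
    img <- unit_to_img(tiff::readTIFF(file.path(dir, files[k])))
    origin <- NULL
    if (!is.null(sidecar)) {
      origin <- c(sidecar$nominal_origins$y[r], sidecar$nominal_origins$x[cc])
    }
    t <- list(row = r, col = cc, img = img)
    if (!is.null(origin)) t$origin <- origin
    tiles[[z]] <- c(tiles[[z]], list(t))
  }
  white_ref <- NULL
  wr <- file.path(dir, "white_ref.tif")
  if (file.exists(wr)) white_ref <- unit_to_img(tiff::readTIFF(wr))
  meta <- NULL
  if (!is.null(sidecar$meta)) {
    meta <- acquisition_meta(
      tile_grid = sidecar$meta$tile_grid,
      overlap_fraction = sidecar$meta$overlap_fraction,
      pixel_size_um = sidecar$meta$pixel_size_um,
      section_thickness_um = sidecar$meta$section_thickness_um,
      tile_shape_px = sidecar$meta$tile_shape_px,
      n_sections = sidecar$meta$n_sections)
  }
  list(tiles = tiles, white_ref = white_ref, meta = meta, sidecar = sidecar)
}

#' Write / read stitched aligned sections
#'
#' Sections go to `sec0001.tif`, ... with the per-section alignment shifts
#' in `shifts.json`.
#'
#' @param stack a [align_stack()] result (`stitched_stack`).
#' @param dir target / source directory.
#' @return `write_stitched` the directory, invisibly; `read_stitched` a
#'   `stitched_stack` (shifts restored from the sidecar).
#' @export
write_stitched <- function(stack, dir) {
  stopifnot(inherits(stack, "stitched_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- stack$volume
  for (z in seq_len(dim(v)[1])) {
    tiff::writeTIFF(img_to_unit(array(v[z, , , ], dim = dim(v)[-1])),
                    file.path(dir, sprintf("sec%04d.tif", z)),
                    bits.per.sample = 8L)
  }
  jsonlite::write_json(list(shifts = stack$shifts,
                            cumulative = stack$cumulative,
                            flagged = stack$flagged),
                       file.path(dir, "shifts.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_stitched
#' @export
read_stitched <- function(dir) {
  files <- sort(list.files(dir, pattern = "^sec\\d{4}\\.tif$"))
  if (length(files) == 0L) stop("no stitched sections found in ", dir)
  secs <- lapply(files, function(f)
    unit_to_img(tiff::readTIFF(file.path(dir, f))))
  d <- dim(secs[[1]])
  vol <- array(0, dim = c(length(secs), d))
  for (z in seq_along(secs)) vol[z, , , ] <- secs[[z]]
  sj <- file.path(dir, "shifts.json")
  shifts <- cumulative <- flagged <- NULL
  if (file.exists(sj)) {
    s <- jsonlite::read_json(sj, simplifyVector = TRUE)
    shifts <- s$shifts; cumulative <- s$cumulative; flagged <- s$flagged
  }
  structure(list(volume = vol, shifts = shifts, cumulative = cumulative,
                 flagged = flagged),
            class = "stitched_stack")
}

#' Write / read per-section binary masks as PNG
#'
#' One file per section, `{organ}_s{section:04d}.png`, the exchange format
#' for manual correction of automatic segmentations in external tools.
#'
#' @param masks logical array (z, y, x) or named list of logical matrices
#'   (names = section indices).
#' @param organ organ name used in the file names.
#' @param dir target / source directory.
#' @param sections section indices; defaults to `1:nz` for an array or the
#'   list names.
#' @return `write_masks` the directory, invisibly; `read_masks` a named list
#'   of logical matrices suitable for [interpolate_labels()].
#' @export
write_masks <- function(masks, organ, dir, sections = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.array(masks) && length(dim(masks)) == 3L) {
    if (is.null(sections)) sections <- seq_len(dim(masks)[1])
    masks <- lapply(seq_len(dim(masks)[1]), function(z)
      matrix(masks[z, , ], dim(masks)[2], dim(masks)[3]))
  } else if (is.list(masks)) {
    if (is.null(sections)) sections <- as.integer(names(masks))
  } else stop("masks must be a 3D logical array or list of matrices")
  for (k in seq_along(masks)) {
    png::writePNG(masks[[k]] * 1,
                  file.path(dir, sprintf("%s_s%04d.png", organ, sections[k])))
  }
  invisible(dir)
}

#' @rdname write_masks
#' @export
read_masks <- function(organ, dir) {
  patt <- sprintf("^%s_s(\\d{4})\\.png$", organ)
  files <- list.files(dir, pattern = patt)
  if (length(files) == 0L) stop("no masks for organ '", organ, "' in ", dir)
  z <- as.integer(sub(patt, "\\1", files))
  out <- lapply(files, function(f) png::readPNG(file.path(dir, f)) > 0.5)
  names(out) <- z
  out[order(z)]
}

#' Write a morphometry report
#'
#' Emits the organ statistics table (organ, volume, volume/weight,
#' volume/brain) as CSV, with provenance fields as a JSON sidecar.
#'
#' @param stats data.frame from [normalize_stats()].
#' @param path CSV output path; a `.json` sidecar is written next to it.
#' @param provenance named list recorded alongside (mask ids, thresholds,
#'   animal metadata); optional.
#' @return `path`, invisibly.
#' @export
write_report <- function(stats, path, provenance = list()) {
  utils::write.csv(stats, path, row.names = FALSE)
  if (length(provenance)) {
    jsonlite::write_json(provenance, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
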