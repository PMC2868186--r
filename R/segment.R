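#' Detector-threshold initial segmentation
#'
#' Semiautomatic organ delineation starts from an automatic pass: a colour
#' feature detector is thresholded by the step opacity transfer function,
#' embedding-compound (OCT) background voxels are removed, and connected
#' components smaller than `min_component_voxels` are discarded (26-connected
#' in 3D by default). The result is a binary mask that can then be corrected
#' manually section by section.
#'
#' @param volume 8-bit RGB image (y, x, 3) or volume (z, y, x, 3).
#' @param detector one of `"red"`, `"green"`, `"blue"`, `"brown"`,
#'   `"balanced"`.
#' @param T detector threshold in `[0, 1]` (strict: voxels with f > T are
#'   kept).
#' @param min_component_voxels discard connected components smaller than
#'   this (default 1, i.e. keep all).
#' @param connectivity 6, 18 or 26 (3D); a 2D image uses the in-plane subset
#'   (8-connectivity for 18 or 26).
#' @param exclude_background remove OCT voxels first (default TRUE).
#' @param T_chroma,T_bright background thresholds, see
#'   [classify_background()].
#' @return logical mask, same spatial shape as `volume`.
#' @export
threshold_segment <- function(volume, detector, T,
                              min_component_voxels = 1L,
                              connectivity = 26L,
                              exclude_background = TRUE,
                              T_chroma = 0.06, T_bright = 200) {
  f <- feature_detect(volume, detector)
  mask <- step_otf(f, T) == 255L
  dim(mask) <- dim(f)
  if (exclude_background) {
    mask <- mask & !classify_background(volume, T_chroma, T_bright)
  }
  if (min_component_voxels > 1L && any(mask)) {
    m3 <- mask
    if (length(dim(m3)) == 2L) dim(m3) <- c(1L, dim(m3))
    lab <- .cc_label_3d(as.logical(m3), dim(m3), as.integer(connectivity))
    sizes <- tabulate(lab, nbins = attr(lab, "n_components"))
    keep <- which(sizes >= min_component_voxels)
    m3 <- array(lab %in% keep, dim = dim(m3))
    dim(m3) <- dim(mask)
    mask <- m3
  }
  mask
}

#' Label connected components of a binary voxel mask
#'
#' @param mask logical array, 2D (y, x) or 3D (z, y, x).
#' @param connectivity 6, 18 or 26.
#' @return integer array of component labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  mask <- check_binary_mask(mask)
  d <- dim(mask)
  m3 <- mask
  if (length(d) == 2L) dim(m3) <- c(1L, d)
  lab <- .cc_label_3d(as.logical(m3), dim(m3), as.integer(connectivity))
  n <- attr(lab, "n_components")
  dim(lab) <- d
  structure(lab, n_components = n)
}

#' Signed Euclidean distance field of a 2D mask
#'
#' Positive inside the mask, negative outside; exact Euclidean distances
#' (in pixels) to the opposite phase. An all-TRUE mask gives +Inf everywhere,
#' an all-FALSE mask -Inf.
#'
#' @param mask logical matrix.
#' @return numeric matrix of signed distances.
#' @export
signed_distance <- function(mask) {
  mask <- check_binary_mask(mask)
  if (!is.matrix(mask)) stop("mask must be a 2D matrix")
  sqrt(.edt_sq_2d(!mask)) - sqrt(.edt_sq_2d(mask))
}

#' Interpolate sparse per-section organ masks across a section range
#'
#' Manual delineation is carried out only in selected sections; the mask on
#' every intermediate section is reconstructed by shape interpolation:
#' between each consecutive pair of labelled sections the two signed
#' Euclidean distance fields are blended linearly in z and the intermediate
#' mask is the positive superlevel set of the blend. Labelled sections are
#' reproduced bit-exactly; sections outside the labelled bracket copy the
#' nearest labelled mask. `method = "nearest"` copies the nearest labelled
#' section throughout instead.
#'
#' @param sparse named list of logical matrices; names are the (integer)
#'   section indices that were labelled.
#' @param sections integer vector of target section indices (typically a
#'   contiguous range).
#' @param method `"distance"` (default) or `"nearest"`.
#' @return logical array of dimension (length(sections), ny, nx).
#' @export
interpolate_labels <- function(sparse, sections,
                               method = c("distance", "nearest")) {
  method <- match.arg(method)
  if (length(sparse) == 0L) stop("no labelled sections supplied")
  zs <- as.integer(names(sparse))
  if (anyNA(zs)) stop("sparse mask names must be integer section indices")
  ord <- order(zs)
  zs <- zs[ord]
  masks <- lapply(sparse[ord], check_binary_mask)
  d2 <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), d2), logical(1)))) {
    stop("all labelled masks must have the same in-plane shape")
  }
  sdf <- NULL
  if (method == "distance" && length(masks) > 1L) {
    sdf <- lapply(masks, signed_distance)
  }
  out <- array(FALSE, dim = c(length(sections), d2))
  for (i in seq_along(sections)) {
    z <- sections[i]
    k <- match(z, zs)
    if (!is.na(k)) {                       # labelled: copy bit-exactly
      out[i, , ] <- masks[[k]]
    } else if (z < zs[1]) {
      out[i, , ] <- masks[[1]]
    } else if (z > zs[length(zs)]) {
      out[i, , ] <- masks[[length(masks)]]
    } else {
      hi <- which(zs > z)[1]
      lo <- hi - 1L
      if (method == "nearest") {
        k <- if (z - zs[lo] <= zs[hi] - z) lo else hi
        out[i, , ] <- masks[[k]]
      } else {
        t <- (z - zs[lo]) / (zs[hi] - zs[lo])
        s <- (1 - t) * sdf[[lo]] + t * sdf[[hi]]
        m <- s > 0
        m[is.na(m)] <- FALSE   # blend of +Inf and -Inf: shape undefined
        out[i, , ] <- m
      }
    }
  }
  out
}

#' Exclude the blood pool from an organ mask
#'
#' Cardiac chambers and vessels freeze with blood in place; their voxels are
#' strongly red and are removed from the organ mask by the red ratio
#' detector, leaving the tissue-only mask used for cardiac tissue mass.
#'
#' @param organ_mask binary mask.
#' @param volume 8-bit RGB image/volume of the same spatial shape.
#' @param T_blood red-ratio threshold in `[0, 1]`; voxels with f_R > T_blood
#'   are excluded.
#' @return logical tissue mask.
#' @export
exclude_blood_pool <- function(organ_mask, volume, T_blood) {
  organ_mask <- check_binary_mask(organ_mask, "organ_mask")
  if (T_blood < 0 || T_blood > 1) stop("T_blood must be in [0, 1]")
  f <- ratio_feature(volume, "red")
  if (!identical(dim(organ_mask), dim(f))) {
    stop("organ_mask and volume have different spatial shapes")
  }
  organ_mask & !(f > T_blood)
}

#' Merge binary organ masks into a labelled volume
#'
#' Overlapping voxels go to the earlier mask in list order (first wins); the
#' number of overlap voxels reassigned this way is reported.
#'
#' @param masks list of binary masks of identical shape.
#' @param names character vector of organ names, one per mask, unique.
#' @param spacing_um voxel spacing (dz, dy, dx), um, carried in the result.
#' @return an object of class `label_volume`: list with integer `labels`
#'   (0 = unlabelled), `name_table` (id -> name), `spacing_um`,
#'   `overlap_voxels`.
#' @export
merge_labels <- function(masks, names, spacing_um = c(40, 15.6, 15.6)) {
  if (length(masks) != length(names)) stop("one name per mask required")
  if (anyDuplicated(names)) stop("duplicate organ names")
  if (length(masks) == 0L) {
    return(structure(list(labels = array(0L, dim = c(0L, 0L, 0L)),
                          name_table = character(0),
                          spacing_um = spacing_um, overlap_voxels = 0L),
                     class = "label_volume"))
  }
  masks <- lapply(masks, check_binary_mask)
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), logical(1)))) {
    stop("all masks must have the same shape")
  }
  labels <- array(0L, dim = d)
  overlap <- 0L
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    overlap <- overlap + sum(m & labels != 0L)
    labels[m & labels == 0L] <- i
  }
  if (overlap > 0L) {
    message(overlap, " overlap voxel(s) assigned to the earlier mask")
  }
  structure(list(labels = labels,
                 name_table = stats::setNames(names, seq_along(names)),
                 spacing_um = spacing_um,
                 overlap_voxels = as.integer(overlap)),
            class = "label_volume")
}
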