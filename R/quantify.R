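#' Voxel-count volumetry
#'
#' Volume of a segmented region: whole-voxel count times the physical voxel
#' volume (in-plane pixel area times section thickness), reported in mm^3.
#'
#' @param mask binary mask (any dimensionality).
#' @param spacing_um voxel spacing (dz, dy, dx) in um.
#' @return volume in mm^3.
#' @examples
#' m <- array(FALSE, dim = c(1, 1, 1)); m[1] <- TRUE
#' region_volume(m, c(40, 15.6, 15.6))   # 9.7344e-06 mm^3
#' @export
region_volume <- function(mask, spacing_um) {
  mask <- check_binary_mask(mask)
  if (length(spacing_um) != 3L || any(spacing_um <= 0)) {
    stop("spacing_um must be three positive values (dz, dy, dx)")
  }
  sum(mask) * prod(spacing_um) / 1e9
}

#' Normalize organ volumes by body weight and brain volume
#'
#' Absolute organ volumes vary with animal size; volume per gram of gross
#' body weight reduces size variability, and volume relative to brain volume
#' reduces variability due to lean body mass. The brain's own volume/brain
#' ratio is 1 by construction.
#'
#' @param volumes named numeric vector of organ volumes in mm^3.
#' @param weight_g gross animal weight, g.
#' @param brain_volume_mm3 brain volume, mm^3; if `NULL`, taken from
#'   `volumes[["brain"]]` (case-insensitive), and an error is raised if
#'   absent.
#' @return data.frame with columns `organ`, `volume_mm3`,
#'   `volume_per_weight` (mm^3/g) and `volume_per_brain` (dimensionless),
#'   unrounded.
#' @examples
#' normalize_stats(c(brain = 579.65, heart = 351.52), weight_g = 25.8)
#' @export
normalize_stats <- function(volumes, weight_g, brain_volume_mm3 = NULL) {
  if (!is.numeric(volumes) || is.null(names(volumes)) ||
      any(!nzchar(names(volumes)))) {
    stop("volumes must be a named numeric vector (organ -> mm^3)")
  }
  if (any(volumes < 0)) stop("volumes must be nonnegative")
  if (!is.numeric(weight_g) || weight_g <= 0) stop("weight_g must be > 0")
  if (is.null(brain_volume_mm3)) {
    k <- match("brain", tolower(names(volumes)))
    if (is.na(k)) {
      stop("brain volume required for brain normalization: supply ",
           "brain_volume_mm3 or include a 'brain' entry")
    }
    brain_volume_mm3 <- volumes[[k]]
  }
  if (brain_volume_mm3 <= 0) stop("brain_volume_mm3 must be > 0")
  data.frame(organ = names(volumes),
             volume_mm3 = as.numeric(volumes),
             volume_per_weight = as.numeric(volumes) / weight_g,
             volume_per_brain = as.numeric(volumes) / brain_volume_mm3,
             row.names = NULL)
}

#' Percent difference between two measurements
#'
#' Two conventions used when comparing animals: `"higher"` reports how much
#' larger `a` is than the reference `b`, `(a/b - 1) * 100`; `"thinner"`
#' reports how much smaller, `(b - a)/b * 100`. The returned value is
#' rounded half-up to `digits`; the unrounded value is kept in attribute
#' `unrounded`. The two modes are complementary:
#' `thinner(a, b) = 100 * (1 - a/b)`.
#'
#' @param a measurement being compared.
#' @param b reference measurement, > 0.
#' @param mode `"higher"` or `"thinner"`.
#' @param digits decimals of the reported value (default 0, whole percent).
#' @return rounded percent with attribute `unrounded`.
#' @examples
#' percent_difference(13.625, 9.706, "higher")   # 40 (40.38 unrounded)
#' percent_difference(84, 502, "thinner")        # 83 (83.27 unrounded)
#' @export
percent_difference <- function(a, b, mode = c("higher", "thinner"),
                               digits = 0) {
  mode <- match.arg(mode)
  if (!is.numeric(b) || b <= 0) stop("reference b must be > 0")
  v <- if (mode == "higher") (a / b - 1) * 100 else (b - a) / b * 100
  structure(round_half_up(v, digits), unrounded = v)
}

#' Fractional vascularization of an adipose depot
#'
#' Percentage of the adipose analysis region (including its vessels)
#' classified as vasculature.
#'
#' @param adipose_mask binary mask of the adipose tissue.
#' @param vessel_mask binary mask of the vessel voxels, same shape.
#' @return percent vascularized.
#' @export
fraction_vascularized <- function(adipose_mask, vessel_mask) {
  adipose_mask <- check_binary_mask(adipose_mask, "adipose_mask")
  vessel_mask <- check_binary_mask(vessel_mask, "vessel_mask")
  if (!identical(dim(adipose_mask), dim(vessel_mask))) {
    stop("masks must have the same shape")
  }
  region <- adipose_mask | vessel_mask
  n <- sum(region)
  if (n == 0L) stop("empty adipose region")
  100 * sum(vessel_mask & region) / n
}

#' Layer thicknesses along a sampling ray
#'
#' Skin-layer (epidermis / dermis / hypodermis) and peritoneum thicknesses
#' are measured on a reformatted section by casting a ray across the layers:
#' the thickness of each layer is its run length along the ray times the
#' pixel size, corrected for the ray direction (a ray at 45 degrees crosses
#' sqrt(2) times more tissue per pixel step). Layer identity along the ray is
#' supplied as a per-pixel label image (from manual tracing or a detector
#' classification); rays are user-chosen, as the measurements are made
#' interactively.
#'
#' @param label_image integer matrix of per-pixel layer labels (0 = outside
#'   any layer).
#' @param start ray start (y, x), 1-based pixel coordinates.
#' @param direction ray direction (dy, dx); need not be normalized.
#' @param layers named integer vector mapping layer name -> label id, in the
#'   order the ray should meet them; every requested layer must occur on the
#'   ray.
#' @param pixel_size_um in-plane pixel size, um.
#' @return object of class `skin_profile`: data.frame with columns `layer`,
#'   `pixels` (run length), `thickness_um`.
#' @export
layer_thickness <- function(label_image, start, direction, layers,
                            pixel_size_um = 15.6) {
  if (!is.matrix(label_image)) stop("label_image must be a matrix")
  if (length(start) != 2L || length(direction) != 2L) {
    stop("start and direction must be (y, x) pairs")
  }
  if (all(direction == 0)) stop("direction must be nonzero")
  u <- direction / max(abs(direction))   # unit pixel step along major axis
  step_um <- pixel_size_um * sqrt(sum(u^2))
  d <- dim(label_image)
  p <- as.numeric(start)
  lab <- integer(0)
  repeat {
    ij <- round_half_up(p)
    if (ij[1] < 1 || ij[1] > d[1] || ij[2] < 1 || ij[2] > d[2]) break
    lab <- c(lab, label_image[ij[1], ij[2]])
    p <- p + u
  }
  out <- data.frame(layer = names(layers),
                    pixels = NA_integer_, thickness_um = NA_real_)
  r <- rle(lab)
  for (i in seq_along(layers)) {
    runs <- which(r$values == layers[[i]])
    if (length(runs) == 0L) {
      stop("layer '", names(layers)[i], "' not crossed by the ray")
    }
    px <- r$lengths[runs[1]]   # first crossing
    out$pixels[i] <- px
    out$thickness_um[i] <- px * step_um
  }
  class(out) <- c("skin_profile", class(out))
  out
}
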