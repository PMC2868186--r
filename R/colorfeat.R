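#' Colour-ratio feature detectors and the step opacity transfer function
#'
#' Block-face cryo-imaging records tissue in true colour, and tissue classes
#' separate well on simple functions of the RGB triple: the channel ratio
#' detectors select strongly red (liver, lung, vasculature), green, or blue
#' regions; the brown detector targets tissue whose colour mixes one part red
#' with two parts green and no blue (intestine, brown fat); and the balanced
#' detector scores chromaticity, near zero for the achromatic white embedding
#' compound (OCT). Every detector maps each voxel to a scalar feature
#' f in `[0, 1]`, which a step opacity transfer function then binarizes for
#' rendering or segmentation.
#'
#' For an 8-bit voxel (R, G, B) with S = R + G + B:
#' \describe{
#'   \item{ratio}{f_C = C / S for the chosen channel C; f = 0 where S = 0.}
#'   \item{brown}{f_Br = 0.33 f_R + 0.67 f_G.}
#'   \item{balanced}{f = (|R-G| + |G-B| + |R-B|) / (3 * 255), which equals
#'     2 (max - min) / 765; range `[0, 2/3]`.}
#' }
#'
#' @param volume numeric array with a trailing RGB dimension, either an image
#'   `(y, x, 3)` or a volume `(z, y, x, 3)`, 8-bit values in 0..255.
#' @param channel which channel ratio to compute: `"red"`, `"green"` or
#'   `"blue"`.
#' @return a numeric array of per-voxel feature values (channel dimension
#'   dropped) with attribute `detector`.
#' @examples
#' v <- array(c(153, 51, 51), dim = c(1, 1, 3))
#' ratio_feature(v, "red")       # 0.6
#' balanced_feature(array(c(255, 255, 255), dim = c(1, 1, 3)))  # 0
#' @export
ratio_feature <- function(volume, channel = c("red", "green", "blue")) {
  channel <- match.arg(channel)
  volume <- check_rgb(volume)
  ci <- match(channel, c("red", "green", "blue"))
  s <- channel_of(volume, 1L) + channel_of(volume, 2L) + channel_of(volume, 3L)
  f <- channel_of(volume, ci)
  pos <- s > 0
  f[pos] <- f[pos] / s[pos]
  f[!pos] <- 0          # black voxels: no chromatic evidence, stay transparent
  structure(f, detector = channel)
}

#' @rdname ratio_feature
#' @export
brown_feature <- function(volume) {
  fr <- ratio_feature(volume, "red")
  fg <- ratio_feature(volume, "green")
  structure(0.33 * fr + 0.67 * fg, detector = "brown")
}

#' @rdname ratio_feature
#' @export
balanced_feature <- function(volume) {
  volume <- check_rgb(volume)
  r <- channel_of(volume, 1L)
  g <- channel_of(volume, 2L)
  b <- channel_of(volume, 3L)
  f <- (abs(r - g) + abs(g - b) + abs(r - b)) / (3 * 255)
  structure(f, detector = "balanced")
}

#' Compute a named feature detector
#'
#' Dispatcher over the detectors of [ratio_feature()], used by the
#' segmentation and rendering layers.
#'
#' @inheritParams ratio_feature
#' @param detector one of `"red"`, `"green"`, `"blue"`, `"brown"`,
#'   `"balanced"`.
#' @return per-voxel feature array, as for [ratio_feature()].
#' @export
feature_detect <- function(volume, detector) {
  switch(as.character(detector),
    red = , green = , blue = ratio_feature(volume, detector),
    brown = brown_feature(volume),
    balanced = balanced_feature(volume),
    stop("unknown detector: ", detector,
         " (expected red, green, blue, brown or balanced)")
  )
}

#' Step opacity transfer function
#'
#' Maps a feature map to binary per-voxel opacity: alpha = 255 where f > T
#' (strictly), 0 where f <= T. The threshold boundary is deliberately
#' exclusive, so a voxel exactly at T stays transparent.
#'
#' @param feature numeric array of feature values in `[0, 1]`.
#' @param T threshold in `[0, 1]`.
#' @return integer array of 0/255 opacities with attribute `threshold`.
#' @export
step_otf <- function(feature, T) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T < 0 || T > 1) {
    stop("T must be a single finite value in [0, 1]")
  }
  a <- ifelse(feature > T, 255L, 0L)
  dim(a) <- dim(feature)
  structure(a, threshold = T)
}

#' Classify embedding-compound (OCT) background voxels
#'
#' The embedding compound is a uniform bright white, so a voxel is classified
#' as background when it is both achromatic (balanced feature at most
#' `T_chroma`) and bright (mean of R, G, B at least `T_bright`). The
#' brightness conjunct keeps dark gray tissue, which is also near-achromatic,
#' out of the background class.
#'
#' @inheritParams ratio_feature
#' @param T_chroma chromaticity threshold on the balanced feature
#'   (default 0.06).
#' @param T_bright minimum mean intensity, 8-bit scale (default 200).
#' @return logical array, `TRUE` for background voxels.
#' @export
classify_background <- function(volume, T_chroma = 0.06, T_bright = 200) {
  volume <- check_rgb(volume)
  f <- balanced_feature(volume)
  m <- (channel_of(volume, 1L) + channel_of(volume, 2L) +
          channel_of(volume, 3L)) / 3
  out <- f <= T_chroma & m >= T_bright
  dim(out) <- dim(f)
  out
}
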