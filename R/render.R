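#' Orthographic true-colour volume rendering
#'
#' Minimal axis-aligned front-to-back compositing: each voxel contributes its
#' own (true) colour weighted by an opacity map, typically the binary output
#' of [step_otf()]. With normalized opacity a = alpha / 255, per ray:
#' `C_out = C_in + (1 - A_in) * a * C_voxel` and
#' `A_out = A_in + (1 - A_in) * a` (associated / premultiplied colour).
#' The ray stops once accumulated opacity exceeds `early_termination`, and
#' whatever transparency remains is filled with the background colour. With
#' a binary opacity map the result is a first-hit projection of the
#' thresholded structure.
#'
#' @param volume 8-bit RGB volume (z, y, x, 3).
#' @param alpha per-voxel opacity array (z, y, x), values in 0..255.
#' @param axis viewing axis: `"+z"`, `"-z"`, `"+y"`, `"-y"`, `"+x"`, `"-x"`;
#'   the sign sets which face the rays enter first.
#' @param background colour behind the volume (default black, which makes
#'   empty rays black as in OCT-removed renderings).
#' @param early_termination accumulated-opacity cutoff (default 0.999).
#' @return 8-bit RGB image.
#' @export
render_orthographic <- function(volume, alpha, axis = "+z",
                                background = c(0, 0, 0),
                                early_termination = 0.999) {
  volume <- check_rgb(volume)
  if (!identical(dim(volume)[1:3], dim(alpha))) {
    stop("volume and alpha must have the same spatial shape")
  }
  if (any(alpha < 0 | alpha > 255)) stop("alpha values must be in 0..255")
  ax <- match.arg(axis, c("+z", "-z", "+y", "-y", "+x", "-x"))
  axid <- match(substr(ax, 2, 2), c("z", "y", "x"))
  forward <- substr(ax, 1, 1) == "+"

  # rotate so the traversal axis is first: (t, r, c, channel)
  perm <- switch(axid, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  vol <- aperm(volume, c(perm, 4L))
  al <- aperm(alpha, perm)
  nt <- dim(al)[1]
  ord <- if (forward) seq_len(nt) else rev(seq_len(nt))

  d2 <- dim(al)[2:3]
  C <- array(0, dim = c(d2, 3L))
  A <- matrix(0, d2[1], d2[2])
  for (t in ord) {
    live <- A < early_termination
    if (!any(live)) break
    a <- matrix(al[t, , ], d2[1], d2[2]) / 255
    w <- (1 - A) * a
    w[!live] <- 0
    for (c in 1:3) {
      C[, , c] <- C[, , c] + w * matrix(vol[t, , , c], d2[1], d2[2])
    }
    A <- A + w
  }
  for (c in 1:3) C[, , c] <- C[, , c] + (1 - A) * background[c]
  clip8(C)
}
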