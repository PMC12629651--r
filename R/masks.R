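# Binary-mask geometry helpers shared by the phantom generator and the
# measurement core. Convention: masks are logical matrices indexed
# [row, col], origin top-left; pixel (r, c) has its center at coordinates
# (r, c) in pixel units.

#' Rasterize an ellipse into a binary mask
#'
#' Pixel centers inside the (optionally rotated) ellipse are set `TRUE`.
#' The ellipse axis direction is measured from the row (vertical) axis, so
#' `angle_deg = 0` puts the `a` semi-axis along image rows.
#'
#' @param nrow,ncol mask grid dimensions in pixels.
#' @param center numeric `(row, col)` center in pixel units.
#' @param semi_axes numeric `(a, b)`: semi-axis along the axis direction
#'   and perpendicular to it, in pixels.
#' @param angle_deg rotation of the `a` axis from the row axis, degrees.
#' @return logical `nrow x ncol` matrix.
#' @export
rasterize_ellipse <- function(nrow, ncol, center, semi_axes, angle_deg = 0) {
  th <- angle_deg * pi / 180
  dr <- matrix(seq_len(nrow) - center[1], nrow, ncol)
  dc <- matrix(seq_len(ncol) - center[2], nrow, ncol, byrow = TRUE)
  u <- cos(th) * dr + sin(th) * dc      # along long axis
  v <- -sin(th) * dr + cos(th) * dc     # perpendicular
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2 <= 1
}

# Ellipse with a shrunken angular sector: pixels whose polar angle (in the
# ellipse's normalized frame) falls inside a sector of fractional width
# `frac` must additionally lie inside the ellipse scaled by `scale`.
# This emulates a second segmenter that loses part of the boundary, giving
# a controllable Dice disagreement against the unperturbed mask.
rasterize_ellipse_degraded <- function(nrow, ncol, center, semi_axes,
                                       angle_deg = 0, frac = 0, phase = 0,
                                       scale = 0.7) {
  base <- rasterize_ellipse(nrow, ncol, center, semi_axes, angle_deg)
  if (frac <= 0) return(base)
  th <- angle_deg * pi / 180
  dr <- matrix(seq_len(nrow) - center[1], nrow, ncol)
  dc <- matrix(seq_len(ncol) - center[2], nrow, ncol, byrow = TRUE)
  u <- cos(th) * dr + sin(th) * dc
  v <- -sin(th) * dr + cos(th) * dc
  ang <- atan2(v / semi_axes[2], u / semi_axes[1])        # (-pi, pi]
  rel <- (ang - phase) %% (2 * pi)
  in_sector <- rel < frac * 2 * pi
  shrunk <- (u / (scale * semi_axes[1]))^2 + (v / (scale * semi_axes[2]))^2 <= 1
  base & (!in_sector | shrunk)
}

#' Physical mask area
#'
#' @param mask logical matrix.
#' @param pixel_spacing mm/px (isotropic).
#' @return area in mm^2.
#' @export
mask_area <- function(mask, pixel_spacing) {
  sum(mask) * pixel_spacing^2
}

# Row-major run-length encoding of a logical matrix, starting with the run
# of FALSE. Used for the "rle" manifest mask encoding.
rle_encode_mask <- function(mask) {
  v <- as.integer(t(mask))  # row-major flatten
  r <- rle(v)
  lens <- r$lengths
  if (length(r$values) && r$values[1] == 1L) lens <- c(0L, lens)
  list(nrow = nrow(mask), ncol = ncol(mask), runs = as.integer(lens))
}

rle_decode_mask <- function(enc) {
  runs <- as.integer(enc$runs)
  vals <- rep_len(c(0L, 1L), length(runs))
  v <- inverse.rle(list(lengths = runs, values = vals))
  if (length(v) != enc$nrow * enc$ncol)
    ep_stop("run-length mask does not match stated dimensions", "masks")
  matrix(as.logical(v), nrow = enc$nrow, ncol = enc$ncol, byrow = TRUE)
}
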