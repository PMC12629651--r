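# Geometric and arithmetic measurement core: dual-segmentation Dice QC,
# long-axis extraction from binary masks, biplane Simpson method-of-disks
# volumes, ejection fraction, body surface area and LA volume index.

#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks are defined to agree
#' perfectly (Dice 1).
#'
#' @param mask_a,mask_b logical matrices of identical dimensions.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    ep_stop("masks have different dimensions", "mask_b")
  sa <- sum(mask_a); sb <- sum(mask_b)
  if (sa + sb == 0) return(1)
  2 * sum(mask_a & mask_b) / (sa + sb)
}

#' Dual-segmentation quality gate
#'
#' Agreement between two independently produced segmentations of the same
#' frame is a strong indicator of robust segmentation; frames whose Dice
#' falls below the threshold (default 0.8, inclusive) are rejected.
#'
#' @param primary,secondary logical mask matrices.
#' @param threshold inclusion threshold on the Dice score.
#' @return `list(pass = logical, dice = numeric)`.
#' @export
segmentation_qc <- function(primary, secondary, threshold = 0.8) {
  d <- dice(primary, secondary)
  list(pass = d >= threshold, dice = d)
}

# Projected pixel coordinates of a mask onto an axis frame.
# Returns list(t, s, centroid, dir): t along `dir`, s perpendicular,
# both in pixels relative to the centroid.
mask_axis_coords <- function(mask, dir = NULL) {
  px <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(px)
  d <- sweep(px, 2, ctr)
  if (is.null(dir)) {
    cv <- crossprod(d) / nrow(d)
    eg <- eigen(cv, symmetric = TRUE)
    dir <- eg$vectors[, 1]
    if (dir[1] < 0) dir <- -dir  # canonical orientation (towards larger rows)
  }
  list(t = d %*% dir, s = d %*% c(-dir[2], dir[1]), centroid = ctr, dir = dir)
}

#' Extract the long axis of a chamber mask
#'
#' The principal axis of the mask (second-order moments) defines the axis
#' direction; the axis endpoints are where the principal line leaves the
#' mask. The base end is the endpoint with the larger local width
#' (perpendicular extent averaged over the 10% of the axis nearest that
#' end); the other endpoint is the apex. Disconnected or tiny masks
#' (< `min_pixels`) yield an invalid-segmentation exclusion signal rather
#' than an error.
#'
#' @param mask logical matrix, a single connected chamber segmentation.
#' @param pixel_spacing mm/px.
#' @param min_pixels minimum mask size, pixels (default 50).
#' @return object of class `long_axis` (`apex_point`, `base_midpoint` as
#'   `(row, col)`, `length` in mm, `dir` unit vector apex-to-base) or an
#'   exclusion signal (`reason = "invalid_segmentation"`).
#' @export
extract_long_axis <- function(mask, pixel_spacing, min_pixels = 50L) {
  npix <- sum(mask)
  if (npix < min_pixels)
    return(ep_signal("invalid_segmentation",
                     sprintf("mask has %d px (< %d)", npix, min_pixels)))
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) > 1L)
    return(ep_signal("invalid_segmentation",
                     sprintf("mask has %d connected components", max(lab))))
  ax <- mask_axis_coords(mask)
  tmin <- min(ax$t); tmax <- max(ax$t)
  L <- tmax - tmin
  near <- 0.1 * L
  width_at <- function(end_t, sgn) {
    sel <- abs(ax$t - end_t) <= near
    if (!any(sel)) return(0)
    diff(range(ax$s[sel])) + 1
  }
  w_lo <- width_at(tmin); w_hi <- width_at(tmax)
  # base = wider end; tie broken towards the image-lower end (larger t,
  # since dir is canonically oriented towards increasing rows)
  base_at_max <- w_hi >= w_lo
  dir_ab <- if (base_at_max) ax$dir else -ax$dir  # apex -> base
  t_apex <- if (base_at_max) tmin else tmax
  t_base <- if (base_at_max) tmax else tmin
  apex <- ax$centroid + t_apex * ax$dir
  base <- ax$centroid + t_base * ax$dir
  structure(list(
    apex_point = unname(apex), base_midpoint = unname(base),
    length = (L + 1) * pixel_spacing,  # +1 px: pixel extent, not center span
    dir = unname(dir_ab), centroid = unname(ax$centroid),
    length_px = L + 1
  ), class = "long_axis")
}

#' Per-disc diameters along the long axis
#'
#' The long axis is divided into `n_discs` equal slabs from apex to base;
#' the diameter of disc *i* is the full perpendicular extent (maximum
#' chord) of the mask at the slab center, in mm. The extent is measured
#' per one-pixel layer along the axis and linearly interpolated at the
#' slab center, which avoids the outward bias of taking the widest chord
#' anywhere inside a slab. Slabs beyond the mask get diameter 0.
#'
#' @param mask logical matrix.
#' @param axis a `long_axis` from [extract_long_axis()].
#' @param pixel_spacing mm/px.
#' @param n_discs number of disks (default 20).
#' @return numeric vector of length `n_discs`, apex first.
#' @export
disc_diameters <- function(mask, axis, pixel_spacing, n_discs = 20L) {
  px <- which(mask, arr.ind = TRUE)
  d <- sweep(px, 2, axis$apex_point)
  # apex-to-base coordinate anchored at the axis' apex-side pixel edge
  t <- d %*% axis$dir + 0.5
  ax <- list(s = d %*% c(-axis$dir[2], axis$dir[1]))
  Lpx <- axis$length_px
  layer <- floor(as.vector(t))  # 1-px bins [k, k+1) along the axis
  ext <- vapply(split(as.vector(ax$s), layer),
                function(s) diff(range(s)) + 1, numeric(1))
  t_layer <- vapply(split(as.vector(t), layer), mean, numeric(1))
  centers <- (seq_len(n_discs) - 0.5) * Lpx / n_discs
  out <- numeric(n_discs)
  # nearest-layer chord beyond the outermost layer centers (rule = 2);
  # zero for slabs beyond the mask's own axial extent
  span <- centers >= min(t) - 0.5 & centers <= max(t) + 0.5
  if (any(span) && length(t_layer) >= 2) {
    out[span] <- stats::approx(t_layer, ext, xout = centers[span],
                               rule = 2, ties = mean)$y
  } else if (any(span)) {
    out[span] <- ext[1]
  }
  out * pixel_spacing
}

#' Biplane Simpson (method of disks) volume
#'
#' Chamber volume from two orthogonal long-axis views:
#' `V = (pi/4) * (L/n) * sum(a_i * b_i)`, with `a_i`, `b_i` the disc
#' diameters from the two views and `L` the longer of the two long-axis
#' lengths. A view length discrepancy above 20% sets a foreshortening
#' warning flag on the result without rejecting it.
#'
#' @param mask_v1,mask_v2 logical masks from the two views.
#' @param spacing_v1,spacing_v2 pixel spacings, mm/px.
#' @param n_discs number of disks (default 20).
#' @return object of class `biplane_volume` (`volume` in mL, `length` mm,
#'   `diameters_a`, `diameters_b`, `n_discs`, `foreshortening_warning`) or
#'   an invalid-segmentation exclusion signal.
#' @export
biplane_simpson <- function(mask_v1, mask_v2, spacing_v1, spacing_v2,
                            n_discs = 20L) {
  ax1 <- extract_long_axis(mask_v1, spacing_v1)
  if (is_exclusion(ax1)) return(ax1)
  ax2 <- extract_long_axis(mask_v2, spacing_v2)
  if (is_exclusion(ax2)) return(ax2)
  da <- disc_diameters(mask_v1, ax1, spacing_v1, n_discs)
  db <- disc_diameters(mask_v2, ax2, spacing_v2, n_discs)
  L <- max(ax1$length, ax2$length)
  warn <- abs(ax1$length - ax2$length) / L > 0.2
  vol_ml <- pi / 4 * L / n_discs * sum(da * db) / 1000
  structure(list(
    n_discs = as.integer(n_discs), diameters_a = da, diameters_b = db,
    length = L, volume = vol_ml, foreshortening_warning = warn
  ), class = "biplane_volume")
}

#' Ejection fraction
#'
#' `EF = (EDV - ESV) / EDV * 100`, in percent.
#'
#' @param edv end-diastolic volume, mL (> 0).
#' @param esv end-systolic volume, mL.
#' @return EF in percent.
#' @export
ejection_fraction <- function(edv, esv) {
  if (!is.numeric(edv) || edv <= 0) ep_stop("edv must be positive", "edv")
  (edv - esv) / edv * 100
}

#' Body surface area (Mosteller)
#'
#' `BSA = sqrt(weight_kg * height_cm) / 60`, m^2 — the standard echo-lab
#' convention. The DuBois formula
#' `0.007184 * weight^0.425 * height^0.725` is available as an
#' alternative.
#'
#' @param weight kg (> 0).
#' @param height cm (> 0).
#' @param formula `"mosteller"` (default) or `"dubois"`.
#' @return BSA in m^2.
#' @export
body_surface_area <- function(weight, height,
                              formula = c("mosteller", "dubois")) {
  formula <- match.arg(formula)
  if (!is.numeric(weight) || weight <= 0) ep_stop("weight must be positive", "weight")
  if (!is.numeric(height) || height <= 0) ep_stop("height must be positive", "height")
  switch(formula,
         mosteller = sqrt(weight * height) / 60,
         dubois = 0.007184 * weight^0.425 * height^0.725)
}

#' Left atrial volume index
#'
#' `LAVI = LAESV / BSA`, mL/m^2.
#'
#' @param la_esv LA end-systolic volume, mL.
#' @param bsa body surface area, m^2 (> 0).
#' @return LAVI in mL/m^2.
#' @export
lavi <- function(la_esv, bsa) {
  if (!is.numeric(bsa) || bsa <= 0) ep_stop("bsa must be positive", "bsa")
  la_esv / bsa
}
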