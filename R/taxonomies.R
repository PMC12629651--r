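#' Label taxonomies
#'
#' The pipeline organizes exams using two fixed taxonomies: eight imaging
#' modalities (2D/3D B-mode, colour flow, M-mode, pulsed/continuous-wave
#' Doppler, contrast, tissue Doppler) and an extended B-mode view set
#' covering parasternal, apical (including LV-focused zoom variants),
#' subcostal and transoesophageal views plus an unknown class. Classifier
#' backends must emit probability vectors over exactly these label sets.
#'
#' @name taxonomies
NULL

#' @rdname taxonomies
#' @export
echo_modalities <- function() {
  c("B2D", "B3D", "color_flow", "m_mode", "pw_doppler", "cw_doppler",
    "contrast", "tissue_doppler")
}

#' @rdname taxonomies
#' @export
echo_views <- function() {
  c("PLAX", "PLAX_focused", "PSAX", "A4C", "A4C_LV_focused", "A2C",
    "A2C_LV_focused", "ALAX", "A5C", "SC4C", "SCVC", "TEE", "unknown")
}

#' @rdname taxonomies
#' @export
exclusion_reasons <- function() {
  c("none", "no_bmode", "missing_A4C", "missing_A2C", "low_view_confidence",
    "missing_A2C_for_LA", "timing_unavailable", "invalid_segmentation",
    "low_dice", "other")
}

check_enum <- function(x, allowed, field, where = NULL) {
  if (!is.character(x) || length(x) != 1L || !(x %in% allowed))
    ep_stop(sprintf("value '%s' not one of {%s}",
                    paste(as.character(x), collapse = ","),
                    paste(allowed, collapse = ", ")),
            field, where)
  invisible(x)
}
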