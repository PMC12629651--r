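# Pluggable learned-component backends.
#
# The trained networks of a production deployment (modality classifier,
# view classifier, cardiac event detector) are injected behind small
# contracts so the pipeline logic is testable without them. Shipped
# backends: "oracle" (reads the ground-truth block a synthetic recording
# carries), "noisy" (seeded label flips / confidence jitter around the
# truth), and for timing additionally "none" (always fails, exercising the
# ECG fallback).

#' Construct a classifier backend
#'
#' A classifier backend is a list with a `taxonomy` (character vector of
#' labels) and a `classify(recording)` function returning
#' `list(label =, probs =)` where `probs` is a probability vector over the
#' taxonomy (non-negative, summing to 1 within 1e-6).
#'
#' @param kind `"modality"` or `"view"`.
#' @param name `"oracle"` or `"noisy"`.
#' @param flip_prob for `"noisy"`: probability of flipping the true label
#'   to a uniformly drawn other label.
#' @param confidence_sd for `"noisy"`: s.d. of Gaussian jitter applied to
#'   the winning probability (clamped to \[0.5, 1\]).
#' @param seed integer seed driving the noisy backend's randomness.
#' @return a classifier backend.
#' @export
classifier_backend <- function(kind = c("modality", "view"),
                               name = c("oracle", "noisy"),
                               flip_prob = 0.05, confidence_sd = 0.02,
                               seed = 1L) {
  kind <- match.arg(kind); name <- match.arg(name)
  taxonomy <- if (kind == "modality") echo_modalities() else echo_views()
  truth_of <- function(recording) {
    lbl <- recording$truth[[kind]] %||% recording[[kind]]
    if (is.null(lbl) || !(lbl %in% taxonomy)) "unknown" else lbl
  }
  if (name == "oracle") {
    classify <- function(recording) {
      lbl <- truth_of(recording)
      probs <- stats::setNames(rep(0, length(taxonomy)), taxonomy)
      if (lbl %in% taxonomy) probs[lbl] <- 1 else probs[] <- 1 / length(probs)
      # synthetic data may carry an injected confidence for the true label
      ov <- recording$truth$confidence_override
      if (!is.null(ov) && lbl %in% taxonomy) {
        probs[] <- (1 - ov) / (length(probs) - 1)
        probs[lbl] <- ov
      }
      list(label = names(probs)[which.max(probs)], probs = probs)
    }
  } else {
    counter <- new.env(); counter$i <- 0L
    classify <- function(recording) {
      counter$i <- counter$i + 1L
      with_local_seed(seed + counter$i, {
        lbl <- truth_of(recording)
        if (stats::runif(1) < flip_prob && lbl %in% taxonomy)
          lbl <- sample(setdiff(taxonomy, lbl), 1L)
        conf <- min(1, max(0.5, stats::rnorm(1, 0.95, confidence_sd)))
        probs <- stats::setNames(rep((1 - conf) / (length(taxonomy) - 1),
                                     length(taxonomy)), taxonomy)
        if (lbl %in% taxonomy) probs[lbl] <- conf
        list(label = lbl, probs = probs)
      })
    }
  }
  structure(list(kind = kind, name = name, taxonomy = taxonomy,
                 classify = classify),
            class = "classifier_backend")
}

#' Construct an event-detection (timing) backend
#'
#' A timing backend is a list with a `detect(recording)` function
#' returning a list of [cardiac_events()] (source `"network"`), or `NULL`
#' when the detector produces no valid output.
#'
#' The `"oracle"` backend reads the synthetic ground-truth event frames
#' (honouring an injected per-recording offset and availability flag, so
#' corrupted phantoms exercise the reconciliation and fallback paths);
#' `"none"` always fails; `"offset"` shifts the oracle output by
#' `offset_frames`.
#'
#' @param name `"oracle"`, `"none"` or `"offset"`.
#' @param offset_frames frame shift applied by the `"offset"` backend.
#' @return a timing backend.
#' @export
timing_backend <- function(name = c("oracle", "none", "offset"),
                           offset_frames = 0L) {
  name <- match.arg(name)
  detect <- switch(
    name,
    none = function(recording) NULL,
    oracle = function(recording) oracle_detect(recording, 0L),
    offset = function(recording) oracle_detect(recording, as.integer(offset_frames))
  )
  structure(list(name = name, detect = detect), class = "timing_backend")
}

oracle_detect <- function(recording, extra_offset) {
  tr <- recording$truth
  if (is.null(tr) || is.null(tr$ed_frames) || is.null(tr$es_frames)) return(NULL)
  if (isFALSE(tr$timing_available)) return(NULL)
  off <- (tr$timing_offset_frames %||% 0L) + extra_offset
  ev <- list()
  for (i in seq_along(tr$ed_frames)) {
    ed <- tr$ed_frames[i] + off; es <- tr$es_frames[i] + off
    if (ed >= 1 && es > ed && es <= recording$n_frames)
      ev[[length(ev) + 1L]] <- cardiac_events(ed, es, "network")
  }
  if (!length(ev)) NULL else ev
}

validate_probs <- function(probs, taxonomy, where) {
  if (!is.numeric(probs) || length(probs) != length(taxonomy))
    ep_stop("backend probabilities have wrong length", "probs", where,
            class = "echopipe_backend_contract_error")
  if (any(probs < -1e-9) || abs(sum(probs) - 1) > 1e-6)
    ep_stop(sprintf("backend probabilities invalid (sum %.6f)", sum(probs)),
            "probs", where, class = "echopipe_backend_contract_error")
  invisible(probs)
}
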