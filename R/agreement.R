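# Agreement analysis: Bland-Altman statistics, subgroup stratification,
# distribution summaries, and the stage-by-stage feasibility funnel.

#' Bland-Altman agreement statistics
#'
#' Differences are `auto - ref`; bias is their mean, `sd` the sample
#' standard deviation (n-1 denominator), and the limits of agreement are
#' `bias +/- loa_mult * sd` (default 1.96).
#'
#' @param auto,ref pairwise-matched numeric vectors, length >= 2.
#' @param loa_mult limits-of-agreement multiplier.
#' @return object of class `agreement_stats`: `n`, `bias`, `sd`,
#'   `loa_low`, `loa_high`.
#' @export
bland_altman <- function(auto, ref, loa_mult = 1.96) {
  if (length(auto) != length(ref))
    ep_stop("auto and ref must have equal length", "ref")
  keep <- is.finite(auto) & is.finite(ref)
  d <- auto[keep] - ref[keep]
  if (length(d) < 2) ep_stop("need at least 2 matched pairs", "auto")
  bias <- mean(d); s <- stats::sd(d)
  structure(list(n = length(d), bias = bias, sd = s,
                 loa_low = bias - loa_mult * s, loa_high = bias + loa_mult * s),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("n = %d, bias = %.3f (SD %.3f), LOA [%.3f, %.3f]\n",
              x$n, x$bias, x$sd, x$loa_low, x$loa_high))
  invisible(x)
}

#' Stratified Bland-Altman agreement
#'
#' Computes [bland_altman()] per subgroup. Factor/character strata give
#' one group per level; logical strata (disease flags) give a
#' "with"/"without" pair. Groups may overlap across strata, so group n's
#' can sum to more than the number of pairs. Subgroups with fewer than 2
#' pairs are reported with their n and `NA` statistics.
#'
#' @param auto,ref matched numeric vectors.
#' @param strata data.frame of per-pair labels (factor, character or
#'   logical columns), `nrow(strata) == length(auto)`.
#' @param loa_mult limits-of-agreement multiplier.
#' @return data.frame with columns `kind`, `value`, `n`, `bias`, `sd`,
#'   `loa_low`, `loa_high`.
#' @export
stratified_agreement <- function(auto, ref, strata, loa_mult = 1.96) {
  if (!is.data.frame(strata) || nrow(strata) != length(auto))
    ep_stop("strata must be a data.frame with one row per pair", "strata")
  rows <- list()
  add <- function(kind, value, idx) {
    if (sum(idx) >= 2) {
      st <- bland_altman(auto[idx], ref[idx], loa_mult)
      rows[[length(rows) + 1L]] <<- data.frame(
        kind = kind, value = value, n = st$n, bias = st$bias, sd = st$sd,
        loa_low = st$loa_low, loa_high = st$loa_high)
    } else {
      rows[[length(rows) + 1L]] <<- data.frame(
        kind = kind, value = value, n = sum(idx), bias = NA_real_,
        sd = NA_real_, loa_low = NA_real_, loa_high = NA_real_)
    }
  }
  for (col in names(strata)) {
    v <- strata[[col]]
    if (is.logical(v)) {
      add(col, "with", !is.na(v) & v)
      add(col, "without", !is.na(v) & !v)
    } else {
      for (lev in sort(unique(as.character(v[!is.na(v)]))))
        add(col, lev, !is.na(v) & as.character(v) == lev)
    }
  }
  do.call(rbind, rows)
}

# Canonical funnel stages and the exclusion reasons they absorb.
funnel_stages <- function() {
  list(
    bmode_present      = c("no_bmode", "other"),
    views_present      = c("missing_A4C", "missing_A2C"),
    confidence_gate    = "low_view_confidence",
    timing_available   = "timing_unavailable",
    segmentation_valid = "invalid_segmentation",
    dice_qc            = "low_dice"
  )
}

#' Feasibility funnel report
#'
#' Orders every exam's terminal status into the pipeline's exclusion
#' stages (B-mode present, views present, confidence gate, timing,
#' segmentation validity, Dice QC) and reports, per stage, the number of
#' exams entering, excluded and surviving, with percentages of the input.
#' Counts are conserved: at every stage survivors + excluded equals the
#' previous stage's survivors, and the final survivor fraction is the
#' feasibility.
#'
#' @param reasons character vector of terminal exclusion reasons, one per
#'   exam, from [exclusion_reasons()] (`"none"` = measured).
#' @return object of class `feasibility_funnel`: a data.frame `stages`
#'   (stage, entering, excluded, surviving, pct_of_input), `n_input`,
#'   `n_measured`, `feasibility` (percent).
#' @export
feasibility_funnel <- function(reasons) {
  known <- exclusion_reasons()
  bad <- setdiff(unique(reasons), known)
  if (length(bad))
    ep_stop(sprintf("unknown exclusion reason(s): %s", paste(bad, collapse = ", ")),
            "reasons")
  n <- length(reasons)
  stages <- funnel_stages()
  surv <- n
  rows <- list()
  for (st in names(stages)) {
    excl <- sum(reasons %in% stages[[st]])
    rows[[st]] <- data.frame(stage = st, entering = surv, excluded = excl,
                             surviving = surv - excl,
                             pct_of_input = if (n) 100 * (surv - excl) / n else NA_real_)
    surv <- surv - excl
  }
  stopifnot(surv == sum(reasons == "none"))
  structure(list(stages = do.call(rbind, rows), n_input = n,
                 n_measured = surv,
                 feasibility = if (n) 100 * surv / n else NA_real_),
            class = "feasibility_funnel")
}

#' @export
print.feasibility_funnel <- function(x, ...) {
  cat(sprintf("feasibility funnel: %d exams in, %d measured (%.1f%%)\n",
              x$n_input, x$n_measured, x$feasibility))
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Histogram and density summary of a measurement distribution
#'
#' Binned counts plus (when the sample has spread) a Gaussian-kernel
#' density estimate, for side-by-side comparison of measured and
#' reference subsets.
#'
#' @param values numeric vector, length >= 1.
#' @param bins number of bins or a vector of break points (as
#'   `hist(breaks =)`).
#' @return list with `breaks`, `counts`, `mids` and `density` (a
#'   [stats::density()] object, or `NULL` for a degenerate sample).
#' @export
distribution_summary <- function(values, bins = 30) {
  values <- values[is.finite(values)]
  if (!length(values)) ep_stop("no finite values", "values")
  h <- if (length(bins) == 1L && diff(range(values)) == 0) {
    graphics::hist(values, breaks = c(values[1] - 0.5, values[1] + 0.5),
                   plot = FALSE)
  } else {
    graphics::hist(values, breaks = bins, plot = FALSE)
  }
  dens <- if (length(values) >= 2 && stats::sd(values) > 0)
    stats::density(values) else NULL
  list(breaks = h$breaks, counts = h$counts, mids = h$mids, density = dens)
}
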