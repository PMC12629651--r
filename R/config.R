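# Pipeline configuration: the QC constants and backend selections, with
# YAML round-tripping for reproducible runs.

#' Pipeline configuration
#'
#' Bundles the quality-control constants (view-confidence threshold,
#' Dice threshold, timing reconciliation cutoff), measurement settings
#' (number of disks, BSA formula) and backend selections. Defaults are
#' the pipeline's operating point: confidence 0.85, Dice 0.8, 5-frame
#' timing cutoff, 20 disks, Mosteller BSA.
#'
#' @param confidence_threshold view-confidence inclusion gate, in
#'   \[0, 1\].
#' @param dice_threshold dual-segmentation Dice gate, in \[0, 1\].
#' @param timing_cutoff_frames network-vs-regression reconciliation
#'   cutoff, frames (>= 0).
#' @param n_discs disks for biplane Simpson (>= 2).
#' @param bsa_formula `"mosteller"` or `"dubois"`.
#' @param seed integer seed for any stochastic backend / simulation.
#' @param modality_backend,view_backend,timing_backend backend names
#'   (`"oracle"`/`"noisy"` for classifiers, `"oracle"`/`"none"`/
#'   `"offset"` for timing) or ready-made backend objects.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(confidence_threshold = 0.85,
                            dice_threshold = 0.8,
                            timing_cutoff_frames = 5,
                            n_discs = 20L,
                            bsa_formula = c("mosteller", "dubois"),
                            seed = 1L,
                            modality_backend = "oracle",
                            view_backend = "oracle",
                            timing_backend = "oracle") {
  bsa_formula <- match.arg(bsa_formula)
  if (confidence_threshold < 0 || confidence_threshold > 1)
    ep_stop("confidence_threshold must be in [0, 1]", "confidence_threshold")
  if (dice_threshold < 0 || dice_threshold > 1)
    ep_stop("dice_threshold must be in [0, 1]", "dice_threshold")
  if (timing_cutoff_frames < 0)
    ep_stop("timing_cutoff_frames must be >= 0", "timing_cutoff_frames")
  if (n_discs < 2) ep_stop("n_discs must be >= 2", "n_discs")
  as_backend <- function(x, ctor, ...) {
    if (is.character(x)) ctor(name = x, ...) else x
  }
  # the argument shadows the constructor of the same name; fetch it
  tb_ctor <- get("timing_backend", envir = environment(pipeline_config))
  structure(list(
    confidence_threshold = confidence_threshold,
    dice_threshold = dice_threshold,
    timing_cutoff_frames = timing_cutoff_frames,
    n_discs = as.integer(n_discs),
    bsa_formula = bsa_formula,
    seed = as.integer(seed),
    modality_backend = as_backend(modality_backend, classifier_backend,
                                  kind = "modality", seed = seed),
    view_backend = as_backend(view_backend, classifier_backend,
                              kind = "view", seed = seed),
    timing_backend = as_backend(timing_backend, tb_ctor)
  ), class = "pipeline_config")
}

config_scalars <- function(config) {
  list(confidence_threshold = config$confidence_threshold,
       dice_threshold = config$dice_threshold,
       timing_cutoff_frames = config$timing_cutoff_frames,
       n_discs = config$n_discs,
       bsa_formula = config$bsa_formula,
       seed = config$seed,
       modality_backend = config$modality_backend$name,
       view_backend = config$view_backend$name,
       timing_backend = config$timing_backend$name)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return `read_pipeline_config()` returns a [pipeline_config()];
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config_scalars(config), path)
  invisible(path)
}

# Stable hash of the configuration scalars, for provenance logging.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config_scalars(config), tmp, auto_unbox = TRUE)
  unname(tools::md5sum(tmp))
}
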