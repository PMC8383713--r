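#' Analysis configuration
#'
#' Bundles the tunable models of the scoring pipeline: peak-detection
#' geometry, quality model, timing model, profile weights, and optional
#' paths to trained classifier files. Every nested block validates its own
#' invariants on construction. The whole object serializes to and from JSON
#' bit-stably via [save_config()] / [load_config()].
#'
#' @param peak_params a [peak_params()].
#' @param quality_model a [quality_model()].
#' @param timing_model a [timing_model()].
#' @param profile_weights a [profile_weights()] or `NULL` to adapt to the
#'   number of classifiers at analysis time.
#' @param classifier_paths character vector of saved classifier files
#'   (see [save_classifier()]).
#' @return an `analysis_config`.
#' @export
analysis_config <- function(peak_params = msnascore::peak_params(),
                            quality_model = msnascore::quality_model(),
                            timing_model = msnascore::timing_model(),
                            profile_weights = msnascore::profile_weights(),
                            classifier_paths = character(0)) {
  stopifnot(inherits(peak_params, "peak_params"),
            inherits(quality_model, "quality_model"),
            inherits(timing_model, "timing_model"))
  if (!is.null(profile_weights))
    stopifnot(inherits(profile_weights, "profile_weights"))
  structure(list(peak_params = peak_params, quality_model = quality_model,
                 timing_model = timing_model,
                 profile_weights = profile_weights,
                 classifier_paths = classifier_paths),
            class = "analysis_config")
}

config_blocks <- function() list(
  peak_params = peak_params, quality_model = quality_model,
  timing_model = timing_model, profile_weights = profile_weights
)

#' Save an analysis configuration as JSON
#' @param config an [analysis_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  payload <- lapply(config[names(config_blocks())], unclass)
  payload$classifier_paths <- config$classifier_paths
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load an analysis configuration from JSON
#'
#' Unspecified blocks and fields take the documented defaults. Unknown
#' top-level keys or unknown fields inside a block raise an error, and each
#' block re-validates its invariants (so e.g. a negative timing width is
#' rejected with the offending field named).
#'
#' @param path JSON file; an empty object `{}` yields the full default
#'   configuration.
#' @return an [analysis_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_arg("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c(names(config_blocks()), "classifier_paths")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_arg("unknown config keys: %s", paste(unknown, collapse = ", "))
  blocks <- lapply(names(config_blocks()), function(nm) {
    ctor <- config_blocks()[[nm]]
    given <- raw[[nm]]
    if (is.null(given)) return(ctor())
    bad <- setdiff(names(given), names(formals(ctor)))
    if (length(bad))
      stop_arg("unknown fields in config block '%s': %s", nm,
               paste(bad, collapse = ", "))
    do.call(ctor, given)
  })
  names(blocks) <- names(config_blocks())
  analysis_config(peak_params = blocks$peak_params,
                  quality_model = blocks$quality_model,
                  timing_model = blocks$timing_model,
                  profile_weights = blocks$profile_weights,
                  classifier_paths = as.character(raw$classifier_paths %||%
                                                    character(0)))
}
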