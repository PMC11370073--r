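# Pipeline configuration: every numeric constant of the analysis lives here,
# in one place — 30 Hz sampling, 15-s windows, 13 mg / 30 min non-wear,
# 480-min valid days, 4 valid days incl. 1 weekend day, 180/60-min guideline
# thresholds, 500 trees, Harrell knot quantiles.

#' Default pipeline configuration
#'
#' @return Nested named list of configuration values; see
#'   [run_pipeline()] for how each block is used.
#' @export
default_config <- function() {
  list(
    seed = 20190501,
    sample_rate = 30,
    window_s = 15,
    nonwear = list(sd_threshold = 0.013, min_duration_min = 30),
    valid_day = list(wear_min = 480),
    valid_subject = list(min_days = 4, min_weekend = 1),
    guidelines = list(tpa_min = 180, mvpa_min = 60),
    classifier = list(n_trees = 500),
    spline = list(quantiles = c(0.05, 0.35, 0.65, 0.95)),
    covariates = c(
      "maternal_work", "dwelling", "yard", "wear_minutes", "season", "covid"
    ),
    marginal_means = list(policy = "reference", ages = c(2, 3, 4, 5, 6, 7)),
    corpus = list(n_subjects = 31, session_s = 1200),
    recordings = list(n_children = 3, n_days = 5, day_minutes = 660),
    cohort = list(n_children = 150)
  )
}

#' Read / write a pipeline configuration
#'
#' Plain-YAML configuration files; a written configuration reads back
#' identically.
#'
#' @param path YAML file path.
#' @param config Configuration list.
#'
#' @return `read_config()` the configuration list; `write_config()` the
#'   path, invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_config()
  merge_cfg <- function(def, usr) {
    for (k in names(usr)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(usr[[k]])) {
        merge_cfg(def[[k]], usr[[k]])
      } else {
        usr[[k]]
      }
    }
    def
  }
  cfg <- merge_cfg(defaults, cfg)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_config <- function(config) {
  pos <- c(
    sample_rate = config$sample_rate, window_s = config$window_s,
    sd_threshold = config$nonwear$sd_threshold,
    min_duration_min = config$nonwear$min_duration_min,
    wear_min = config$valid_day$wear_min,
    tpa_min = config$guidelines$tpa_min,
    mvpa_min = config$guidelines$mvpa_min,
    n_trees = config$classifier$n_trees
  )
  if (any(pos <= 0)) {
    abort_arg(paste0(
      "config thresholds must be positive; offending: ",
      paste(names(pos)[pos <= 0], collapse = ", ")
    ))
  }
  invisible(config)
}

#' Hash a configuration
#'
#' MD5 of the canonical YAML serialisation, used to stamp every artefact a
#' pipeline run writes.
#'
#' @param config Configuration list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}
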