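#' Full model configuration
#'
#' Assembles all module parameter blocks plus run controls into one
#' configuration object. Every block is the corresponding constructor's
#' output, so defaults are the study conditions throughout.
#'
#' @param geography a [geography_params()] object or argument list.
#' @param onset_quartiles,onset_support onset-to-door sampler anchors.
#' @param pathway a [pathway_constants()] object or argument list.
#' @param outcome a [treatment_effect_model()] object or argument list.
#' @param survival_medians target median survival (years) at `survival_age`
#'   for mRS 0..5, fed to [calibrate_survival_defaults()].
#' @param survival_age reference calibration age.
#' @param deterioration a [deterioration_model()] object or argument list.
#' @param economics an [economic_parameters()] object or argument list.
#' @param n_iterations simulation iterations (default 2000).
#' @param master_seed master random seed.
#' @return an object of class `model_config`.
#' @export
model_config <- function(geography = geography_params(),
                         onset_quartiles = c(60, 85, 133),
                         onset_support = 270,
                         pathway = pathway_constants(),
                         outcome = treatment_effect_model(),
                         survival_medians = c(8.4, 7.9, 7.2, 3.7, 2.7, 1.3),
                         survival_age = 70,
                         deterioration = deterioration_model(),
                         economics = economic_parameters(),
                         n_iterations = 2000,
                         master_seed = 20240101) {
  as_block <- function(x, ctor) {
    if (is.list(x) && is.null(attr(x, "class"))) do.call(ctor, x) else x
  }
  cfg <- structure(
    list(
      geography = as_block(geography, geography_params),
      onset_quartiles = onset_quartiles,
      onset_support = onset_support,
      pathway = as_block(pathway, pathway_constants),
      outcome = as_block(outcome, treatment_effect_model),
      survival_medians = survival_medians,
      survival_age = survival_age,
      deterioration = as_block(deterioration, deterioration_model),
      economics = as_block(economics, economic_parameters),
      n_iterations = n_iterations,
      master_seed = master_seed
    ),
    class = "model_config"
  )
  validate_config(cfg)
  cfg
}

#' Validate a model configuration
#'
#' @param cfg a [model_config()] object.
#' @return `cfg`, invisibly; errors describe the offending block.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "model_config")) stop("not a model_config object")
  stopifnot(inherits(cfg$geography, "geography_params"),
            inherits(cfg$pathway, "pathway_constants"),
            inherits(cfg$outcome, "treatment_effect_model"),
            inherits(cfg$deterioration, "deterioration_model"),
            inherits(cfg$economics, "economic_parameters"))
  validate_geography(cfg$geography)
  if (cfg$n_iterations < 1) stop("n_iterations must be at least 1")
  if (length(cfg$survival_medians) != 6L || any(diff(cfg$survival_medians) >= 0))
    stop("survival_medians must be 6 strictly decreasing values")
  # sampler construction revalidates the onset anchors
  onset_sampler(cfg$onset_quartiles, cfg$onset_support)
  invisible(cfg)
}

#' Read a model configuration from YAML or JSON
#'
#' The file holds named blocks matching [model_config()] arguments; each
#' block is an argument list for the corresponding constructor. Omitted
#' blocks take the defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [model_config()] object.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(model_config, raw)
}
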