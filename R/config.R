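#' Analysis configuration with the study's published thresholds as defaults
#'
#' Every threshold used by the pipeline is a named key. Defaults follow the
#' source study: DE calling at Benjamini-Hochberg FDR <= 0.05 and linear
#' fold change >= 1.5 (>= 1.2 for the TF-focused call); the expression
#' criterion "intensity above the pooled 75th percentile in at least 25% of
#' the samples of some diagnostic group"; sample exclusion at blood
#' fructosamine > 285 umol/l or glucose > 11.1 mmol/l (samples without a
#' diabetes history) and insulin secretion more than 1 SD below the
#' within-group mean.
#'
#' @param fdr FDR threshold for DE calling.
#' @param fold_change linear fold-change threshold for DE calling.
#' @param tf_fold_change fold-change threshold for the TF-focused DE call.
#' @param expression_quantile pooled intensity quantile defining the
#'   expression cutoff tau.
#' @param expression_sample_fraction minimum fraction of a group's samples
#'   that must exceed tau.
#' @param fructosamine_max exclusion threshold, umol/l.
#' @param glucose_max exclusion threshold, mmol/l.
#' @param insulin_sd number of within-group SDs below the mean at which a
#'   sample is excluded as a low secretor.
#' @param soft_power soft-thresholding power beta for the co-expression
#'   adjacency `|cor|^beta`.
#' @param cut_height static cut height on the 1 - TOM dendrogram.
#' @param min_module_size clusters below this size become `unassigned`.
#' @param overlap_alpha BH-q threshold for cross-cohort module preservation.
#' @param z_cutoff |z| threshold for calling a regulator activated/inhibited.
#' @param enrichment_alpha BH-q threshold for over-representation calls.
#' @param hub_top_k hub genes reported per module (by |kME|).
#' @param seed analysis seed.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(fdr = 0.05, fold_change = 1.5,
                            tf_fold_change = 1.2,
                            expression_quantile = 0.75,
                            expression_sample_fraction = 0.25,
                            fructosamine_max = 285, glucose_max = 11.1,
                            insulin_sd = 1,
                            soft_power = 6, cut_height = 0.95,
                            min_module_size = 20, overlap_alpha = 0.05,
                            z_cutoff = 2, enrichment_alpha = 0.05,
                            hub_top_k = 10, seed = 1L) {
  cfg <- list(fdr = fdr, fold_change = fold_change,
              tf_fold_change = tf_fold_change,
              expression_quantile = expression_quantile,
              expression_sample_fraction = expression_sample_fraction,
              fructosamine_max = fructosamine_max, glucose_max = glucose_max,
              insulin_sd = insulin_sd, soft_power = soft_power,
              cut_height = cut_height, min_module_size = min_module_size,
              overlap_alpha = overlap_alpha, z_cutoff = z_cutoff,
              enrichment_alpha = enrichment_alpha, hub_top_k = hub_top_k,
              seed = as.integer(seed))
  pos <- c(cfg$fdr, cfg$fold_change, cfg$tf_fold_change, cfg$fructosamine_max,
           cfg$glucose_max, cfg$insulin_sd, cfg$soft_power, cfg$cut_height,
           cfg$min_module_size, cfg$overlap_alpha, cfg$z_cutoff,
           cfg$enrichment_alpha)
  if (any(pos <= 0)) stop("all thresholds must be positive")
  frac <- c(cfg$expression_quantile, cfg$expression_sample_fraction)
  if (any(frac <= 0 | frac > 1)) stop("fractions must lie in (0, 1]")
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Keys override the defaults of [analysis_config()]; unknown keys are an
#' error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML config requires the yaml package")
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON config requires the jsonlite package")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml, .yml or .json")
  unknown <- setdiff(names(vals), names(formals(analysis_config)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}
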