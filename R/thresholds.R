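# Every numeric constant of the caller's filter cascade in one record.

#' Filter thresholds for the editing-site caller
#'
#' All constants of the step-wise cascade, with defaults matching the
#' published pipeline: per-sample depth >= 6 and group mean depth >= 9;
#' candidate variants need >= 1 call at level >= 0.02 in every sample of a
#' group with group means >= 1.3 calls and >= 0.03 level; other-base
#' contamination limits of 1% overall or > 1 call in any sample;
#' range-over-mean dispersion >= 2; BH-adjusted beta-binomial p < 0.05;
#' control mean level exactly 0 with treated mean >= 0.04; final mean
#' editing level > 0.05; strand-bias Fisher test applied at >= 8 calls per
#' base-type when a direction holds < 25% of a base-type's calls, failing
#' at p < 0.05.
#'
#' @param min_calls_per_sample minimum A/C/G/T calls in every sample.
#' @param min_group_mean_depth minimum mean depth in each sample-group.
#' @param min_sample_variant_level per-sample variation level for a
#'   candidate variant.
#' @param min_group_mean_variant_count group mean variant-call count.
#' @param min_group_mean_variant_level group mean variation level.
#' @param max_other_base_fraction maximum fraction of all A/C/G/T calls from
#'   bases other than reference and variant.
#' @param max_other_base_count_per_sample maximum other-base calls in any
#'   single sample.
#' @param min_range_over_mean minimum (max - min)/mean of the six variation
#'   levels.
#' @param alpha_adjusted BH-adjusted significance cutoff.
#' @param min_treated_mean_level minimum treated-group mean variation level.
#' @param final_min_edit_level final mean editing level must exceed this.
#' @param strand_min_calls_per_basetype minimum calls per base-type for the
#'   strand-bias test to be applicable.
#' @param strand_minor_direction_fraction the test applies only when some
#'   base-type draws less than this fraction of its calls from one read
#'   direction.
#' @param strand_alpha Fisher strand-bias failure cutoff.
#' @return object of class `filter_thresholds` (named list).
#' @export
filter_thresholds <- function(min_calls_per_sample = 6,
                              min_group_mean_depth = 9,
                              min_sample_variant_level = 0.02,
                              min_group_mean_variant_count = 1.3,
                              min_group_mean_variant_level = 0.03,
                              max_other_base_fraction = 0.01,
                              max_other_base_count_per_sample = 1,
                              min_range_over_mean = 2,
                              alpha_adjusted = 0.05,
                              min_treated_mean_level = 0.04,
                              final_min_edit_level = 0.05,
                              strand_min_calls_per_basetype = 8,
                              strand_minor_direction_fraction = 0.25,
                              strand_alpha = 0.05) {
  th <- as.list(environment())
  fracs <- c("min_sample_variant_level", "min_group_mean_variant_level",
             "max_other_base_fraction", "alpha_adjusted",
             "min_treated_mean_level", "final_min_edit_level",
             "strand_minor_direction_fraction", "strand_alpha")
  for (f in fracs)
    if (th[[f]] < 0 || th[[f]] > 1) stopf("%s must be in [0, 1]", f)
  cnts <- c("min_calls_per_sample", "min_group_mean_depth",
            "min_group_mean_variant_count", "min_range_over_mean",
            "strand_min_calls_per_basetype")
  for (f in cnts) if (th[[f]] < 0) stopf("%s must be >= 0", f)
  structure(th, class = "filter_thresholds")
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("edcall filter thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-34s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read filter thresholds from a YAML file
#'
#' The YAML keys mirror the arguments of [filter_thresholds()]
#' field-for-field; absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return `filter_thresholds` object.
#' @export
read_thresholds_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(filter_thresholds)))
  if (length(unknown))
    stopf("unknown threshold field(s) in %s: %s", path,
          paste(unknown, collapse = ", "))
  do.call(filter_thresholds, vals)
}
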