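# Editing-level quantification from Sanger chromatogram peak heights.

#' Editing level from major/minor Sanger peak heights
#'
#' The editing level is `minor / (major + minor)`. Peak-calling software
#' reports a minor peak only when its height reaches `rel_threshold` (5%)
#' of the major peak's, so the smallest measurable level is
#' `0.05/1.05 = 0.048`; below that the call is censored and the level
#' reported as 0 with `censored = TRUE`. Vectorized over peak pairs.
#'
#' @param major,minor peak heights (arbitrary fluorescence units);
#'   `major > 0`, `minor >= 0`, `minor <= major`.
#' @param rel_threshold minimum minor/major height ratio for detection
#'   (default 0.05).
#' @return data frame with columns `level` and `censored`.
#' @examples
#' sanger_level(100, 5)   # 0.0476..., at the 0.048 detection boundary
#' sanger_level(100, 4)   # censored, level 0
#' @export
sanger_level <- function(major, minor, rel_threshold = 0.05) {
  if (any(major <= 0)) stopf("major peak height must be positive")
  if (any(minor < 0)) stopf("minor peak height must be non-negative")
  if (any(minor > major)) stopf("minor peak height exceeds major")
  censored <- minor / major < rel_threshold
  level <- ifelse(censored, 0, minor / (major + minor))
  data.frame(level = level, censored = censored)
}

#' Summarize replicate Sanger measurements per site
#'
#' @param peaks data frame with columns `site`, `major`, `minor` (one row
#'   per replicate).
#' @param rel_threshold see [sanger_level()].
#' @param include_censored include censored replicates (as level 0) in the
#'   mean (default `TRUE`, matching bar graphs drawn against a dotted
#'   detection line).
#' @return data frame with `site`, `n_replicates`, `n_censored`,
#'   `mean_level`.
#' @export
sanger_site_means <- function(peaks, rel_threshold = 0.05,
                              include_censored = TRUE) {
  lv <- sanger_level(peaks$major, peaks$minor, rel_threshold)
  out <- do.call(rbind, lapply(split(seq_len(nrow(peaks)), peaks$site),
    function(idx) {
      keep <- if (include_censored) idx else idx[!lv$censored[idx]]
      data.frame(n_replicates = length(idx),
                 n_censored = sum(lv$censored[idx]),
                 mean_level = if (length(keep)) mean(lv$level[keep]) else NA_real_)
    }))
  cbind(data.frame(site = rownames(out), stringsAsFactors = FALSE), out,
        row.names = NULL)
}
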