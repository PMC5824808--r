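#' Sample ploidy from a segment profile
#'
#' Length-weighted mean total copy number over the autosomal profile.
#'
#' @param profile A `segment_profile`.
#' @return Ploidy (2.0 for a fully diploid genome).
#' @export
sample_ploidy <- function(profile) {
  len <- profile$end - profile$start
  if (sum(len) <= 0) stop("profile covers zero length")
  sum(len * (profile$cn1 + profile$cn2)) / sum(len)
}

#' Genome-doubling call
#'
#' A sample is called genome-doubled when its ploidy strictly exceeds the
#' threshold. The default threshold is 3; the source analyses state the rule
#' both as "greater than 3" and "ploidy >= 3" in different places, so the
#' comparison here is strict and the threshold configurable.
#'
#' @param ploidy Ploidy estimate (>= 0).
#' @param threshold GD threshold.
#' @return Logical.
#' @export
call_gd <- function(ploidy, threshold = 3.0) {
  if (any(ploidy < 0)) stop("ploidy must be >= 0")
  ploidy > threshold
}

#' Ploidy calls for a set of profiles
#'
#' @param profiles List of `segment_profile`.
#' @param threshold GD threshold.
#' @return data.frame with `sample_id`, `ploidy`, `gd`.
#' @export
ploidy_calls <- function(profiles, threshold = 3.0) {
  out <- data.frame(
    sample_id = vapply(profiles, sample_id_of, ""),
    ploidy = vapply(profiles, sample_ploidy, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  out$gd <- call_gd(out$ploidy, threshold)
  out
}

#' Bimodality of the ploidy distribution
#'
#' Percentage of samples whose ploidy falls in `[1.5, 2.5]` (around the
#' diploid mode) or strictly above 3.5 (around the doubled mode).
#'
#' @param ploidies Numeric vector of ploidy values.
#' @return Percentage in `[0, 100]`.
#' @export
ploidy_bimodality <- function(ploidies) {
  if (!length(ploidies)) stop("need at least one ploidy value")
  100 * mean((ploidies >= 1.5 & ploidies <= 2.5) | ploidies > 3.5)
}
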