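#' Viral read normalisation and HPV status
#'
#' Hybrid-capture panels that carry viral baits recover off-target viral
#' reads; normalising the per-virus aligned read-pair count to reads per
#' million sequenced pairs gives a sample-size-free abundance. HPV status
#' uses closed thresholds: >= 5 rpm positive, <= 2 rpm negative, and the
#' open interval in between is reported as indeterminate rather than forced
#' to a binary call.
#'
#' @name viral-status
NULL

#' Reads per million
#'
#' @param viral_count Viral aligned read(-pair) count (>= 0).
#' @param total Total sequenced read(-pair) count (> 0).
#' @return `1e6 * viral_count / total`, vectorised.
#' @export
reads_per_million <- function(viral_count, total) {
  assert_that(all(viral_count >= 0), "`viral_count` must be >= 0")
  assert_that(all(total > 0), "`total` must be positive")
  1e6 * viral_count / total
}

#' Three-way HPV status from reads per million
#'
#' @param rpm Reads-per-million value(s), >= 0.
#' @param positive_min,negative_max Closed thresholds for the positive and
#'   negative calls.
#' @return Character vector in `positive` / `negative` / `indeterminate`.
#' @export
classify_hpv_status <- function(rpm, positive_min = 5, negative_max = 2) {
  assert_that(all(rpm >= 0), "`rpm` must be >= 0")
  dplyr::case_when(
    rpm >= positive_min ~ "positive",
    rpm <= negative_max ~ "negative",
    TRUE ~ "indeterminate"
  )
}

#' Viral read report for a cohort table
#'
#' @param counts Tibble with columns `sample`, `viral_reads`, `total_reads`
#'   (and optionally `virus`).
#' @return The input with `rpm` and `status` columns appended.
#' @export
viral_read_report <- function(counts) {
  counts |>
    mutate(rpm = reads_per_million(.data$viral_reads, .data$total_reads),
           status = classify_hpv_status(.data$rpm))
}
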