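#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n across row_number pull rename distinct
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_chr map_int map2 pmap imap list_rbind
#' @importFrom stats rnorm rbinom rmultinom runif setNames
NULL

BASES <- c("A", "C", "G", "T")

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Run `expr` under a locally fixed RNG state when `seed` is non-NULL.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg, call = NULL)
  invisible(TRUE)
}

assert_fraction <- function(x, name, open_left = FALSE) {
  ok <- is.numeric(x) && all(x <= 1) && all(if (open_left) x > 0 else x >= 0)
  assert_that(ok, paste0("`", name, "` must lie in ", if (open_left) "(0, 1]" else "[0, 1]"))
}
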