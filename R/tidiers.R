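#' Broom-style tidiers
#'
#' `tidy()` returns per-component rows (segments for a purity/ploidy fit,
#' samples for a clustering), `glance()` a one-row model summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @name panelseq-tidiers
NULL

#' @rdname panelseq-tidiers
#' @importFrom generics tidy
#' @export
tidy.purity_ploidy_fit <- function(x, ...) {
  seg <- x$segments
  seg$expected_lr <- if (x$identifiable)
    expected_logratio(seg$C_seg, x$purity, x$ploidy) else NA_real_
  as_tibble(seg)
}

#' @rdname panelseq-tidiers
#' @importFrom generics glance
#' @export
glance.purity_ploidy_fit <- function(x, ...) {
  tibble(purity = x$purity, ploidy = x$ploidy, loglik = x$loglik,
         n_segments = nrow(x$segments), identifiable = x$identifiable)
}

#' @rdname panelseq-tidiers
#' @export
tidy.cohort_clustering <- function(x, ...) {
  tibble(sample = names(x$cut), cluster = unname(x$cut))
}

#' @rdname panelseq-tidiers
#' @export
glance.cohort_clustering <- function(x, ...) {
  tibble(n_samples = length(x$cut), purity = x$purity,
         degenerate = x$degenerate)
}

#' @export
generics::tidy

#' @export
generics::glance
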