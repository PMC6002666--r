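#' Tidy and glance methods for fitted rarefaction models
#'
#' `tidy()` returns one row per model parameter with its asymptotic
#' standard error; `glance()` returns a one-row model summary.
#'
#' @param x A `decay_fit` or `heaps_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.decay_fit <- function(x, ...) {
  tibble(
    term = c("epsilon", "tau", x$asymptote_name),
    estimate = c(x$epsilon, x$tau, x$asymptote),
    std.error = c(x$se_epsilon, x$se_tau, x$se_asymptote)
  )
}

#' @rdname tidy.decay_fit
#' @exportS3Method generics::tidy
tidy.heaps_fit <- function(x, ...) {
  tibble(
    term = c("kappa", "alpha"),
    estimate = c(x$kappa, x$alpha),
    std.error = c(x$se_kappa, x$se_alpha)
  )
}

#' @rdname tidy.decay_fit
#' @exportS3Method generics::glance
glance.decay_fit <- function(x, ...) {
  tibble(
    model = x$model,
    r.squared = x$r_squared,
    adj.r.squared = x$adj_r_squared,
    n_points = x$n_points,
    start_n = x$start_n,
    converged = x$converged
  )
}

#' @rdname tidy.decay_fit
#' @exportS3Method generics::glance
glance.heaps_fit <- function(x, ...) {
  tibble(
    model = "heaps",
    r.squared = x$r_squared,
    adj.r.squared = x$adj_r_squared,
    n_points = x$n_points,
    start_n = x$start_n,
    converged = x$converged,
    verdict = x$verdict,
    low_confidence = x$low_confidence
  )
}
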