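# Tidiers for fitted objects, in the broom idiom: tidy() for per-term /
# per-class tables, glance() for one-row model summaries.

#' Tidy a heavy-tail fit
#'
#' @param x An `ht_fit` from [fit_heavy_tail()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`,
#'   `conf.low`/`conf.high` (power-law exponent only).
#' @export
tidy.ht_fit <- function(x, ...) {
  pars <- unlist(x$spec$params)
  out <- tibble::tibble(
    term = names(pars),
    estimate = unname(pars),
    std.error = if (!is.null(x$se)) unname(x$se[names(pars)]) else NA_real_
  )
  out$conf.low <- NA_real_
  out$conf.high <- NA_real_
  if (!is.null(x$alpha_ci)) {
    out$conf.low[out$term == "alpha"] <- x$alpha_ci[1]
    out$conf.high[out$term == "alpha"] <- x$alpha_ci[2]
  }
  out
}

#' @rdname tidy.ht_fit
#' @export
glance.ht_fit <- function(x, ...) {
  tibble::tibble(
    family = x$spec$family,
    logLik = x$loglik,
    nobs = x$n,
    xmin = x$xmin,
    converged = x$converged
  )
}

#' Tidy a stationary-distribution result
#'
#' @param x A `stationary_result` from [run_dynamics()] or
#'   [stationary_eigen()].
#' @param ... Unused.
#' @return A tibble with one row per class: `spacer_count`, `probability`.
#' @export
tidy.stationary_result <- function(x, ...) {
  tibble::tibble(
    spacer_count = seq_along(x$distribution),
    probability = x$distribution
  )
}

#' @rdname tidy.stationary_result
#' @export
glance.stationary_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    iterations = x$iterations,
    converged = x$converged,
    n_nu_star = x$n_nu_star,
    drift = x$drift,
    degenerate = x$degenerate
  )
}
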