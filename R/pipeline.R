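# High-level workflows: empirical-style fitting of a spacer-count dataset,
# model-based prediction of the stationary spacer distribution, and the
# global extrapolation of the largest expected array size.

report_version <- "1.0"

check_out_dir <- function(out_dir, files, overwrite) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  existing <- file.path(out_dir, files)
  hit <- existing[file.exists(existing)]
  if (length(hit) && !overwrite) {
    abort(sprintf("Output file(s) already exist (use overwrite = TRUE): %s",
                  paste(basename(hit), collapse = ", ")),
          class = "spacerlaw_io_error")
  }
  invisible(NULL)
}

#' Fit heavy-tailed families to a spacer-count dataset
#'
#' The empirical-analysis workflow: pools the per-array counts, fits all
#' five candidate families, ranks the alternatives against the truncated
#' power law, and (optionally) produces the per-group best-fit summary.
#' With `out_dir` set, writes `histogram.tsv`, `ranking.tsv`, optionally
#' `per_group.tsv`, and a machine-readable `report.json`.
#'
#' @param data Spacer-count tibble or path to a TSV readable by
#'   [read_spacer_counts()].
#' @param group Optional `"sample_id"` or `"habitat"` for the per-group
#'   summary.
#' @param xmin Support minimum for all fits.
#' @param min_n Observation floor for per-group fits.
#' @param sig_level Significance threshold for model selection.
#' @param out_dir Optional output directory.
#' @param overwrite Allow overwriting existing outputs.
#' @return A list of class `spacer_fit_report`: `summary`, `histogram`,
#'   `fits`, `ranking`, `best_family`, and `per_group`/`size_curve` when
#'   grouped.
#' @export
run_fit <- function(data, group = NULL, xmin = 1L, min_n = 30,
                    sig_level = 0.05, out_dir = NULL, overwrite = FALSE) {
  if (is.character(data)) data <- read_spacer_counts(data)
  data <- validate_spacer_counts(data)
  check_out_dir(out_dir, c("histogram.tsv", "ranking.tsv", "per_group.tsv",
                           "report.json"), overwrite)

  summary <- summarize_spacers(data)
  histogram <- spacer_histogram(data)
  ranking <- rank_candidates(data$spacer_count, xmin = xmin,
                             sig_level = sig_level)
  fits <- attr(ranking, "fits")
  non_pl <- ranking[ranking$family_2 != "powerlaw", ]
  best_family <- if (all(!is.na(non_pl$R)) && all(non_pl$R > 0)) {
    "truncated_powerlaw"
  } else {
    ok <- non_pl[!is.na(non_pl$R) & non_pl$R < 0, ]
    if (nrow(ok)) ok$family_2[which.min(ok$R)] else "indeterminate"
  }

  per_group <- size_curve <- NULL
  if (!is.null(group)) {
    per_group <- per_group_best_fit(data, group = group, min_n = min_n,
                                    xmin = xmin, sig_level = sig_level)
    size_curve <- best_fit_size_curve(per_group)
  }

  report <- structure(
    list(summary = summary, histogram = histogram, fits = fits,
         ranking = ranking, best_family = best_family,
         per_group = per_group, size_curve = size_curve),
    class = "spacer_fit_report"
  )

  if (!is.null(out_dir)) {
    readr::write_tsv(histogram, file.path(out_dir, "histogram.tsv"))
    readr::write_tsv(dplyr::select(ranking, -dplyr::any_of("note")) |>
                       dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                                   ~ signif(.x, 10))),
                     file.path(out_dir, "ranking.tsv"))
    if (!is.null(per_group)) {
      readr::write_tsv(per_group, file.path(out_dir, "per_group.tsv"))
    }
    json <- list(
      version = report_version,
      summary = as.list(summary),
      best_family = best_family,
      fits = purrr::map(fits, function(f) {
        c(list(family = f$spec$family), f$spec$params,
          list(loglik = f$loglik, n = f$n, xmin = f$xmin))
      }),
      ranking = ranking[setdiff(names(ranking), "note")]
    )
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.spacer_fit_report <- function(x, ...) {
  cat("<spacer_fit_report>\n")
  cat("  arrays:", x$summary$n_arrays, " samples:", x$summary$n_samples,
      " mean count:", signif(x$summary$mean, 4), "\n")
  cat("  best family:", x$best_family, "\n")
  tpl <- x$fits$truncated_powerlaw
  cat("  truncated power law: alpha =", signif(tpl$spec$params$alpha, 4),
      " lambda =", signif(tpl$spec$params$lam, 4), "\n")
  print(x$ranking[setdiff(names(x$ranking), "note")])
  invisible(x)
}

#' Predict the stationary spacer distribution from the dynamics model
#'
#' The model-based workflow: runs the Markov-chain dynamics to stationarity,
#' fits a truncated power law to the stationary class abundances, and
#' optionally cross-checks the iterative solution against the left principal
#' eigenvector of the combined transition matrix. With `out_dir` set, writes
#' `stationary.tsv` (spacer_count, probability) and `report.json`.
#'
#' @param params A [dynamics_params()] object.
#' @param init Initial state for [run_dynamics()].
#' @param cross_check Also solve the eigenvector problem and report the L1
#'   discrepancy.
#' @param out_dir Optional output directory.
#' @param overwrite Allow overwriting existing outputs.
#' @return A list of class `spacer_sim_report`: `result`, `fit` (`NULL` with
#'   `degenerate = TRUE` when the dynamics are frozen), `alpha`, `lambda`,
#'   and `eigen_l1` when cross-checked.
#' @export
run_simulate <- function(params, init = "uniform", cross_check = FALSE,
                         out_dir = NULL, overwrite = FALSE) {
  check_out_dir(out_dir, c("stationary.tsv", "report.json"), overwrite)
  result <- run_dynamics(params, init = init)
  fit <- NULL
  alpha <- lambda <- NA_real_
  if (!result$degenerate) {
    fit <- fit_stationary(result)
    alpha <- fit$spec$params$alpha
    lambda <- fit$spec$params$lam
  }
  eigen_l1 <- NULL
  if (cross_check && !result$degenerate) {
    eig <- stationary_eigen(params, result$n_nu_star)
    eigen_l1 <- sum(abs(eig$distribution - result$distribution))
  }
  report <- structure(
    list(result = result, fit = fit, alpha = alpha, lambda = lambda,
         degenerate = result$degenerate, eigen_l1 = eigen_l1),
    class = "spacer_sim_report"
  )
  if (!is.null(out_dir)) {
    readr::write_tsv(tidy(result), file.path(out_dir, "stationary.tsv"))
    json <- list(
      version = report_version,
      degenerate = result$degenerate,
      converged = result$converged,
      iterations = result$iterations,
      n_nu_star = result$n_nu_star,
      alpha = alpha, lambda = lambda, eigen_l1 = eigen_l1
    )
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.spacer_sim_report <- function(x, ...) {
  cat("<spacer_sim_report>\n")
  if (x$degenerate) {
    cat("  degenerate dynamics (frozen state); fit skipped\n")
  } else {
    cat("  iterations:", x$result$iterations,
        " converged:", x$result$converged, "\n")
    cat("  fitted truncated power law: alpha =", signif(x$alpha, 4),
        " lambda =", signif(x$lambda, 5), "\n")
  }
  if (!is.null(x$eigen_l1)) {
    cat("  iteration-vs-eigenvector L1:", format(x$eigen_l1, digits = 3), "\n")
  }
  invisible(x)
}

#' Extrapolate the largest expected array size in a population
#'
#' Under the normalized discrete truncated power law
#' \eqn{p(i) \propto i^{-\alpha} e^{-\lambda i}} on `{1, 2, ...}`, returns
#' the largest array size `i` whose expected number of carriers in a
#' population of `population_size` cells is at least one,
#' i.e. the largest `i` with \eqn{population\_size \cdot p(i) \ge 1}.
#'
#' @param alpha Power-law exponent (> 0 unless `support_max` is finite).
#' @param lam Exponential decay rate (> 0 unless `support_max` is finite).
#' @param population_size Number of cells (>= 1).
#' @param support_max Upper support bound, default unbounded.
#' @return The largest such integer `i`, or `0L` when even `i = 1` has
#'   expected count below one.
#' @examples
#' extrapolate_max_array(2.57, 0.004, 1e12)
#' @export
extrapolate_max_array <- function(alpha, lam, population_size,
                                  support_max = Inf) {
  if (population_size < 1) {
    abort("`population_size` must be >= 1.", class = "spacerlaw_param_error")
  }
  spec <- dist_spec("truncated_powerlaw", alpha = alpha, lam = lam,
                    support_max = support_max)
  lpop <- log(population_size)
  expected_ok <- function(i) lpop + dist_logpmf(spec, i) >= 0
  if (!expected_ok(spec$support_min)) return(0L)
  if (is.finite(support_max)) {
    i_all <- spec$support_min:support_max
    return(max(i_all[lpop + dist_logpmf(spec, i_all) >= 0]))
  }
  # pmf strictly decreasing: bracket by doubling, then bisect
  lo <- spec$support_min
  hi <- 2L * lo + 1L
  while (expected_ok(hi)) {
    lo <- hi
    hi <- 2L * hi
    if (hi > .Machine$integer.max / 2) break
  }
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (expected_ok(mid)) lo <- mid else hi <- mid
  }
  as.integer(lo)
}
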