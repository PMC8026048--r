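# Pairwise loglikelihood-ratio comparison of fitted heavy-tailed families
# (Vuong-style normal approximation) and candidate ranking against the
# truncated power law.

# canonical ordering of the non-reference candidates in ranking tables
ht_candidate_order <- c("exponential", "stretched_exponential",
                        "lognormal", "powerlaw")

#' Loglikelihood-ratio comparison of two fitted families
#'
#' Computes the Vuong-style statistic
#' \eqn{R = \sum_i [\ln p_1(x_i) - \ln p_2(x_i)]} over the fitted
#' observations, the per-observation standard deviation \eqn{\sigma} of the
#' pointwise log-ratios, and the two-sided normal-approximation p-value
#' \eqn{p = 2\,\bar\Phi(|R| / (\sigma\sqrt n))}. A positive `R` favors the
#' first family; the sign is only trusted (column `preferred`) when the
#' p-value falls below `sig_level`.
#'
#' @param fit1,fit2 [fit_heavy_tail()] results fitted to the same data with
#'   the same `xmin`.
#' @param x,weights Observations and weights; default taken from `fit1`.
#' @param sig_level Significance threshold for declaring a preference.
#' @param one_sided If `TRUE`, use the one-sided tail (for nested pairs).
#' @return A one-row tibble: `family_1`, `family_2`, `R`, `sigma`,
#'   `p_value`, `n`, `preferred`.
#' @examples
#' x <- dist_rand(dist_spec("truncated_powerlaw", alpha = 2.5, lam = 0.01),
#'                1000, seed = 7)
#' f1 <- fit_heavy_tail(x, "truncated_powerlaw")
#' f2 <- fit_heavy_tail(x, "exponential")
#' compare_fits(f1, f2)
#' @export
compare_fits <- function(fit1, fit2, x = NULL, weights = NULL,
                         sig_level = 0.05, one_sided = FALSE) {
  stopifnot(inherits(fit1, "ht_fit"), inherits(fit2, "ht_fit"))
  if (fit1$xmin != fit2$xmin) {
    abort("Both fits must use the same `xmin`.", class = "spacerlaw_param_error")
  }
  if (is.null(x)) {
    x <- fit1$data
    weights <- fit1$weights
  }
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(x) == 0L) abort("No observations to compare.", class = "spacerlaw_param_error")
  n <- sum(weights)
  d <- dist_logpmf(fit1$spec, x) - dist_logpmf(fit2$spec, x)
  R <- sum(weights * d)
  dbar <- R / n
  sigma2 <- sum(weights * (d - dbar)^2) / n
  sigma <- sqrt(sigma2)
  if (sigma == 0) {
    p_value <- if (abs(R) < 1e-12) 1 else 0
  } else {
    z <- abs(R) / (sigma * sqrt(n))
    p_value <- if (one_sided) pnorm(z, lower.tail = FALSE) else 2 * pnorm(z, lower.tail = FALSE)
  }
  preferred <- if (p_value < sig_level && abs(R) > 0) {
    if (R > 0) fit1$spec$family else fit2$spec$family
  } else {
    "indeterminate"
  }
  tibble::tibble(
    family_1 = fit1$spec$family, family_2 = fit2$spec$family,
    R = R, sigma = sigma, p_value = p_value, n = n, preferred = preferred
  )
}

#' Rank candidate families against the truncated power law
#'
#' Fits the truncated power law and each candidate family to the same data,
#' then reports one pairwise loglikelihood-ratio comparison per candidate
#' with the truncated power law as the first (reference) family. Positive
#' ratios indicate that the truncated power law fits better. Fit failures
#' annotate the affected row instead of aborting the table.
#'
#' @param x Integer observations.
#' @param families Candidate families to compare against the reference;
#'   rows are ordered exponential, stretched exponential, lognormal,
#'   power law.
#' @param xmin Support minimum used for every fit.
#' @param weights Optional observation weights.
#' @param sig_level Significance threshold passed to [compare_fits()].
#' @return A tibble with one row per candidate (columns as in
#'   [compare_fits()] plus `note`); the list of fits is attached as
#'   attribute `"fits"`.
#' @examples
#' x <- dist_rand(dist_spec("truncated_powerlaw", alpha = 2.57, lam = 0.004),
#'                2000, seed = 11)
#' rank_candidates(x)
#' @export
rank_candidates <- function(x, families = ht_candidate_order, xmin = 1L,
                            weights = NULL, sig_level = 0.05) {
  if (length(families) == 0L) {
    abort("`families` must name at least one candidate.", class = "spacerlaw_param_error")
  }
  families <- match.arg(families, ht_candidate_order, several.ok = TRUE)
  families <- ht_candidate_order[ht_candidate_order %in% families]
  ref <- fit_heavy_tail(x, "truncated_powerlaw", xmin = xmin, weights = weights)
  fits <- list(truncated_powerlaw = ref)
  rows <- purrr::map(families, function(fam) {
    alt <- try(fit_heavy_tail(x, fam, xmin = xmin, weights = weights), silent = TRUE)
    if (inherits(alt, "try-error")) {
      return(tibble::tibble(
        family_1 = "truncated_powerlaw", family_2 = fam,
        R = NA_real_, sigma = NA_real_, p_value = NA_real_,
        n = NA_real_, preferred = NA_character_,
        note = conditionMessage(attr(alt, "condition"))
      ))
    }
    fits[[fam]] <<- alt
    cmp <- compare_fits(ref, alt, x = x, weights = weights, sig_level = sig_level)
    cmp$note <- NA_character_
    cmp
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  out
}

#' Per-group best-fit summary across metagenomes or habitats
#'
#' For every group (metagenome sample or habitat) with enough arrays, fits
#' all candidate families to the group's spacer counts and reports whether a
#' power-law family (truncated or pure) beats every non-power-law candidate,
#' and whether every pairwise comparison is individually significant. Groups
#' below the observation floor are flagged `"insufficient"` rather than
#' dropped.
#'
#' @param data A spacer-count dataset (see [read_spacer_counts()]).
#' @param group `"sample_id"` or `"habitat"`.
#' @param min_n Minimum number of arrays per group for fitting.
#' @param xmin,sig_level Passed to the fitting and comparison routines.
#' @return A tibble with one row per group: `n_arrays`, `status`,
#'   `best_family`, `powerlaw_best`, `all_significant`.
#' @seealso [best_fit_size_curve()] for the aggregate
#'   proportion-versus-group-size curve.
#' @export
per_group_best_fit <- function(data, group = c("sample_id", "habitat"),
                               min_n = 30, xmin = 1L, sig_level = 0.05) {
  group <- match.arg(group)
  if (nrow(data) == 0L) abort("Empty dataset.", class = "spacerlaw_param_error")
  data |>
    dplyr::group_by(.data[[group]]) |>
    dplyr::group_modify(function(df, key) {
      n_arr <- nrow(df)
      if (n_arr < min_n) {
        return(tibble::tibble(
          n_arrays = n_arr, status = "insufficient",
          best_family = NA_character_, powerlaw_best = NA,
          all_significant = NA
        ))
      }
      tab <- try(rank_candidates(df$spacer_count, xmin = xmin,
                                 sig_level = sig_level), silent = TRUE)
      if (inherits(tab, "try-error")) {
        return(tibble::tibble(
          n_arrays = n_arr, status = "fit_error",
          best_family = NA_character_, powerlaw_best = NA,
          all_significant = NA
        ))
      }
      non_pl <- tab[tab$family_2 != "powerlaw", ]
      pl_best <- all(!is.na(non_pl$R)) && all(non_pl$R > 0)
      best <- if (pl_best) {
        "truncated_powerlaw"
      } else {
        losers <- non_pl[!is.na(non_pl$R) & non_pl$R < 0, ]
        if (nrow(losers)) losers$family_2[which.min(losers$R)] else "indeterminate"
      }
      tibble::tibble(
        n_arrays = n_arr, status = "ok", best_family = best,
        powerlaw_best = pl_best,
        all_significant = all(!is.na(tab$p_value)) && all(tab$p_value < sig_level)
      )
    }) |>
    dplyr::ungroup()
}

#' Proportion of groups best fit by a power law, by group size
#'
#' Aggregates a [per_group_best_fit()] table into the proportion of groups
#' (metagenomes) whose spacer counts are best described by a power-law
#' family, within logarithmic bins of group size (number of arrays).
#'
#' @param group_table Output of [per_group_best_fit()].
#' @param n_bins Number of logarithmic size bins.
#' @return A tibble: `bin_mid` (geometric bin midpoint), `n_groups`,
#'   `proportion`.
#' @export
best_fit_size_curve <- function(group_table, n_bins = 8) {
  ok <- group_table[group_table$status == "ok", ]
  if (nrow(ok) == 0L) {
    return(tibble::tibble(bin_mid = numeric(), n_groups = integer(),
                          proportion = numeric()))
  }
  brk <- exp(seq(log(min(ok$n_arrays)), log(max(ok$n_arrays) + 1),
                 length.out = n_bins + 1))
  ok |>
    dplyr::mutate(bin = cut(.data$n_arrays, breaks = unique(brk),
                            include.lowest = TRUE)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      bin_mid = exp(mean(log(.data$n_arrays))),
      n_groups = dplyr::n(),
      proportion = mean(.data$powerlaw_best),
      .groups = "drop"
    ) |>
    dplyr::select(-"bin")
}
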