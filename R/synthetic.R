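# Synthetic spacer-count datasets: collections of per-metagenome samples
# whose pooled counts follow a chosen generating distribution, plus
# non-heavy-tailed negative controls. These stand in for the large public
# metagenome/genome collections so every pipeline stage is testable offline.

default_habitat_mix <- function() {
  # proportions matching the habitat composition of the classified
  # metagenome collection
  n <- c(21, 2, 82, 344, 599, 503, 289, 275, 747, 152, 638, 56, 152)
  setNames(n / sum(n), habitat_types)
}

#' Generate a synthetic spacer-count dataset
#'
#' Draws per-array spacer counts i.i.d. from a generating distribution and
#' arranges them into per-metagenome samples with habitat labels, emulating
#' the structure of a metagenome collection. Fully deterministic under
#' `seed`.
#'
#' @param generator A [dist_spec()] for the per-array spacer counts (e.g.
#'   `dist_spec("truncated_powerlaw", alpha = 2.57, lam = 0.004)`).
#' @param n_metagenomes Number of samples.
#' @param arrays_per_metagenome Scalar or length-`n_metagenomes` vector of
#'   array counts per sample; `NULL` draws sizes log-uniformly from
#'   `size_range`.
#' @param habitat_mix Named vector of habitat proportions (summing to 1);
#'   defaults to the observed composition of the 13 habitat types.
#' @param seed Integer seed.
#' @param size_range Log-uniform range for per-sample array counts when
#'   `arrays_per_metagenome` is `NULL`.
#' @return A spacer-count tibble (`sample_id`, `habitat`, `array_id`,
#'   `spacer_count`).
#' @examples
#' gen <- dist_spec("truncated_powerlaw", alpha = 2.57, lam = 0.004)
#' d <- generate_spacer_dataset(gen, n_metagenomes = 5,
#'                              arrays_per_metagenome = 50, seed = 1)
#' @export
generate_spacer_dataset <- function(generator, n_metagenomes,
                                    arrays_per_metagenome = NULL,
                                    habitat_mix = NULL, seed = NULL,
                                    size_range = c(10, 10000)) {
  stopifnot(inherits(generator, "dist_spec"))
  if (n_metagenomes < 1) abort("`n_metagenomes` must be >= 1.", class = "spacerlaw_param_error")
  if (is.null(habitat_mix)) habitat_mix <- default_habitat_mix()
  if (abs(sum(habitat_mix) - 1) > 1e-8) {
    abort("`habitat_mix` proportions must sum to 1.", class = "spacerlaw_param_error")
  }
  if (!is.null(seed)) set.seed(seed)

  sizes <- if (is.null(arrays_per_metagenome)) {
    as.integer(round(exp(runif(n_metagenomes, log(size_range[1]), log(size_range[2])))))
  } else if (length(arrays_per_metagenome) == 1L) {
    rep(as.integer(arrays_per_metagenome), n_metagenomes)
  } else if (length(arrays_per_metagenome) == n_metagenomes) {
    as.integer(arrays_per_metagenome)
  } else {
    abort("`arrays_per_metagenome` must be scalar or length `n_metagenomes`.",
          class = "spacerlaw_param_error")
  }
  if (any(sizes < 1)) abort("Array counts must be >= 1.", class = "spacerlaw_param_error")

  habitats <- sample(names(habitat_mix), n_metagenomes, replace = TRUE,
                     prob = habitat_mix)
  counts <- dist_rand(generator, sum(sizes))
  out <- tibble::tibble(
    sample_id = rep(sprintf("MG%05d", seq_len(n_metagenomes)), sizes),
    habitat = rep(habitats, sizes),
    array_id = unlist(lapply(sizes, function(k) sprintf("A%06d", seq_len(k))),
                      use.names = FALSE),
    spacer_count = counts
  )
  attr(out, "provenance") <- "synthetic"
  out
}

#' Generate a non-heavy-tailed negative-control dataset
#'
#' Draws spacer counts from a light-tailed family (`lognormal`,
#' `exponential`, or `gaussian_rounded`, a rounded positive normal) so that
#' model-selection routines can be checked against data that should *not*
#' prefer a power law.
#'
#' @param family `"lognormal"`, `"exponential"` or `"gaussian_rounded"`.
#' @param params Named list of family parameters (`mu`/`sigma`, `lam`, or
#'   `mean`/`sd`).
#' @param n Number of arrays.
#' @param seed Integer seed.
#' @return A spacer-count tibble with a single control sample.
#' @examples
#' d <- generate_negative_control("gaussian_rounded",
#'                                list(mean = 12, sd = 4), n = 100, seed = 1)
#' @export
generate_negative_control <- function(family = c("lognormal", "exponential",
                                                 "gaussian_rounded"),
                                      params, n, seed = NULL) {
  family <- match.arg(family)
  if (n < 1) abort("`n` must be >= 1.", class = "spacerlaw_param_error")
  if (!is.null(seed)) set.seed(seed)
  counts <- switch(family,
    lognormal = dist_rand(dist_spec("lognormal", mu = params$mu,
                                    sigma = params$sigma), n),
    exponential = dist_rand(dist_spec("exponential", lam = params$lam), n),
    gaussian_rounded = {
      x <- integer(0)
      while (length(x) < n) {
        draw <- as.integer(round(rnorm(2L * (n - length(x)),
                                       params$mean, params$sd)))
        x <- c(x, draw[draw >= 1L])
      }
      x[seq_len(n)]
    }
  )
  out <- tibble::tibble(
    sample_id = "NC00001",
    habitat = "unclassified",
    array_id = sprintf("A%06d", seq_len(n)),
    spacer_count = counts
  )
  attr(out, "provenance") <- paste0("synthetic_negative_control_", family)
  out
}
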