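# Reading, writing and summarising per-array spacer-count tables. The
# canonical format is a 4-column TSV: sample_id, habitat, array_id,
# spacer_count (one row per CRISPR array).

#' Recognised habitat types
#'
#' The thirteen habitat labels used to classify metagenomic samples; any
#' other label is mapped to `"unclassified"` at ingest.
#' @export
habitat_types <- c(
  "Air", "Aquaculture", "Aquatic Sediment", "Engineered", "Fresh Water",
  "Host (human)", "Host (other)", "Host (plant)", "Marine",
  "Non-Marine Saline and Alkaline", "Terrestrial (soil)",
  "Terrestrial (other)", "Thermal Springs"
)

spacer_cols <- c("sample_id", "habitat", "array_id", "spacer_count")

validate_spacer_counts <- function(data, call_site = "spacer dataset") {
  missing <- setdiff(spacer_cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s.", call_site,
                  paste(missing, collapse = ", ")),
          class = "spacerlaw_format_error")
  }
  data <- tibble::as_tibble(data)[spacer_cols]
  if (nrow(data) == 0L) {
    abort("Empty spacer-count dataset.", class = "spacerlaw_format_error")
  }

  cnt <- suppressWarnings(as.numeric(data$spacer_count))
  bad <- is.na(cnt) | cnt < 1 | cnt != floor(cnt)
  if (any(bad)) {
    warn(sprintf("Rejected %d row(s) with missing, zero or non-integer spacer counts (rows: %s).",
                 sum(bad), paste(head(which(bad), 10), collapse = ", ")))
  }
  rejected <- data[bad, ]
  data <- data[!bad, ]
  data$spacer_count <- as.integer(cnt[!bad])
  if (nrow(data) == 0L) {
    abort("No valid rows left after filtering.", class = "spacerlaw_format_error")
  }

  unknown <- !(data$habitat %in% c(habitat_types, "unclassified"))
  if (any(unknown)) {
    warn(sprintf("Mapped %d unrecognised habitat label(s) to 'unclassified'.",
                 sum(unknown)))
    data$habitat[unknown] <- "unclassified"
  }

  if (anyDuplicated(data[c("sample_id", "array_id")])) {
    abort("Duplicate (sample_id, array_id) pairs in dataset.",
          class = "spacerlaw_format_error")
  }
  attr(data, "rejected") <- rejected
  data
}

#' Read a per-array spacer-count table
#'
#' Reads a tab-separated table with columns `sample_id`, `habitat`,
#' `array_id`, `spacer_count` (one CRISPR array per row). Rows with missing,
#' zero or non-integer counts are rejected with a warning (and returned in
#' the `"rejected"` attribute); habitat labels outside the thirteen
#' recognised types are mapped to `"unclassified"`.
#'
#' @param path Path to the TSV file.
#' @return A validated tibble of spacer-count records.
#' @export
read_spacer_counts <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "spacerlaw_io_error")
  }
  # parser chatter about absent columns is superseded by our own validation
  data <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    habitat = readr::col_character(),
    array_id = readr::col_character(),
    spacer_count = readr::col_double(),
    .default = readr::col_character()
  )))
  validate_spacer_counts(data, call_site = path)
}

#' Write a per-array spacer-count table
#'
#' Writes the canonical 4-column tab-separated representation (UTF-8, LF
#' line endings); the inverse of [read_spacer_counts()].
#'
#' @param data Spacer-count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spacer_counts <- function(data, path) {
  missing <- setdiff(spacer_cols, names(data))
  if (length(missing)) {
    abort(sprintf("Dataset is missing column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "spacerlaw_format_error")
  }
  readr::write_tsv(tibble::as_tibble(data)[spacer_cols], path)
  invisible(path)
}

#' Summary statistics of a spacer-count dataset
#'
#' Counts of samples, arrays and spacers plus the population mean, standard
#' deviation (denominator `n`) and maximum of the per-array spacer counts.
#'
#' @param data Spacer-count tibble.
#' @return A one-row tibble: `n_samples`, `n_arrays`, `n_spacers`, `mean`,
#'   `sd`, `max`.
#' @examples
#' d <- tibble::tibble(sample_id = "s1", habitat = "Marine",
#'                     array_id = c("a1", "a2", "a3"), spacer_count = 1:3)
#' summarize_spacers(d)
#' @export
summarize_spacers <- function(data) {
  if (nrow(data) == 0L) abort("Empty dataset.", class = "spacerlaw_param_error")
  x <- data$spacer_count
  tibble::tibble(
    n_samples = dplyr::n_distinct(data$sample_id),
    n_arrays = nrow(data),
    n_spacers = sum(x),
    mean = mean(x),
    sd = sqrt(mean((x - mean(x))^2)),
    max = max(x)
  )
}

#' Histogram of array sizes
#'
#' Exact integer counts of arrays per spacer number, optionally per group;
#' the counts always sum to the number of arrays.
#'
#' @param data Spacer-count tibble.
#' @param by Optional grouping column (`"sample_id"` or `"habitat"`).
#' @return A tibble with columns (`by`,) `spacer_count`, `n_arrays`.
#' @export
spacer_histogram <- function(data, by = NULL) {
  if (nrow(data) == 0L) abort("Empty dataset.", class = "spacerlaw_param_error")
  keys <- c(by, "spacer_count")
  data |>
    dplyr::count(dplyr::across(dplyr::all_of(keys)), name = "n_arrays") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}
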