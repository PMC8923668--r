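#' @keywords internal
#' @noRd
check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Read and write population activity tables
#'
#' CSV schema: `cell_id`, `induction`, `time_min`, `n_loci`, `nascent_cu`,
#' `mature_count` (plus any extra columns, preserved).
#'
#' @param path CSV file path.
#' @param cells a population data.frame as from [simulate_population()].
#' @return `read_population_csv` returns a validated data.frame;
#'   `write_population_csv` returns `path` invisibly.
#' @export
read_population_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("cell_id", "induction", "time_min", "n_loci",
                      "nascent_cu", "mature_count"), "population table")
  df
}

#' @rdname read_population_csv
#' @export
write_population_csv <- function(cells, path) {
  check_columns(cells, c("cell_id", "induction", "time_min", "n_loci",
                         "nascent_cu", "mature_count"), "population table")
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' Read and write smFISH spot tables
#'
#' CSV schema: `cell_id`, `spot_id`, `compartment`, `intensity_cu`
#' (optionally `nascent_flag`).
#'
#' @param path CSV file path.
#' @param spots a spot table data.frame.
#' @return `read_spot_table` returns a validated data.frame.
#' @export
read_spot_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("cell_id", "spot_id", "compartment", "intensity_cu"),
                "spot table")
  df
}

#' @rdname read_spot_table
#' @export
write_spot_table <- function(spots, path) {
  check_columns(spots, c("cell_id", "spot_id", "compartment", "intensity_cu"),
                "spot table")
  write.csv(spots, path, row.names = FALSE)
  invisible(path)
}

#' Read and write bulk qPCR time series
#'
#' CSV schema: `condition`, `induction`, `time_min`, `replicate`,
#' `mrna_per_cell`.
#'
#' @param path CSV file path.
#' @param series a bulk series data.frame.
#' @return `read_bulk_series` returns a validated data.frame.
#' @export
read_bulk_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("condition", "induction", "time_min", "replicate",
                      "mrna_per_cell"), "bulk series")
  df
}

#' @rdname read_bulk_series
#' @export
write_bulk_series <- function(series, path) {
  check_columns(series, c("condition", "induction", "time_min", "replicate",
                          "mrna_per_cell"), "bulk series")
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Read and write kinetic parameters and protocols as config files
#'
#' Plain key-value configuration, JSON (`.json`) or YAML (`.yaml`/`.yml`,
#' requires the `yaml` package).
#'
#' @param params a [kinetic_params].
#' @param protocol an [induction_protocol].
#' @param path file path; the extension selects the format.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "kinetic_params"))
  write_config(unclass(params), path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  do.call(kinetic_params, read_config(path))
}

#' @rdname write_params
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "induction_protocol"))
  seg <- protocol$segments[, c("duration_min", "hormone", "nup98_depleted",
                               "inhibitor")]
  write_config(list(segments = seg), path)
}

#' @rdname write_params
#' @export
read_protocol <- function(path) {
  x <- read_config(path)
  induction_protocol(as.data.frame(x$segments))
}

#' @keywords internal
#' @noRd
write_config <- function(x, path) {
  if (grepl("\\.(yaml|yml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML config files")
    }
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @keywords internal
#' @noRd
read_config <- function(path) {
  if (grepl("\\.(yaml|yml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML config files")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
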