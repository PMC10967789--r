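# Cohort CSV schema, configuration serialization, and the two orchestration
# entry points (compute on a cohort file, simulate a cohort). One strict CSV
# dialect: comma delimiter, dot decimal, mandatory header, '#' comment lines.

#' Write a cohort table to CSV
#'
#' Writes the documented dialect: '#' comment lines stating units, then a
#' header row and comma-separated values with dot decimals, full precision.
#'
#' @param cohort Cohort tibble (see `cohort_columns`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cohort <- cohort[, cohort_columns]
  cohort$sex <- toupper(as.character(cohort$sex))
  header <- c(
    "# ctdosim cohort table",
    "# units: age y; height, ap, lat cm; weight kg; bmi kg/m2;",
    "#        topogram_length, diagnostic_length mm; ctdi_vol mGy;",
    "#        dlp_topogram, dlp_diagnostic mGy.cm",
    "# dialect: comma delimiter, dot decimal, sex coded F/M")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(readr::format_csv(cohort), con, sep = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Strict dialect (comma delimiter, dot decimal, '#' comments, mandatory
#' header). A missing required column is a schema error; an unparseable
#' numeric cell invalidates only its row, which is reported (with its file
#' line number) in the `"row_errors"` attribute and via a warning while the
#' rest of the file loads. Sex is case-insensitive on read and canonicalised
#' to uppercase F/M.
#'
#' @param path Path to a cohort CSV.
#' @return Cohort tibble of valid rows; attribute `"row_errors"` holds a
#'   tibble (`line`, `id`, `field`, `value`) of rejected rows.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  is_data <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[is_data]
  line_no <- which(is_data)
  if (length(lines) < 1) stop("no header row found in ", path, call. = FALSE)
  # strict dialect: no quoting, so the field count is the comma count + 1;
  # a comma-decimal cell ("161,04") breaks the count and rejects its row
  n_fields <- lengths(strsplit(lines, ",", fixed = TRUE))
  malformed <- which(n_fields != n_fields[1])
  malformed <- malformed[malformed > 1]
  shape_errors <- tibble::tibble(
    line = line_no[malformed], id = NA_character_, field = NA_character_,
    value = sprintf("%d field(s), expected %d", n_fields[malformed],
                    n_fields[1]))
  if (length(malformed) > 0) {
    lines <- lines[-malformed]
    line_no <- line_no[-malformed]
  }
  tab <- readr::read_csv(I(paste0(lines, collapse = "\n")),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(cohort_columns, names(tab))
  if (length(missing_cols) > 0)
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0) stop("cohort file contains no data rows", call. = FALSE)
  data_lines <- line_no[-1]
  errs <- list()
  parsed <- tab
  for (col in numeric_cohort_columns) {
    x <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(x) & !is.na(tab[[col]]))
    for (i in bad)
      errs[[length(errs) + 1L]] <- tibble::tibble(
        line = data_lines[i], id = tab$id[i], field = col,
        value = tab[[col]][i])
    parsed[[col]] <- x
  }
  parsed$sex <- toupper(parsed$sex)
  row_errors <- dplyr::bind_rows(
    c(list(shape_errors,
           tibble::tibble(line = integer(), id = character(),
                          field = character(), value = character())),
      errs))
  if (nrow(row_errors) > 0) {
    warning(sprintf("%d row(s) dropped as unparseable (e.g. line %d, %s'%s'); remaining rows loaded",
                    length(unique(row_errors$line)), row_errors$line[1],
                    ifelse(is.na(row_errors$field[1]), "",
                           paste0("field ", row_errors$field[1], " = ")),
                    row_errors$value[1]), call. = FALSE)
    parsed <- parsed[!data_lines %in% row_errors$line, ]
  }
  out <- tibble::as_tibble(parsed[, cohort_columns])
  attr(out, "row_errors") <- row_errors
  out
}

#' Write / read a synthetic-cohort configuration as YAML
#'
#' The configuration round-trips unchanged (15 significant digits).
#'
#' @param config A [synthetic_config()].
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: a validated
#'   `synthetic_config`.
#' @export
write_config <- function(config, path) {
  validate_synthetic_config(config)
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  do.call(synthetic_config, cfg)
}

#' Analysis run configuration
#'
#' Bundles the choices that parameterise [run_compute()]; validated up front
#' and serialized next to the outputs for provenance.
#'
#' @param phantom Reference phantom for the k lookup.
#' @param protocol Protocol name for the f-factor (default `"chest"`).
#' @param dlp_source `"diagnostic"` or `"total"` (adds topogram DLP).
#' @param alpha Significance level for the statistical layer.
#' @param interpolation k lookup mode: `"table"` or `"fit"`.
#' @param phantom_diameter Audit reference diameter in cm.
#' @return Object of class `run_config`.
#' @export
run_config <- function(phantom = c("body_32cm", "head_16cm"),
                       protocol = "chest",
                       dlp_source = c("diagnostic", "total"),
                       alpha = 0.05,
                       interpolation = c("table", "fit"),
                       phantom_diameter = 32) {
  cfg <- list(phantom = match.arg(phantom), protocol = protocol,
              dlp_source = match.arg(dlp_source), alpha = alpha,
              interpolation = match.arg(interpolation),
              phantom_diameter = phantom_diameter)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  lookup_f(f_factor_table(), protocol) # fails early on unknown protocol
  if (!(phantom_diameter > 0))
    stop("phantom_diameter must be positive", call. = FALSE)
  structure(cfg, class = "run_config")
}

log_msg <- function(...) message("[ctdosim] ", sprintf(...))

summary_variables <- c("age", "height", "weight", "bmi", "ap", "lat",
                       "topogram_length", "diagnostic_length", "ctdi_vol",
                       "dlp_topogram", "dlp_diagnostic", "d_eff", "k",
                       "ssde", "dlp_ss", "ed", "delta_pct")

#' Run the full dosimetry analysis on a cohort file
#'
#' Reads a cohort CSV, derives the per-patient dose chain, and writes the
#' output bundle to `out_dir`: `derived.csv` (per-patient), `summary.csv`
#' (stratified mean/sd/range), `comparisons.csv` (sex comparisons, skipped
#' with a logged reason when a stratum is too small), `correlations.csv`
#' (Spearman matrix), `audit.csv`, and `run_config.yaml` (the configuration
#' that produced the bundle). Progress and every configuration decision are
#' logged to stderr.
#'
#' @param cohort_path Path to a cohort CSV (see [read_cohort()]).
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the derived tibble and the paths written.
#' @export
run_compute <- function(cohort_path, config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  cohort <- read_cohort(cohort_path)
  log_msg("read %d record(s) from %s", nrow(cohort), cohort_path)
  log_msg("phantom %s, protocol %s (f = %g mSv/(mGy.cm)), DLP source: %s, k lookup: %s",
          config$phantom, config$protocol,
          lookup_f(f_factor_table(), config$protocol), config$dlp_source,
          config$interpolation)
  derived <- derive_all(cohort,
                        k_table = conversion_table(config$phantom),
                        protocol = config$protocol,
                        dlp_source = config$dlp_source,
                        interpolation = config$interpolation)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(derived = file.path(out_dir, "derived.csv"))
  readr::write_csv(derived, paths$derived)
  have_both <- all(c("F", "M") %in% derived$sex) &&
    min(table(derived$sex)) >= 3 && nrow(derived) >= 6
  if (nrow(derived) >= 2) {
    paths$summary <- file.path(out_dir, "summary.csv")
    strata <- c("all", intersect(c("F", "M"), names(which(table(derived$sex) >= 2))))
    readr::write_csv(summarize_cohort(derived, summary_variables, strata),
                     paths$summary)
  } else {
    log_msg("skipping summary table: fewer than 2 records")
  }
  if (have_both) {
    paths$comparisons <- file.path(out_dir, "comparisons.csv")
    readr::write_csv(
      compare_by_sex(derived,
                     c("ctdi_vol", "ssde", "dlp_topogram", "dlp_diagnostic",
                       "dlp_ss", "ed", "d_eff", "diagnostic_length"),
                     alpha = config$alpha),
      paths$comparisons)
  } else {
    log_msg("skipping sex-comparison table: need >= 3 records per sex")
  }
  if (nrow(derived) >= 5 && all(table(derived$sex) >= 5)) {
    paths$correlations <- file.path(out_dir, "correlations.csv")
    readr::write_csv(spearman_matrix(derived), paths$correlations)
  } else {
    log_msg("skipping correlation table: need >= 5 records per stratum")
  }
  paths$audit <- file.path(out_dir, "audit.csv")
  audit <- audit_cohort(derived, config$phantom_diameter)
  readr::write_csv(
    dplyr::bind_cols(audit$scan_change, audit$size, n = audit$n),
    paths$audit)
  readr::write_csv(audit$length_to_height,
                   file.path(out_dir, "audit_length_to_height.csv"))
  yaml::write_yaml(unclass(config), file.path(out_dir, "run_config.yaml"),
                   precision = 15)
  log_msg("wrote output bundle to %s", out_dir)
  invisible(list(derived = derived, audit = audit, paths = paths))
}

#' Simulate a cohort to file
#'
#' Generates a synthetic cohort from a configuration (file path or object),
#' writes it in the cohort CSV schema, and writes the calibration report and
#' the serialized configuration alongside.
#'
#' @param config A [synthetic_config()] or path to its YAML serialization.
#' @param out_path Output CSV path; the calibration report is written next to
#'   it as `<stem>_calibration.csv`, the config as `<stem>_config.yaml`.
#' @param seed Optional master-seed override.
#' @return Invisibly, the generated cohort tibble.
#' @export
run_simulate <- function(config, out_path, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_synthetic_config(config)
  if (!is.null(seed)) config$seed <- seed
  cohort <- generate_cohort(config)
  write_cohort(cohort, out_path)
  stem <- sub("\\.csv$", "", out_path)
  readr::write_csv(calibration_report(cohort, config),
                   paste0(stem, "_calibration.csv"))
  write_config(config, paste0(stem, "_config.yaml"))
  log_msg("simulated %d records (seed %s) -> %s", nrow(cohort),
          format(config$seed), out_path)
  invisible(cohort)
}
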