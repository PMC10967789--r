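# Cohort layer: apply the per-study dose arithmetic to every record, then the
# statistical machinery (stratified summaries, normality-gated two-group
# tests, Spearman correlations, scan-length / size audit).

#' Required cohort-table columns
#'
#' Column schema of a cohort table: one row per study, units as written by
#' [write_cohort()] (lengths in mm, dimensions/height in cm, CTDIvol in mGy,
#' DLPs in mGy.cm).
#'
#' @format Character vector of column names.
#' @export
cohort_columns <- c("id", "sex", "age", "height", "weight", "bmi", "ap",
                    "lat", "topogram_length", "diagnostic_length", "ctdi_vol",
                    "dlp_topogram", "dlp_diagnostic")

numeric_cohort_columns <- setdiff(cohort_columns, c("id", "sex"))
# ctdi_vol and the DLPs may legitimately be zero (e.g. sub-threshold display);
# geometry must be strictly positive
nonneg_columns <- c("ctdi_vol", "dlp_topogram", "dlp_diagnostic")

#' Validate patient records
#'
#' Row-level validation of a cohort table: all physical quantities must be
#' positive (dose indices may be zero) and finite, sex must be F/M, ids must
#' be unique. BMI inconsistency with weight/height beyond 0.5 kg/m2 is
#' flagged but does not invalidate the record, since recorded BMI and
#' measured anthropometrics routinely disagree in registry extracts.
#'
#' @param records A data frame with the columns in `cohort_columns`.
#' @return A tibble of issues with columns `row`, `id`, `field`, `severity`
#'   (`"error"` or `"flag"`) and `message`; zero rows if the cohort is clean.
#' @export
validate_cohort <- function(records) {
  missing_cols <- setdiff(cohort_columns, names(records))
  if (length(missing_cols) > 0)
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  issues <- list()
  add <- function(rows, field, severity, msg) {
    if (length(rows) > 0)
      issues[[length(issues) + 1L]] <<- tibble::tibble(
        row = rows, id = as.character(records$id[rows]), field = field,
        severity = severity, message = msg)
  }
  if (anyDuplicated(records$id))
    add(which(duplicated(records$id)), "id", "error", "duplicate id")
  add(which(!toupper(as.character(records$sex)) %in% c("F", "M")),
      "sex", "error", "sex must be F or M")
  for (col in numeric_cohort_columns) {
    x <- records[[col]]
    bad <- if (col %in% nonneg_columns) !is.finite(x) | x < 0 else !is.finite(x) | x <= 0
    add(which(bad), col, "error",
        if (col %in% nonneg_columns) "must be non-negative and finite"
        else "must be strictly positive and finite")
  }
  ok_num <- is.finite(records$weight) & is.finite(records$height) &
    records$height > 0 & is.finite(records$bmi)
  bmi_calc <- records$weight / (records$height / 100)^2
  add(which(ok_num & abs(bmi_calc - records$bmi) > 0.5), "bmi", "flag",
      "recorded BMI differs from weight/(height/100)^2 by more than 0.5 kg/m2")
  if (length(issues) == 0)
    return(tibble::tibble(row = integer(), id = character(),
                          field = character(), severity = character(),
                          message = character()))
  dplyr::bind_rows(issues)
}

#' Derive the full per-patient dose chain for a cohort
#'
#' For every record computes the effective diameter, the conversion factor k
#' read from the phantom table, SSDE, the size-specific dose-length product,
#' effective dose, and the topogram-vs-diagnostic scan-length change.
#'
#' Records failing validation are dropped with a warning and reported in the
#' `"failures"` attribute of the result; the call errors only if no record
#' survives. BMI-consistency flags are attached as attribute `"flags"`.
#'
#' @param records Cohort data frame (see `cohort_columns`).
#' @param k_table A [conversion_table()]; default the 32-cm body phantom.
#' @param f_table An [f_factor_table()].
#' @param protocol Protocol name used to resolve the f-factor; default
#'   `"chest"` (f = 0.014 mSv/(mGy.cm)).
#' @param dlp_source `"diagnostic"` (default) uses the diagnostic-scan DLP
#'   for DLPss and ED; `"total"` adds the topogram DLP.
#' @param interpolation Passed to [lookup_k()] (`"table"` or `"fit"`).
#' @return A tibble: the input records (order preserved) joined with columns
#'   `d_eff`, `k`, `ssde`, `dlp_used`, `dlp_ss`, `ed`, `delta_mm`,
#'   `delta_pct`, `category`.
#' @export
derive_all <- function(records, k_table = conversion_table(),
                       f_table = f_factor_table(), protocol = "chest",
                       dlp_source = c("diagnostic", "total"),
                       interpolation = c("table", "fit")) {
  dlp_source <- match.arg(dlp_source)
  interpolation <- match.arg(interpolation)
  if (nrow(records) == 0) stop("cohort is empty", call. = FALSE)
  issues <- validate_cohort(records)
  errors <- issues[issues$severity == "error", ]
  flags <- issues[issues$severity == "flag", ]
  if (nrow(flags) > 0)
    warning(nrow(flags), " record(s) carry a BMI consistency flag",
            call. = FALSE)
  keep <- setdiff(seq_len(nrow(records)), unique(errors$row))
  if (length(keep) == 0)
    stop("all records failed validation; first issue: ", errors$message[1],
         " (id ", errors$id[1], ", field ", errors$field[1], ")",
         call. = FALSE)
  if (nrow(errors) > 0)
    warning("dropped ", length(unique(errors$row)),
            " invalid record(s); ids: ",
            paste(unique(errors$id), collapse = ", "), call. = FALSE)
  rec <- tibble::as_tibble(records[keep, ])
  rec$sex <- toupper(as.character(rec$sex))
  f <- lookup_f(f_table, protocol)
  d_eff <- effective_diameter(rec$ap, rec$lat)
  k <- lookup_k(k_table, d_eff, method = interpolation)
  dlp_used <- rec$dlp_diagnostic +
    if (dlp_source == "total") rec$dlp_topogram else 0
  out <- dplyr::bind_cols(
    rec,
    tibble::tibble(
      d_eff = d_eff, k = k,
      ssde = ssde(rec$ctdi_vol, k),
      dlp_used = dlp_used,
      dlp_ss = dlp_ss(dlp_used, k),
      ed = effective_dose(dlp_used, f)
    ),
    scan_length_change(rec$topogram_length, rec$diagnostic_length)
  )
  attr(out, "failures") <- errors
  attr(out, "flags") <- flags
  out
}

#' Stratified cohort summary
#'
#' Mean, sample standard deviation (n-1 denominator), range and n for the
#' requested variables, in the `all`, `F` and `M` strata.
#'
#' @param data A cohort or derived-dose tibble with a `sex` column.
#' @param variables Character vector of numeric column names.
#' @param strata Which strata to report; any of `"all"`, `"F"`, `"M"`.
#' @return Tibble with columns `stratum`, `variable`, `n`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
summarize_cohort <- function(data, variables,
                             strata = c("all", "F", "M")) {
  strata <- match.arg(strata, several.ok = TRUE)
  rows <- lapply(strata, function(s) {
    d <- if (s == "all") data else data[data$sex == s, ]
    if (nrow(d) < 2)
      stop("stratum '", s, "' has fewer than 2 records", call. = FALSE)
    dplyr::bind_rows(lapply(variables, function(v) {
      x <- d[[v]]
      if (is.null(x)) stop("unknown variable '", v, "'", call. = FALSE)
      tibble::tibble(stratum = s, variable = v, n = length(x),
                     mean = mean(x), sd = stats::sd(x),
                     min = min(x), max = max(x))
    }))
  })
  dplyr::bind_rows(rows)
}

#' Normality-gated two-group comparison
#'
#' Applies the Shapiro-Wilk test to each group; if both groups are compatible
#' with normality at `alpha`, the groups are compared with a two-sided
#' Student's t-test (equal variances by default), otherwise with a two-sided
#' Mann-Whitney U test. A degenerate (all-identical) group, for which the
#' Shapiro-Wilk statistic is undefined, falls through to the Mann-Whitney
#' path with a warning.
#'
#' @param values_f,values_m Numeric vectors (e.g. female and male values),
#'   each of length >= 3.
#' @param alpha Normality-gate significance level (default 0.05).
#' @param var_equal Use the equal-variance t statistic (default TRUE); set
#'   FALSE for Welch.
#' @param variable Optional variable name carried into the result.
#' @return One-row tibble: `variable`, `test_used` (`"student_t"` or
#'   `"mann_whitney"`), `statistic`, `p_value`, `normality_p_f`,
#'   `normality_p_m`, `n_f`, `n_m`.
#' @export
compare_groups <- function(values_f, values_m, alpha = 0.05,
                           var_equal = TRUE, variable = NA_character_) {
  if (length(values_f) < 3 || length(values_m) < 3)
    stop("each group needs at least 3 observations", call. = FALSE)
  shapiro_p <- function(x) {
    if (length(unique(x)) == 1) {
      warning("degenerate group (all values identical); ",
              "normality test undefined, using Mann-Whitney", call. = FALSE)
      return(NA_real_)
    }
    stats::shapiro.test(x)$p.value
  }
  p_f <- shapiro_p(values_f)
  p_m <- shapiro_p(values_m)
  normal <- !is.na(p_f) && !is.na(p_m) && p_f >= alpha && p_m >= alpha
  if (normal) {
    ht <- stats::t.test(values_f, values_m, var.equal = var_equal)
    test_used <- "student_t"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(values_f, values_m, exact = FALSE, correct = TRUE))
    test_used <- "mann_whitney"
  }
  tibble::tibble(variable = variable, test_used = test_used,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 normality_p_f = p_f, normality_p_m = p_m,
                 n_f = length(values_f), n_m = length(values_m))
}

#' Sex comparison for several variables
#'
#' Runs [compare_groups()] (F vs M) for each requested variable.
#'
#' @inheritParams summarize_cohort
#' @inheritParams compare_groups
#' @return Tibble with one row per variable.
#' @export
compare_by_sex <- function(data, variables, alpha = 0.05, var_equal = TRUE) {
  dplyr::bind_rows(lapply(variables, function(v) {
    compare_groups(data[[v]][data$sex == "F"], data[[v]][data$sex == "M"],
                   alpha = alpha, var_equal = var_equal, variable = v)
  }))
}

#' Spearman correlations of a target with a set of covariates
#'
#' Rank correlation (average-rank tie handling) of `target` with each
#' covariate, per stratum. A constant target or covariate makes the rank
#' correlation undefined; it is reported as NA with a reason rather than
#' dropped silently.
#'
#' @param data Derived-dose tibble (must contain `sex`, the target and all
#'   covariates).
#' @param target Target variable (default `"ctdi_vol"`).
#' @param covariates Covariate names; default the anthropometric set plus
#'   effective diameter and diagnostic scan length.
#' @param strata Any of `"all"`, `"F"`, `"M"`.
#' @return Tibble: `stratum`, `target`, `covariate`, `n`, `rho`, `p_value`,
#'   `note`.
#' @export
spearman_matrix <- function(data, target = "ctdi_vol",
                            covariates = c("age", "weight", "height", "bmi",
                                           "lat", "ap", "d_eff",
                                           "diagnostic_length"),
                            strata = c("all", "F", "M")) {
  strata <- match.arg(strata, several.ok = TRUE)
  dplyr::bind_rows(lapply(strata, function(s) {
    d <- if (s == "all") data else data[data$sex == s, ]
    if (nrow(d) < 5)
      stop("stratum '", s, "' has fewer than 5 records", call. = FALSE)
    y <- d[[target]]
    dplyr::bind_rows(lapply(covariates, function(v) {
      x <- d[[v]]
      if (is.null(x)) stop("unknown covariate '", v, "'", call. = FALSE)
      if (length(unique(x)) == 1 || length(unique(y)) == 1) {
        return(tibble::tibble(stratum = s, target = target, covariate = v,
                              n = length(x), rho = NA_real_,
                              p_value = NA_real_,
                              note = "constant variable; rank correlation undefined"))
      }
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE))
      tibble::tibble(stratum = s, target = target, covariate = v,
                     n = length(x), rho = unname(ct$estimate),
                     p_value = ct$p.value, note = NA_character_)
    }))
  }))
}

ratio_of_means_pct <- function(length_mm, height_cm) {
  100 * mean(length_mm) / (10 * mean(height_cm))
}

#' Cohort audit: scan-length changes, size vs phantom, length-to-height
#'
#' Descriptive audit of a derived cohort: the percentage of studies whose
#' diagnostic scan was shortened / unchanged / extended relative to the
#' topogram; the percentage of patients whose effective diameter lies below
#' vs above the reference phantom diameter (ties counted as "below"); and
#' scan-length-to-height ratios per stratum. Ratios are reported under two
#' conventions: ratio of means (mean length over mean height, the default
#' headline figure) and mean of per-patient ratios.
#'
#' @param derived Output of [derive_all()].
#' @param phantom_diameter Reference phantom diameter in cm (default 32).
#' @return List of class `cohort_audit`: `scan_change` (tibble of
#'   percentages), `size` (tibble), `length_to_height` (tibble per stratum
#'   and scan type, both conventions), `n`.
#' @export
audit_cohort <- function(derived, phantom_diameter = 32) {
  if (nrow(derived) == 0) stop("cohort is empty", call. = FALSE)
  n <- nrow(derived)
  pct <- function(lgl) 100 * sum(lgl) / n
  scan_change <- tibble::tibble(
    pct_shortened = pct(derived$category == "shortened"),
    pct_unchanged = pct(derived$category == "unchanged"),
    pct_extended = pct(derived$category == "extended")
  )
  size <- tibble::tibble(
    phantom_diameter_cm = phantom_diameter,
    pct_deff_below_phantom = pct(derived$d_eff <= phantom_diameter),
    pct_deff_above_phantom = pct(derived$d_eff > phantom_diameter)
  )
  strata <- c("all", intersect(c("F", "M"), unique(derived$sex)))
  lth <- dplyr::bind_rows(lapply(strata, function(s) {
    d <- if (s == "all") derived else derived[derived$sex == s, ]
    dplyr::bind_rows(lapply(
      c(topogram = "topogram_length", diagnostic = "diagnostic_length"),
      function(col) {
        tibble::tibble(
          stratum = s,
          scan = sub("_length$", "", col),
          ratio_of_means_pct = ratio_of_means_pct(d[[col]], d$height),
          mean_of_ratios_pct = mean(100 * d[[col]] / (10 * d$height))
        )
      }))
  }))
  structure(list(scan_change = scan_change, size = size,
                 length_to_height = lth, n = n),
            class = "cohort_audit")
}

#' @export
print.cohort_audit <- function(x, ...) {
  cat(sprintf("<cohort_audit> n = %d\n", x$n))
  cat(sprintf("  scan length: %.1f%% shortened, %.1f%% unchanged, %.1f%% extended\n",
              x$scan_change$pct_shortened, x$scan_change$pct_unchanged,
              x$scan_change$pct_extended))
  cat(sprintf("  effective diameter vs %g cm phantom: %.1f%% below, %.1f%% above\n",
              x$size$phantom_diameter_cm, x$size$pct_deff_below_phantom,
              x$size$pct_deff_above_phantom))
  print(x$length_to_height)
  invisible(x)
}
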