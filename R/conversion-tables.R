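# Size-conversion-factor tables (AAPM Report 204) and protocol f-factors
# (AAPM Report 96). Tables ship as plain-text files under inst/extdata; the
# published exponential fit is stored alongside as a cross-check and as an
# optional continuous lookup.

ctdosim_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ctdosim")
  if (!nzchar(path)) stop("missing package data file: ", file, call. = FALSE)
  path
}

#' Load a size-conversion-factor table
#'
#' Returns the monotone map from effective diameter to the conversion factor
#' k for a named reference phantom, as tabulated in AAPM Report 204 for the
#' 32-cm body phantom (chest/abdomen protocols) or the 16-cm head phantom.
#' The object carries the tabulated knots plus the report's exponential-fit
#' coefficients \eqn{k = a e^{-b d}} used for cross-validation.
#'
#' @param phantom `"body_32cm"` (default) or `"head_16cm"`.
#' @return An object of class `conversion_table` with elements `phantom`,
#'   `points` (tibble with `d_eff_cm`, `k`) and `fit` (named vector `a`, `b`).
#' @export
conversion_table <- function(phantom = c("body_32cm", "head_16cm")) {
  phantom <- match.arg(phantom)
  file <- switch(phantom,
    body_32cm = "aapm204_k_body_32cm.tsv",
    head_16cm = "aapm204_k_head_16cm.tsv"
  )
  pts <- utils::read.table(ctdosim_extdata(file), header = TRUE, sep = "\t",
                           comment.char = "#")
  fit <- yaml::read_yaml(ctdosim_extdata("aapm204_fits.yaml"))[[phantom]]
  new_conversion_table(phantom, tibble::as_tibble(pts),
                       c(a = fit$a, b = fit$b))
}

new_conversion_table <- function(phantom, points, fit = NULL) {
  stopifnot(is.data.frame(points),
            all(c("d_eff_cm", "k") %in% names(points)))
  if (nrow(points) == 0) stop("conversion table is empty", call. = FALSE)
  if (any(diff(points$d_eff_cm) <= 0))
    stop("conversion table diameters must be strictly increasing", call. = FALSE)
  if (any(diff(points$k) >= 0))
    stop("conversion factors must be strictly decreasing in diameter",
         call. = FALSE)
  structure(list(phantom = phantom, points = tibble::as_tibble(points),
                 fit = fit),
            class = "conversion_table")
}

#' @export
print.conversion_table <- function(x, ...) {
  cat(sprintf("<conversion_table> phantom %s, %d knots, d_eff %g-%g cm\n",
              x$phantom, nrow(x$points), min(x$points$d_eff_cm),
              max(x$points$d_eff_cm)))
  if (!is.null(x$fit))
    cat(sprintf("  fit: k = %.6f * exp(-%.8f * d)\n", x$fit["a"], x$fit["b"]))
  invisible(x)
}

#' Look up the size conversion factor k for an effective diameter
#'
#' Linear interpolation between the bracketing tabulated diameters; at a
#' tabulated diameter the table entry is returned exactly. Outside the
#' tabulated range the value is clamped to the nearest endpoint with a
#' warning (extrapolating the fit would eventually yield k well below any
#' measured value). With `method = "fit"` the report's exponential model is
#' evaluated instead of the table.
#'
#' @param table A [conversion_table()].
#' @param d_eff Effective diameter(s) in cm, strictly positive.
#' @param method `"table"` (interpolate the tabulated knots, default) or
#'   `"fit"` (evaluate the exponential model).
#' @return Conversion factor(s) k, dimensionless.
#' @export
lookup_k <- function(table, d_eff, method = c("table", "fit")) {
  if (!inherits(table, "conversion_table"))
    stop("`table` must be a conversion_table", call. = FALSE)
  method <- match.arg(method)
  check_positive(d_eff, "d_eff")
  d <- table$points$d_eff_cm
  if (any(d_eff < min(d) | d_eff > max(d))) {
    warning(sprintf(
      "effective diameter outside tabulated range [%g, %g] cm; clamping to nearest endpoint",
      min(d), max(d)), call. = FALSE)
    d_eff <- pmin(pmax(d_eff, min(d)), max(d))
  }
  if (method == "fit") {
    if (is.null(table$fit)) stop("table carries no fit coefficients", call. = FALSE)
    return(unname(table$fit["a"] * exp(-table$fit["b"] * d_eff)))
  }
  stats::approx(d, table$points$k, xout = d_eff, method = "linear",
                ties = "ordered")$y
}

#' Load the protocol f-factor table
#'
#' DLP-to-effective-dose conversion coefficients per protocol/anatomic region
#' (adult values, AAPM Report 96); chest is 0.014 mSv/(mGy.cm).
#'
#' @return Named list of coefficients in mSv/(mGy.cm), class `f_factor_table`.
#' @export
f_factor_table <- function() {
  tab <- yaml::read_yaml(ctdosim_extdata("f_factors.yaml"))
  stopifnot(all(unlist(tab) > 0))
  structure(tab, class = "f_factor_table")
}

#' Resolve an f-factor by protocol name
#'
#' @param table An [f_factor_table()].
#' @param protocol Protocol name, e.g. `"chest"`.
#' @return f in mSv/(mGy.cm).
#' @export
lookup_f <- function(table, protocol) {
  if (!inherits(table, "f_factor_table"))
    stop("`table` must be an f_factor_table", call. = FALSE)
  if (length(protocol) != 1 || !protocol %in% names(table))
    stop("unknown protocol '", paste(protocol, collapse = ","),
         "'; known protocols: ", paste(names(table), collapse = ", "),
         call. = FALSE)
  table[[protocol]]
}

#' Cross-validate the exponential fit against the tabulated knots
#'
#' @param table A [conversion_table()].
#' @return Maximum relative deviation |fit - table| / table over the knots.
#' @export
fit_table_deviation <- function(table) {
  if (is.null(table$fit)) stop("table carries no fit coefficients", call. = FALSE)
  k_fit <- table$fit["a"] * exp(-table$fit["b"] * table$points$d_eff_cm)
  max(abs(k_fit - table$points$k) / table$points$k)
}
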