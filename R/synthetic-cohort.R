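# Calibrated synthetic chest-CT cohort generator.
#
# The generator reproduces the statistical structure the analysis layer
# assumes: per-sex anthropometric marginals, a Gaussian-copula rank coupling
# between BMI and effective diameter, an exponential (ATCM-like) dose-vs-size
# model with multiplicative lognormal noise, and a clipped-normal
# scan-length-change model. Only marginal summaries and rank correlations are
# calibrated; the Gaussian copula is the minimal joint structure consistent
# with them.

#' Synthetic cohort configuration
#'
#' Full parameterisation of the synthetic-cohort generator. Every argument
#' has a default calibrated to a retrospective adult chest-CT service cohort
#' (134 studies, 68 female / 66 male); pass `n_female`/`n_male` or any target
#' to override. All `mean`/`sd` pairs are targets for the *realized* cohort
#' (truncation and clipping shifts are corrected internally by location
#' adjustment).
#'
#' @param n_female,n_male Number of records per sex (>= 2).
#' @param female,male Per-sex target lists; see [sex_targets()] for the
#'   structure and defaults.
#' @param bmi_range Inclusion window for BMI in kg/m2; draws outside are
#'   rejected (default 18-35, mirroring common obesity/underweight exclusion
#'   criteria).
#' @param height_bmi_cor Latent correlation between height and BMI (default 0).
#' @param rho_bmi_deff_pooled Whole-group BMI-Deff Spearman calibration
#'   *check* target (the pooled value is an emergent property of the per-sex
#'   couplings, not a generation knob; see the methods vignette).
#' @param aspect_ratio AP/LAT ratio model: `mean`, `sd`, `min`, `max`.
#' @param topo_height_ratio Topogram-length-to-height ratio model: `mean`,
#'   `sd` (dimensionless; length mm / height mm).
#' @param delta_pct Scan-length change model in percent of the topogram
#'   length: `mean`, `sd`, `min`, `max` (draws are clipped to \[min, max\]).
#' @param dlp_diagnostic_mean,dlp_topogram_mean Pooled-cohort target means in
#'   mGy.cm used to solve the DLP efficiency factor and the topogram dose
#'   fraction.
#' @param seed Master seed; per-stage child streams are derived from it, so
#'   adding a stage never perturbs earlier draws.
#' @return Object of class `synthetic_config` (a validated nested list that
#'   round-trips through YAML serialization unchanged).
#' @export
synthetic_config <- function(n_female = 68, n_male = 66,
                             female = sex_targets("F"),
                             male = sex_targets("M"),
                             bmi_range = list(min = 18, max = 35),
                             height_bmi_cor = 0,
                             rho_bmi_deff_pooled = 0.77,
                             aspect_ratio = list(mean = 0.73, sd = 0.03,
                                                 min = 0.5, max = 0.95),
                             topo_height_ratio = list(mean = 0.2299,
                                                      sd = 0.025),
                             delta_pct = list(mean = 4.54, sd = 11.35,
                                              min = -27.2, max = 36.86),
                             dlp_diagnostic_mean = 286.51,
                             dlp_topogram_mean = 5.28,
                             seed = 42) {
  cfg <- list(n_female = n_female, n_male = n_male, female = female,
              male = male, bmi_range = bmi_range,
              height_bmi_cor = height_bmi_cor,
              rho_bmi_deff_pooled = rho_bmi_deff_pooled,
              aspect_ratio = aspect_ratio,
              topo_height_ratio = topo_height_ratio, delta_pct = delta_pct,
              dlp_diagnostic_mean = dlp_diagnostic_mean,
              dlp_topogram_mean = dlp_topogram_mean, seed = seed)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

#' Default per-sex calibration targets
#'
#' Age in years, height in cm, BMI in kg/m2, effective diameter in cm,
#' CTDIvol in mGy (32-cm phantom reference); `rho_*` are Spearman
#' rank-correlation targets.
#'
#' @param sex `"F"` or `"M"`.
#' @return Named list of target sublists, each `list(mean =, sd =)`, plus the
#'   two rank targets.
#' @export
sex_targets <- function(sex = c("F", "M")) {
  sex <- match.arg(sex)
  if (sex == "F") {
    list(age = list(mean = 65.89, sd = 12.91),
         height = list(mean = 161.04, sd = 5.97),
         bmi = list(mean = 26.88, sd = 5.70),
         d_eff = list(mean = 28.74, sd = 3.43),
         ctdi_vol = list(mean = 7.38, sd = 3.23),
         rho_bmi_deff = 0.82, rho_ctdi_deff = 0.79)
  } else {
    list(age = list(mean = 63.15, sd = 13.15),
         height = list(mean = 175.8, sd = 7.10),
         bmi = list(mean = 27.8, sd = 5.93),
         d_eff = list(mean = 31.13, sd = 3.05),
         ctdi_vol = list(mean = 8.30, sd = 2.49),
         rho_bmi_deff = 0.90, rho_ctdi_deff = 0.87)
  }
}

validate_synthetic_config <- function(cfg) {
  problems <- character()
  need <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  need(cfg$n_female >= 2, "n_female must be >= 2")
  need(cfg$n_male >= 2, "n_male must be >= 2")
  for (s in c("female", "male")) {
    t <- cfg[[s]]
    for (v in c("age", "height", "bmi", "d_eff", "ctdi_vol")) {
      need(is.numeric(t[[v]]$mean) && t[[v]]$mean > 0,
           paste0(s, "$", v, "$mean must be positive"))
      need(is.numeric(t[[v]]$sd) && t[[v]]$sd >= 0,
           paste0(s, "$", v, "$sd must be >= 0"))
    }
    for (r in c("rho_bmi_deff", "rho_ctdi_deff"))
      need(abs(t[[r]]) < 1,
           paste0(s, "$", r, ": infeasible rank target (|rho| must be < 1)"))
    need(t$bmi$mean > cfg$bmi_range$min && t$bmi$mean < cfg$bmi_range$max,
         paste0(s, "$bmi$mean must lie inside bmi_range"))
  }
  need(cfg$bmi_range$min < cfg$bmi_range$max, "bmi_range: min < max required")
  need(abs(cfg$height_bmi_cor) < 1, "height_bmi_cor must be in (-1, 1)")
  need(cfg$aspect_ratio$sd >= 0 && cfg$aspect_ratio$mean > 0 &&
         cfg$aspect_ratio$min > 0 && cfg$aspect_ratio$max < 1.5 &&
         cfg$aspect_ratio$min <= cfg$aspect_ratio$mean &&
         cfg$aspect_ratio$mean <= cfg$aspect_ratio$max,
       "aspect_ratio: need 0 < min <= mean <= max and sd >= 0")
  need(cfg$topo_height_ratio$mean > 0 && cfg$topo_height_ratio$sd >= 0,
       "topo_height_ratio: mean > 0 and sd >= 0 required")
  need(cfg$delta_pct$sd >= 0 &&
         cfg$delta_pct$min <= cfg$delta_pct$mean &&
         cfg$delta_pct$mean <= cfg$delta_pct$max &&
         cfg$delta_pct$min > -100,
       "delta_pct: need min <= mean <= max, sd >= 0, min > -100")
  need(cfg$dlp_diagnostic_mean > 0, "dlp_diagnostic_mean must be positive")
  need(cfg$dlp_topogram_mean > 0, "dlp_topogram_mean must be positive")
  need(is.numeric(cfg$seed) && length(cfg$seed) == 1,
       "seed must be a single number")
  if (length(problems) > 0)
    stop("invalid synthetic_config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> n = %d F + %d M, seed %s\n",
              x$n_female, x$n_male, format(x$seed)))
  cat(sprintf("  BMI window [%g, %g]; rank targets BMI~Deff %.2f F / %.2f M, CTDI~Deff %.2f F / %.2f M\n",
              x$bmi_range$min, x$bmi_range$max, x$female$rho_bmi_deff,
              x$male$rho_bmi_deff, x$female$rho_ctdi_deff,
              x$male$rho_ctdi_deff))
  invisible(x)
}

# Spearman target -> latent Pearson correlation of the Gaussian copula
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# mean of a normal *truncated* to [lo, hi]
truncated_normal_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# mean of a normal *clipped* (not truncated) to [lo, hi]
clipped_normal_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  lo * pnorm(a) + hi * (1 - pnorm(b)) + mu * (pnorm(b) - pnorm(a)) -
    sd * (dnorm(b) - dnorm(a))
}

# location adjustment: find mu such that fn(mu) == target
solve_location <- function(fn, target, sd) {
  if (sd == 0) return(target)
  uniroot(function(m) fn(m) - target,
          interval = target + c(-6, 6) * max(sd, 1e-6), extendInt = "yes",
          tol = 1e-10)$root
}

#' Solved generator coefficients
#'
#' Deterministically derives, from a configuration's calibration targets, the
#' internal model coefficients the generator uses: the location-adjusted BMI
#' and scan-change means (so truncation/clipping do not shift the realized
#' means), the per-sex dose model \eqn{CTDI_{vol} = c_0 e^{g (D_{eff} - 32)}
#' \varepsilon} with lognormal noise (solved from the CTDIvol mean/sd and the
#' CTDI-Deff rank target), the DLP efficiency factor and the topogram dose
#' fraction (solved so the expected pooled DLP means hit their targets).
#'
#' @param config A [synthetic_config()].
#' @return Nested list: per-sex `bmi_mu_adj`, `c0` (mGy), `g` (per cm),
#'   `sigma` (log-scale noise sd); shared `delta_mu_adj`, `dlp_efficiency`,
#'   `topo_dlp_fraction`.
#' @export
generator_coefficients <- function(config) {
  validate_synthetic_config(config)
  per_sex <- lapply(list(female = config$female, male = config$male),
                    function(t) {
    bmi_mu_adj <- solve_location(
      function(m) truncated_normal_mean(m, t$bmi$sd, config$bmi_range$min,
                                        config$bmi_range$max),
      t$bmi$mean, t$bmi$sd)
    mu_c <- t$ctdi_vol$mean; sd_c <- t$ctdi_vol$sd
    s2 <- log(1 + (sd_c / mu_c)^2)
    s <- sqrt(s2)
    rho_p <- spearman_to_pearson(t$rho_ctdi_deff)
    if (t$d_eff$sd > 0 && s > 0) {
      g <- rho_p * s / t$d_eff$sd
      sigma <- sqrt(1 - rho_p^2) * s
    } else {
      g <- 0
      sigma <- s
    }
    m <- log(mu_c) - s2 / 2
    list(bmi_mu_adj = bmi_mu_adj, c0 = exp(m - g * (t$d_eff$mean - 32)),
         g = g, sigma = sigma)
  })
  dp <- config$delta_pct
  delta_mu_adj <- solve_location(
    function(m) clipped_normal_mean(m, dp$sd, dp$min, dp$max), dp$mean, dp$sd)
  # expected diagnostic length (mm) per sex, pre-rounding
  e_diag <- function(t) 10 * t$height$mean * config$topo_height_ratio$mean *
    (1 + dp$mean / 100)
  e_topo <- function(t) 10 * t$height$mean * config$topo_height_ratio$mean
  n_f <- config$n_female; n_m <- config$n_male
  e_dlp_unit <- (n_f * config$female$ctdi_vol$mean * e_diag(config$female) +
                 n_m * config$male$ctdi_vol$mean * e_diag(config$male)) /
    (10 * (n_f + n_m))
  e_topo_unit <- (n_f * config$female$ctdi_vol$mean * e_topo(config$female) +
                  n_m * config$male$ctdi_vol$mean * e_topo(config$male)) /
    (10 * (n_f + n_m))
  c(per_sex,
    list(delta_mu_adj = delta_mu_adj,
         dlp_efficiency = config$dlp_diagnostic_mean / e_dlp_unit,
         topo_dlp_fraction = config$dlp_topogram_mean / e_topo_unit))
}

# deterministic child seed per (master seed, stage label); adding a stage
# never perturbs the streams of existing stages
child_seed <- function(master, label) {
  h <- 17
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + round(as.numeric(master)) %% 2147483647 * 31) %% 2147483647)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

generate_sex <- function(sex, n, targets, config, coef) {
  stage <- function(label) child_seed(config$seed, paste0(sex, "/", label))
  lo <- config$bmi_range$min; hi <- config$bmi_range$max
  h_mu <- targets$height$mean; h_sd <- targets$height$sd
  b_sd <- targets$bmi$sd; b_mu <- coef$bmi_mu_adj
  rho_hb <- config$height_bmi_cor

  # (1) height + BMI from a bivariate normal, BMI rejected outside the window
  set.seed(stage("anthro"))
  height <- numeric(0); bmi <- numeric(0)
  if (b_sd == 0) {
    if (b_mu < lo || b_mu > hi)
      stop("degenerate BMI outside inclusion window", call. = FALSE)
    height <- h_mu + h_sd * rnorm(n)
    bmi <- rep(b_mu, n)
  } else {
    while (length(bmi) < n) {
      m <- max(2L * n, 64L)
      zh <- rnorm(m)
      zb <- rho_hb * zh + sqrt(1 - rho_hb^2) * rnorm(m)
      b <- b_mu + b_sd * zb
      keep <- b >= lo & b <= hi
      height <- c(height, (h_mu + h_sd * zh)[keep])
      bmi <- c(bmi, b[keep])
    }
    height <- height[seq_len(n)]
    bmi <- bmi[seq_len(n)]
  }
  weight <- bmi * (height / 100)^2

  # (2) effective diameter via Gaussian copula against BMI
  set.seed(stage("deff"))
  if (b_sd > 0) {
    p_lo <- pnorm(lo, b_mu, b_sd); p_hi <- pnorm(hi, b_mu, b_sd)
    v <- (pnorm(bmi, b_mu, b_sd) - p_lo) / (p_hi - p_lo)
    z1 <- qnorm(clip(v, 1e-12, 1 - 1e-12))
  } else {
    z1 <- rep(0, n)
  }
  rho_p <- spearman_to_pearson(targets$rho_bmi_deff)
  zd <- rho_p * z1 + sqrt(1 - rho_p^2) * rnorm(n)
  d_eff <- targets$d_eff$mean + targets$d_eff$sd * zd

  # (3) split Deff into AP/LAT at a near-constant aspect ratio, exactly
  # preserving sqrt(ap * lat) == d_eff
  set.seed(stage("aspect"))
  ar <- config$aspect_ratio
  r <- clip(ar$mean + ar$sd * rnorm(n), ar$min, ar$max)
  ap <- d_eff * sqrt(r)
  lat <- d_eff / sqrt(r)

  # (4) ATCM-like dose model: exponential in size, lognormal noise
  set.seed(stage("ctdi"))
  ctdi <- exp(log(coef$c0) + coef$g * (d_eff - 32) + coef$sigma * rnorm(n))

  # (5) scan geometry: topogram from height, diagnostic from clipped-normal
  # percent change; lengths reported in whole mm as on dose reports
  set.seed(stage("length"))
  tr <- config$topo_height_ratio
  ratio <- clip(tr$mean + tr$sd * rnorm(n), 0.05, 0.6)
  topo <- pmax(1, round(10 * height * ratio))
  dp <- config$delta_pct
  delta <- clip(coef$delta_mu_adj + dp$sd * rnorm(n), dp$min, dp$max)
  diag_len <- pmax(1, round(topo * (1 + delta / 100)))

  # (6) dose-length products
  dlp_diag <- coef$dlp_efficiency * ctdi * diag_len / 10
  dlp_topo <- coef$topo_dlp_fraction * ctdi * topo / 10

  set.seed(stage("age"))
  age <- clip(targets$age$mean + targets$age$sd * rnorm(n), 18, 105)

  tibble::tibble(sex = sex, age = age, height = height, weight = weight,
                 bmi = bmi, ap = ap, lat = lat, topogram_length = topo,
                 diagnostic_length = diag_len, ctdi_vol = ctdi,
                 dlp_topogram = dlp_topo, dlp_diagnostic = dlp_diag)
}

#' Generate a synthetic chest-CT cohort
#'
#' Deterministic for a fixed configuration (the master seed is part of the
#' configuration): per-sex pipeline drawing anthropometrics, effective
#' diameter coupled to BMI through a Gaussian copula, AP/LAT split at a
#' near-constant aspect ratio, an exponential dose-vs-size CTDIvol model,
#' scan lengths, and dose-length products.
#'
#' @param config A [synthetic_config()].
#' @return A cohort tibble with the columns in `cohort_columns`, females
#'   first, ids `P0001`, `P0002`, ...
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  coef <- generator_coefficients(config)
  shared <- coef[c("delta_mu_adj", "dlp_efficiency", "topo_dlp_fraction")]
  out <- dplyr::bind_rows(
    generate_sex("F", config$n_female, config$female, config,
                 c(coef$female, shared)),
    generate_sex("M", config$n_male, config$male, config,
                 c(coef$male, shared))
  )
  out <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("P%04d", seq_len(nrow(out)))), out)
  out[, cohort_columns]
}

#' Calibration report: configured targets vs realized cohort
#'
#' One row per calibration target (per-sex means, rank correlations, the
#' pooled BMI-Deff rank correlation, scan-change mean, topogram-to-height
#' ratio, pooled DLP means) comparing the configured value with the value
#' realized in a generated cohort. Gaps beyond 3 Monte-Carlo standard errors
#' are flagged.
#'
#' @param cohort A cohort generated from `config` (or any cohort table).
#' @param config The [synthetic_config()] whose targets to check.
#' @return Tibble: `target`, `stratum`, `configured`, `realized`, `gap`,
#'   `mc_se`, `flagged`.
#' @export
calibration_report <- function(cohort, config) {
  validate_synthetic_config(config)
  d_eff <- effective_diameter(cohort$ap, cohort$lat)
  rows <- list()
  add <- function(target, stratum, configured, realized, mc_se) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      target = target, stratum = stratum, configured = configured,
      realized = realized, gap = abs(realized - configured), mc_se = mc_se,
      flagged = abs(realized - configured) > 3 * mc_se)
  }
  mean_se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  spearman_se <- function(r, n) {
    (1 - r^2) * sqrt(1 + r^2 / 2) / sqrt(max(n - 3, 1))
  }
  spear <- function(x, y) cor(x, y, method = "spearman")
  for (s in c("F", "M")) {
    t <- config[[if (s == "F") "female" else "male"]]
    i <- cohort$sex == s
    for (v in c("age", "height", "bmi", "ctdi_vol"))
      add(paste0("mean_", v), s, t[[v]]$mean, mean(cohort[[v]][i]),
          mean_se(cohort[[v]][i]))
    add("mean_d_eff", s, t$d_eff$mean, mean(d_eff[i]), mean_se(d_eff[i]))
    n_s <- sum(i)
    r1 <- spear(cohort$bmi[i], d_eff[i])
    add("rho_bmi_deff", s, t$rho_bmi_deff, r1, spearman_se(r1, n_s))
    r2 <- spear(cohort$ctdi_vol[i], d_eff[i])
    add("rho_ctdi_deff", s, t$rho_ctdi_deff, r2, spearman_se(r2, n_s))
  }
  r_pool <- spear(cohort$bmi, d_eff)
  add("rho_bmi_deff", "all", config$rho_bmi_deff_pooled, r_pool,
      spearman_se(r_pool, nrow(cohort)))
  delta <- 100 * (cohort$diagnostic_length - cohort$topogram_length) /
    cohort$topogram_length
  add("mean_delta_pct", "all", config$delta_pct$mean, mean(delta),
      mean_se(delta))
  ratio <- cohort$topogram_length / (10 * cohort$height)
  add("mean_topo_height_ratio", "all", config$topo_height_ratio$mean,
      mean(ratio), mean_se(ratio))
  add("mean_dlp_diagnostic", "all", config$dlp_diagnostic_mean,
      mean(cohort$dlp_diagnostic), mean_se(cohort$dlp_diagnostic))
  add("mean_dlp_topogram", "all", config$dlp_topogram_mean,
      mean(cohort$dlp_topogram), mean_se(cohort$dlp_topogram))
  dplyr::bind_rows(rows)
}
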