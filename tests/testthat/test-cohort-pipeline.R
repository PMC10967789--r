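test_that("derive_all computes the per-record chain against the tables", {
  rec <- random_records(1, seed = 2)
  rec$ap <- 32
  rec$lat <- 32
  body <- conversion_table("body_32cm")
  k32 <- lookup_k(body, 32)
  d <- derive_all(rec)
  expect_equal(d$d_eff, 32)
  expect_equal(d$k, k32)
  expect_equal(d$ssde, rec$ctdi_vol * k32)
  expect_equal(d$dlp_ss, rec$dlp_diagnostic * k32)
  expect_equal(d$ed, rec$dlp_diagnostic * 0.014)
  # zero diagnostic DLP propagates to zero adjusted dose
  rec$dlp_diagnostic <- 0
  d0 <- derive_all(rec)
  expect_equal(d0$dlp_ss, 0)
  expect_equal(d0$ed, 0)
})

test_that("dlp_source = 'total' adds the topogram DLP", {
  rec <- random_records(5, seed = 3)
  d <- derive_all(rec, dlp_source = "total")
  expect_equal(d$dlp_used, rec$dlp_diagnostic + rec$dlp_topogram)
  expect_equal(d$ed, 0.014 * (rec$dlp_diagnostic + rec$dlp_topogram))
})

test_that("derive_all is a pure map: permuting inputs permutes outputs", {
  rec <- random_records(30, seed = 4)
  perm <- sample(30)
  a <- derive_all(rec)
  b <- derive_all(rec[perm, ])
  expect_equal(b, a[perm, ], ignore_attr = TRUE)
})

test_that("invalid records are collected by id, pipeline fails only if all fail", {
  rec <- random_records(5, seed = 5)
  rec$height[2] <- -1
  rec$ctdi_vol[4] <- NA
  expect_warning(d <- derive_all(rec), "dropped 2")
  expect_equal(nrow(d), 3)
  expect_setequal(attr(d, "failures")$id, rec$id[c(2, 4)])
  rec_bad <- random_records(3, seed = 6)
  rec_bad$ap <- -rec_bad$ap
  expect_error(derive_all(rec_bad), "all records failed")
})

test_that("BMI inconsistent with weight and height is flagged, not rejected", {
  rec <- random_records(4, seed = 7)
  rec$bmi[3] <- rec$bmi[3] + 2
  expect_warning(d <- derive_all(rec), "BMI consistency")
  expect_equal(nrow(d), 4)
  expect_equal(attr(d, "flags")$id, rec$id[3])
})

test_that("mean effective dose is exactly f times mean DLP (linearity)", {
  d <- derive_all(small_cohort(seed = 8))
  expect_equal(mean(d$ed), 0.014 * mean(d$dlp_diagnostic), tolerance = 1e-14)
})

test_that("stratified summaries use sample SD and respect strata", {
  dat <- tibble::tibble(sex = c("F", "F", "F", "M", "M"),
                        v = c(3, 4, 5, 10, 10), w = rep(7, 5))
  s <- summarize_cohort(dat, c("v", "w"))
  sv <- s[s$variable == "v", ]
  expect_equal(sv$mean[sv$stratum == "all"], 6.4)
  expect_equal(sv$mean[sv$stratum == "F"], 4)
  expect_equal(sv$sd[sv$stratum == "F"], 1)
  expect_equal(sv$sd[sv$stratum == "M"], 0)
  expect_equal(s$sd[s$variable == "w" & s$stratum == "all"], 0)
  expect_equal(sv$n[sv$stratum == "all"],
               sv$n[sv$stratum == "F"] + sv$n[sv$stratum == "M"])
  two <- summarize_cohort(dat[1:2, ], "v", strata = "all")
  expect_equal(two$sd, abs(3 - 4) / sqrt(2))
  expect_error(summarize_cohort(dat[dat$sex == "X", ], "v"), "fewer than 2")
})

test_that("group comparison gates on Shapiro-Wilk and reports the test used", {
  set.seed(21)
  x <- rnorm(30)
  same <- compare_groups(x, x)
  expect_equal(same$p_value, 1)
  expect_equal(same$test_used, "student_t")
  shifted <- compare_groups(rnorm(30), rnorm(30) + 10)
  expect_lt(shifted$p_value, 0.05)
  skewed <- compare_groups(exp(rnorm(40)), exp(rnorm(40)))
  expect_equal(skewed$test_used, "mann_whitney")
  # the decision is reproducible from the two normality p-values alone
  for (i in 1:20) {
    a <- if (i %% 2) rnorm(25) else exp(rnorm(25) * 2)
    b <- if (i %% 3) rnorm(25) else exp(rnorm(25) * 2)
    res <- compare_groups(a, b)
    gate <- res$normality_p_f >= 0.05 && res$normality_p_m >= 0.05
    expect_equal(res$test_used, if (gate) "student_t" else "mann_whitney")
  }
})

test_that("degenerate groups fall through to Mann-Whitney with a warning", {
  set.seed(22)
  expect_warning(res <- compare_groups(rep(5, 10), rnorm(10)), "degenerate")
  expect_equal(res$test_used, "mann_whitney")
  expect_error(compare_groups(1:2, rnorm(5)), "at least 3")
})

test_that("the default synthetic cohort shows the expected sex differences", {
  d <- derive_all(generate_cohort(synthetic_config()))
  cmp <- compare_by_sex(d, c("dlp_ss", "ctdi_vol"))
  expect_lt(cmp$p_value[cmp$variable == "dlp_ss"], 0.05)
  # size adjustment raises the cohort dose-length product by about 20%
  expect_gt(mean(d$dlp_ss) / mean(d$dlp_diagnostic), 1.15)
  expect_lt(mean(d$dlp_ss) / mean(d$dlp_diagnostic), 1.25)
})

test_that("spearman_matrix handles perfect, inverted and constant covariates", {
  set.seed(23)
  dat <- tibble::tibble(sex = rep(c("F", "M"), each = 10),
                        ctdi_vol = runif(20, 3, 18))
  dat$same <- dat$ctdi_vol
  dat$neg <- -dat$ctdi_vol
  dat$flat <- 5
  m <- spearman_matrix(dat, covariates = c("same", "neg", "flat"),
                       strata = "all")
  expect_equal(m$rho[m$covariate == "same"], 1)
  expect_equal(m$rho[m$covariate == "neg"], -1)
  expect_true(is.na(m$rho[m$covariate == "flat"]))
  expect_match(m$note[m$covariate == "flat"], "constant")
})

test_that("spearman_matrix is invariant under strictly monotone transforms", {
  set.seed(24)
  dat <- tibble::tibble(sex = rep("F", 40), ctdi_vol = rlnorm(40),
                        x = rnorm(40))
  dat$x <- dat$x + dat$ctdi_vol
  r1 <- spearman_matrix(dat, covariates = "x", strata = "F")$rho
  dat2 <- dat
  dat2$ctdi_vol <- log(dat2$ctdi_vol)
  dat2$x <- exp(dat2$x / 5)
  r2 <- spearman_matrix(dat2, covariates = "x", strata = "F")$rho
  expect_equal(r1, r2, tolerance = 1e-14)
})

test_that("male-stratum CTDIvol~Deff correlation recovers its calibration target", {
  d <- derive_all(generate_cohort(synthetic_config()))
  m <- spearman_matrix(d, strata = "M")
  expect_lt(abs(m$rho[m$covariate == "d_eff"] - 0.87), 0.06)
})

test_that("audit percentages partition and honour the tie rule at 32 cm", {
  rec <- random_records(40, seed = 25)
  rec$diagnostic_length <- rec$topogram_length
  d <- derive_all(rec)
  a <- audit_cohort(d)
  expect_equal(a$scan_change$pct_unchanged, 100)
  expect_equal(a$scan_change$pct_shortened + a$scan_change$pct_unchanged +
                 a$scan_change$pct_extended, 100)
  rec31 <- random_records(10, seed = 26)
  rec31$ap <- 31
  rec31$lat <- 31
  expect_equal(audit_cohort(derive_all(rec31))$size$pct_deff_below_phantom, 100)
  rec32 <- rec31
  rec32$ap <- 32
  rec32$lat <- 32
  a32 <- audit_cohort(derive_all(rec32))
  expect_equal(a32$size$pct_deff_below_phantom, 100) # ties count as below
})

test_that("length-to-height ratios are reported under both conventions", {
  rec <- random_records(12, seed = 27)
  d <- derive_all(rec)
  a <- audit_cohort(d)
  r <- a$length_to_height
  expect_equal(
    r$ratio_of_means_pct[r$stratum == "all" & r$scan == "topogram"],
    100 * mean(rec$topogram_length) / (10 * mean(rec$height)))
  expect_equal(
    r$mean_of_ratios_pct[r$stratum == "all" & r$scan == "diagnostic"],
    mean(100 * rec$diagnostic_length / (10 * rec$height)))
})
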