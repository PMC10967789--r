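test_that("generation is deterministic in the config and varies with the seed", {
  cfg <- synthetic_config(n_female = 15, n_male = 15, seed = 101)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- synthetic_config(n_female = 15, n_male = 15, seed = 102)
  other <- generate_cohort(cfg2)
  expect_false(identical(generate_cohort(cfg), other))
  expect_identical(names(other), cohort_columns)
})

test_that("generated cohorts satisfy the record invariants and inclusion window", {
  coh <- small_cohort(seed = 31, n_female = 60, n_male = 60)
  issues <- validate_cohort(coh)
  expect_equal(nrow(issues), 0)
  expect_true(all(coh$bmi >= 18 & coh$bmi <= 35))
  expect_equal(coh$weight, coh$bmi * (coh$height / 100)^2, tolerance = 1e-14)
  # AP/LAT split preserves the drawn effective diameter by construction:
  # the aspect ratio stays inside its configured band
  cfg <- synthetic_config()
  r <- coh$ap / coh$lat
  expect_true(all(r >= cfg$aspect_ratio$min & r <= cfg$aspect_ratio$max))
  # lengths are reported in whole millimetres
  expect_equal(coh$topogram_length, round(coh$topogram_length))
  expect_equal(coh$diagnostic_length, round(coh$diagnostic_length))
})

test_that("degenerate config (all sds zero) collapses to the target means", {
  cfg <- synthetic_config(
    n_female = 5, n_male = 5,
    female = modifyList(sex_targets("F"), list(
      age = list(mean = 60, sd = 0), height = list(mean = 160, sd = 0),
      bmi = list(mean = 27, sd = 0), d_eff = list(mean = 29, sd = 0),
      ctdi_vol = list(mean = 8, sd = 0))),
    male = modifyList(sex_targets("M"), list(
      age = list(mean = 62, sd = 0), height = list(mean = 175, sd = 0),
      bmi = list(mean = 28, sd = 0), d_eff = list(mean = 31, sd = 0),
      ctdi_vol = list(mean = 9, sd = 0))),
    aspect_ratio = list(mean = 0.73, sd = 0, min = 0.5, max = 0.95),
    topo_height_ratio = list(mean = 0.23, sd = 0),
    delta_pct = list(mean = 5, sd = 0, min = -30, max = 40),
    seed = 1)
  coh <- generate_cohort(cfg)
  f <- coh[coh$sex == "F", ]
  expect_equal(f$bmi, rep(27, 5))
  expect_equal(f$height, rep(160, 5))
  expect_equal(f$ctdi_vol, rep(8, 5))
  expect_equal(f$weight, f$bmi * (f$height / 100)^2)
  expect_equal(effective_diameter(f$ap, f$lat), rep(29, 5), tolerance = 1e-12)
  m <- coh[coh$sex == "M", ]
  expect_equal(effective_diameter(m$ap, m$lat), rep(31, 5), tolerance = 1e-12)
})

test_that("CTDIvol increases with effective diameter as calibrated", {
  cfg <- synthetic_config(n_female = 2000, n_male = 2000, seed = 33)
  coh <- generate_cohort(cfg)
  d_eff <- effective_diameter(coh$ap, coh$lat)
  for (s in c("F", "M")) {
    i <- coh$sex == s
    expect_gt(cor(coh$ctdi_vol[i], d_eff[i], method = "spearman"), 0.5)
  }
  co <- generator_coefficients(cfg)
  expect_gt(co$female$g, 0)
  expect_gt(co$male$g, 0)
  expect_gt(co$female$c0, 0)
})

test_that("solved dose model reproduces the CTDIvol mean and sd targets", {
  cfg <- synthetic_config(n_female = 20000, n_male = 2, seed = 34)
  coh <- generate_cohort(cfg)
  f <- coh[coh$sex == "F", ]
  expect_lt(abs(mean(f$ctdi_vol) - 7.38), 3 * sd(f$ctdi_vol) / sqrt(nrow(f)))
  expect_lt(abs(sd(f$ctdi_vol) - 3.23), 0.15)
})

test_that("calibration report flags a deliberately mis-specified coupling", {
  cfg_indep <- synthetic_config(
    n_female = 300, n_male = 300,
    female = modifyList(sex_targets("F"), list(rho_bmi_deff = 0)),
    male = modifyList(sex_targets("M"), list(rho_bmi_deff = 0)),
    seed = 35)
  coh <- generate_cohort(cfg_indep)
  claimed <- synthetic_config(n_female = 300, n_male = 300, seed = 35)
  rep <- calibration_report(coh, claimed)
  expect_true(all(rep$flagged[rep$target == "rho_bmi_deff" &
                                rep$stratum %in% c("F", "M")]))
  honest <- calibration_report(coh, cfg_indep)
  expect_false(any(honest$flagged[honest$target == "rho_bmi_deff" &
                                    honest$stratum %in% c("F", "M")]))
})

test_that("infeasible or inconsistent configurations are rejected field by field", {
  expect_error(synthetic_config(n_female = 0), "n_female")
  expect_error(
    synthetic_config(female = modifyList(sex_targets("F"),
                                         list(rho_bmi_deff = 1))),
    "infeasible rank target")
  expect_error(
    synthetic_config(female = modifyList(sex_targets("F"), list(
      ctdi_vol = list(mean = 7, sd = -1)))),
    "sd")
  expect_error(synthetic_config(delta_pct = list(mean = 50, sd = 5,
                                                 min = -10, max = 40)),
               "delta_pct")
  expect_error(synthetic_config(bmi_range = list(min = 30, max = 20)),
               "bmi_range")
})

test_that("location adjustments cancel truncation and clipping mean shifts", {
  co <- generator_coefficients(synthetic_config())
  # adjusted means differ from the targets in the right direction
  expect_gt(co$female$bmi_mu_adj, 26.88) # window is left-heavier than right
  tm <- ctdosim:::truncated_normal_mean(co$female$bmi_mu_adj, 5.70, 18, 35)
  expect_equal(tm, 26.88, tolerance = 1e-8)
  cm <- ctdosim:::clipped_normal_mean(co$delta_mu_adj, 11.35, -27.2, 36.86)
  expect_equal(cm, 4.54, tolerance = 1e-8)
})
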