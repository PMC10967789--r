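# Fixtures are built in code: random-but-valid record tables for identity
# tests, and small generated cohorts for pipeline tests.

random_records <- function(n, seed = 1) {
  set.seed(seed)
  height <- runif(n, 150, 195)
  bmi <- runif(n, 18, 35)
  tibble::tibble(
    id = sprintf("R%04d", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = runif(n, 20, 90),
    height = height,
    weight = bmi * (height / 100)^2,
    bmi = bmi,
    ap = runif(n, 18, 33),
    lat = runif(n, 28, 44),
    topogram_length = round(runif(n, 300, 500)),
    diagnostic_length = round(runif(n, 300, 500)),
    ctdi_vol = runif(n, 2, 20),
    dlp_topogram = runif(n, 3, 8),
    dlp_diagnostic = runif(n, 80, 600)
  )
}

small_cohort <- function(seed = 42, n_female = 20, n_male = 20) {
  generate_cohort(synthetic_config(n_female = n_female, n_male = n_male,
                                   seed = seed))
}
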