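---
title: "Size-adjusted CT dosimetry: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-adjusted CT dosimetry: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdosim)
```

## Why size adjustment

CTDIvol and DLP are defined against a 32-cm acrylic phantom. A patient whose
chest cross-section is smaller than the phantom absorbs *more* dose per unit
CTDIvol than the phantom would, so the reported indices understate exposure
for most adults. The correction chain implemented here is

1. effective diameter $D_{eff} = \sqrt{AP \times LAT}$, the diameter of the
   circle with the same area as the elliptical cross-section, measured at the
   most extensive slice (per-slice diameter series are out of scope);
2. a conversion factor $k(D_{eff})$ from the AAPM Report 204
   effective-diameter table for the 32-cm body phantom;
3. $SSDE = CTDI_{vol} \times k$ for a single cross-section, and its
   whole-scan analogue $DLP_{ss} = DLP \times k$;
4. $ED = DLP \times f$ with the protocol coefficient $f$ (chest:
   0.014 mSv/(mGy·cm), AAPM Report 96).

By construction $DLP_{ss}/DLP = SSDE/CTDI_{vol} = k$ for every record; the
test suite asserts this to machine precision, which pins the implementation
to the algebra rather than to any particular cohort.

$DLP_{ss}$ and $ED$ are computed from the **diagnostic-scan DLP only** by
default. The topogram contributes ~2% of the total DLP and is tabulated
separately on dose reports; `derive_all(dlp_source = "total")` adds it for
sensitivity analyses.

## The conversion table

The k table ships as a plain-text file (`inst/extdata/`), one row per cm of
effective diameter from 8 to 45 cm. The entries are computed from the
report's published exponential fit $k = a\,e^{-b\,D_{eff}}$
(body: $a = 3.704369$, $b = 0.03671937$) rounded to the report's 2-decimal
precision; the coefficients are stored alongside and the package
cross-validates table against fit (maximum relative deviation < 1% for the
body table).

Lookup is by **linear interpolation** between bracketing rows, matching how
a physicist reads the printed table; `interpolation = "fit"` evaluates the
continuous model instead (the two agree to ~0.5%, the rounding quantum).
Whether to interpolate or take the nearest row is genuinely open; nearest-row
would introduce a 0.5-cm staircase with no physical basis, so interpolation
is the default. Outside the tabulated range the value is **clamped** to the
nearest endpoint with a warning rather than extrapolated: the exponential
fit keeps decaying and would produce k well below anything measured (and
k < 1 values at absurd diameters), so clamping is the conservative failure
mode.

## The statistical layer

The cohort layer mirrors standard dose-audit practice:

- stratified mean, sample SD (n−1), and range per variable for the whole
  group and per sex;
- two-group comparisons gated on normality: Shapiro–Wilk per group at
  $\alpha = 0.05$; both compatible with normality → two-sided Student's
  t-test, otherwise two-sided Mann–Whitney U. The **equal-variance** t
  statistic is the default (the classical pairing with a Shapiro gate);
  `var_equal = FALSE` gives Welch. A degenerate all-identical group, for
  which the Shapiro–Wilk statistic is undefined, falls through to the
  Mann–Whitney path with a warning.
- Spearman rank correlation with average-rank ties (`cor.test`,
  asymptotic p); a constant variable is reported as NA with a reason.
- **No multiple-testing correction** is applied: each comparison is reported
  at raw $\alpha = 0.05$, the convention in this audit literature where the
  tests are descriptive, not confirmatory. Apply `p.adjust` downstream if a
  family-wise claim is needed.

The audit reports scan-length change categories (shortened / unchanged /
extended; "unchanged" means exact mm equality — dose reports print whole
millimetres, so exact ties are meaningful), the proportion of patients above
vs below the phantom diameter (a tie at exactly 32 cm counts as "below",
keeping the two-way partition), and scan-length-to-height ratios.
Length-to-height ratios are reported under **both** conventions — ratio of
means and mean of per-patient ratios — because the two differ in the second
decimal and published summaries rarely say which was used; the ratio of
means is the headline column.

## The synthetic cohort generator

No per-patient registry extract can ship with the package, so the generator
produces cohorts with the statistical structure the analysis assumes. Its
defaults are calibrated to a retrospective adult chest-CT service cohort of
134 studies (68 F / 66 M): per-sex age, height and BMI marginals, per-sex
effective-diameter and CTDIvol marginals, rank couplings BMI↔D_eff
(0.82 F / 0.90 M) and CTDIvol↔D_eff (0.79 F / 0.87 M), a scan-length-change
model (+4.54 ± 11.35%, clipped to the observed extremes [−27.2, +36.86]%),
and a topogram-to-height ratio of 0.2299 ± 0.025.

Pipeline, per sex (each stage draws from its own seed stream derived from
the master seed, so adding a stage never perturbs earlier draws):

1. (height, BMI) from a bivariate normal (independent by default); BMI draws
   outside the inclusion window [18, 35] kg/m² are rejected. The
   pre-truncation mean is **location-adjusted** (closed-form truncated-normal
   mean, solved by `uniroot`) so the *realized* BMI mean hits its target.
2. weight := BMI × (height/100)² exactly.
3. D_eff via a **Gaussian copula** against BMI: the latent Pearson
   correlation is $2\sin(\pi\rho_S/6)$ for a Spearman target $\rho_S$, which
   makes the realized rank correlation hit the target exactly in
   distribution, truncation notwithstanding. Only marginals and rank
   correlations are calibrated — the copula is the minimal joint structure
   consistent with them, not an empirical claim about chest anatomy.
4. AP/LAT split at a near-constant aspect ratio AP/LAT ≈ 0.73 ± 0.03
   (clipped to [0.5, 0.95]), so that $\sqrt{AP \times LAT}$ reproduces the
   drawn D_eff to machine precision. Real joint AP–LAT behaviour beyond the
   means is not modelled.
5. CTDIvol := $c_0\,e^{g(D_{eff}-32)}\,\varepsilon$ with lognormal noise —
   the log-linear dose-vs-size response of attenuation-based tube-current
   modulation. $c_0$, $g$ and the noise SD are solved in closed form from
   the per-sex CTDIvol mean/SD and the CTDIvol↔D_eff rank target
   (`generator_coefficients()`), not free parameters.
6. topogram length := height × ratio draw, rounded to whole mm; diagnostic
   length := topogram × (1 + Δ/100) with Δ clipped normal,
   location-adjusted for the clipping shift, rounded to whole mm. The mm
   rounding is what produces a small (~1–2%) "unchanged" class, as real
   audits show.
7. DLP_diag := efficiency × CTDIvol × length/10; the single multiplicative
   efficiency (~0.90) is solved so the expected pooled diagnostic DLP hits
   its 286.51 mGy·cm target — it absorbs everything the
   CTDIvol-times-length model ignores (overranging geometry, modulation
   profile). The topogram DLP uses an analogous solved fraction
   (~1.7% of the CTDIvol × topogram-length product).

`calibration_report()` compares every configured target with its realized
value and flags gaps beyond 3 Monte-Carlo standard errors; the test suite
runs it at 10,000 per sex (means within 3 SE, rank targets within ±0.03) and
across 500 replicates at the study size n = 134 — sizes chosen so the whole
suite runs in seconds while leaving Monte-Carlo error well below the
tolerances checked.

### What the generator deliberately does not reproduce

- **The pooled BMI↔D_eff rank correlation.** With per-sex Gaussian copulas
  and the default marginals, the whole-group value is an *emergent* quantity
  — there is no remaining degree of freedom — and it comes out ≈ 0.84. The
  configured whole-group check target of 0.77 lies *below both* within-sex
  values, which no location-shift mixture of this kind can produce when the
  between-sex shifts in BMI and D_eff are concordant; a service cohort with
  that property has joint structure (e.g. sex-specific non-Gaussian tails)
  that marginal summaries cannot identify. `calibration_report()` therefore
  flags the pooled row at large n by design; at n = 134 the sampling
  distribution of the pooled correlation is wide enough (SD ≈ 0.03) to cover
  0.77.
- **BMI dispersion.** A distribution supported on [18, 35] cannot have
  SD 5.7 (the maximum on an interval of width 17 is $17/\sqrt{12} \approx
  4.9$); the generator matches the BMI *mean* exactly and realizes
  SD ≈ 4.2. Published cohort SDs that exceed the bound indicate heaping or
  heavier-than-normal tails in the source data.
- **Scan-length covariance.** Δ% is drawn independently of topogram length,
  so the realized mean (diagnostic − topogram) difference is
  E[topo] × E[Δ]/100 ≈ 17.5 mm; audited cohorts reporting a smaller mm
  difference alongside a larger mean percent change imply negative
  correlation between Δ% and scan length, which is not modelled.
- Pathology-driven exclusions, body-composition effects, and multiphase
  protocols are out of scope; the generator emulates included,
  single-phase studies only.

Consequently, green recovery tests show the pipeline is *self-consistent* —
the statistics layer recovers what the generator encodes — not that real
registry data meet the generator's assumptions.

## Numerical conventions

- Lengths are carried in mm, dose-length products in mGy·cm; the only
  mm→cm conversion happens in the generator's DLP model.
- All internal arithmetic is full precision; values are rounded (2 decimals)
  only at the presentation layer (`report` CLI subcommand, README examples).
- CSV dialect is strict: comma delimiter, dot decimal, `#` comments,
  mandatory header; a malformed row is rejected with its file line number
  while the rest of the file loads, and ambiguous locales are never guessed.
- Per-record validation drops invalid rows (collected by id) and fails only
  if no record survives; a BMI inconsistent with weight/height by more than
  0.5 kg/m² is flagged but kept, since registry BMI fields are routinely
  stale.
- The master seed plus per-stage child streams make every cohort
  byte-reproducible from its serialized configuration.
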