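# dosefindsim

Simulation of phase I dose-finding designs on a continuous standardized
dose scale: rule-based **accelerated titration** (AT, the two-phase 3+3 /
modified-Fibonacci up-and-down variant) versus Bayesian **escalation with
overdose control** (EWOC, and its proportional-odds variant EWOC-PO).

The package is for biostatisticians evaluating the operating
characteristics of dose-escalation rules before writing a protocol.  It
provides:

* **Trinary dose–toxicity generating models.**  Outcomes are Y = 0
  (grade 0–1), Y = 1 (grade 2), Y = 2 (DLT), generated from
  P(Y ≥ j | x) = F(α_j + β_j x) with the clinician-facing
  reparameterization α₁ = F⁻¹(ρ₁), α₂ = F⁻¹(ρ₀),
  β = (F⁻¹(θ) − F⁻¹(ρ₀))/γ, so that P(DLT | γ) = θ exactly.  Five
  response models (proportional-odds logistic; steep/flat scaled-normal;
  two non-proportional-odds perturbations) probe robustness.
* **An exact AT state machine** — one patient per level with fast
  escalation until the first grade ≥ 2 toxicity, then 3-patient 3+3
  cohorts, a 62-patient cap, and explicit handling of the range
  boundaries.
* **EWOC/EWOC-PO** — a componentwise random-walk Metropolis–Hastings
  sampler for the posterior of (ρ₀[, ρ₁], γ) under the vague priors
  γ ~ U[0,1], ρ₀ ~ U[0,θ], ρ₁|ρ₀ ~ U[ρ₀,1]; each patient is dosed at the
  α-quantile of the MTD posterior (θ = 0.33, α = 0.25, n = 30).
* **A reproducible trial engine and metrics** — bias and √MSE of the MTD
  estimate, DLT-rate summaries, optimal-dose proportions (±15% of the
  true MTD), and nearest-rank trial-size percentiles, per (design,
  scenario) cell.

## Worked example

Compare one AT design with EWOC on a single scenario (true MTD 0.5,
ρ₁ = 0.5, model A), 20 trials per cell at reduced MCMC length:

```r
library(dosefindsim)

designs <- list(at_config(0.1, 2, 1.5),
                ewoc_config("binary", n_burnin = 2000, n_keep = 2000))
scen <- scenario_grid("A", gammas = 0.5, rho1s = 0.5)
rows <- run_study(study_config(designs, scen, n_trials = 20,
                               master_seed = 1))
summarize_study(rows)[, c("design", "bias", "rmse", "avg_dlt_prop",
                          "prop_mtd_optimal", "size_q50")]
#>          design       bias       rmse avg_dlt_prop prop_mtd_optimal size_q50
#> 1 AT(0.1,2,1.5) -0.0362500 0.20930606    0.2072461             0.45       13
#> 2          EWOC -0.0562958 0.09598019    0.2683333             0.60       30
```

Both designs are safe here (average DLT proportion below θ = 0.33), but
EWOC estimates the MTD with less than half the AT design's root MSE and
puts 60% of trials within ±15% of the true MTD versus 45% for AT, while
AT trials are shorter (median 13 patients versus the fixed 30) — the
efficiency/safety trade-off the simulation study quantifies.

The bundled configuration files reproduce the full study layouts:

```sh
inst/cli/dosefindsim simulate \
  --config inst/configs/full_modelA.cfg --out out/ [--full-scale]
inst/cli/dosefindsim report --trials out/trials.csv --out report/
```

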