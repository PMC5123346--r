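# fractionate

Simulation and inference for a continuous model of **one-sided genome
fractionation** — the progressive deletion of duplicate genes after a
whole-genome duplication.

Because at least one copy of every region survives, aligning the
fractionating chromosome against its duplicate decomposes it into
alternating **visible** (retained) and **invisible** (deleted) segments.
This package implements a continuous model of that process on the real
line and the inference machinery that goes with it:

* **Model.** Deletion events arrive in discrete *sweeps*. Within a sweep,
  spacings between deletion points are Exponential(mean ν) and deleted
  lengths Exponential(mean μ), both along the concatenation of currently
  visible segments. A deletion that covers pre-existing deletion points
  *swallows* them: the invisible runs merge and an event counter C(x)
  accumulates (1 plus the swallowed counters).
* **Closed forms.** Visible spacing after sweep t: λ_t = ν/t. A new event
  swallows a geometric number of points:
  p_q = λ/(μ+λ) · (μ/(μ+λ))^q. Retained genome fraction after t sweeps:
  (1 − μ/(ν+μ))^t. The counter distribution π_t(i) evolves by a
  composition/convolution recursion.
* **Fitting.** Visible lengths are exponential with rate λ⁻¹ = t/ν;
  invisible lengths are approximately Gamma(α, β) (β a rate), fitted by
  maximum likelihood, with Cullen–Frey moment diagnostics.
* **Empirical laws.** 1/α − 1 = s(r)·(t−1) and 1/β = μ·exp[b(r)·(t−1)]
  with r = μ/ν and quadratics s, b (reference coefficients included;
  `calibrate()` re-estimates them from fresh simulations).
* **Inference.** Given observed (λ⁻¹, α, β), a scan over integer candidate
  t inverts the laws to (ν_t, μ_t), predicts β_t, and selects
  t̂ = argmin |β − β_t|/β.

## Worked example

Simulate the standard configuration (μ = 1, ν = 3, five sweeps, genome
length 10,000 maintained by replenishment from five replicate trials), fit
the observables, and run the inference scan:

```r
library(fractionate)

run <- run_fractionation(sweep_params(nu = 3, mu = 1),
                         sim_config(genome_length = 10000, sweeps = 5,
                                    replicates = 5, seed = 11))
run
#> Fractionation run: nu = 3, mu = 1, 5 sweeps x 5 replicates, G = 10000
#>   sweep 1: mean visible 3.02 (n=16554), mean invisible 0.9959 (n=16549), retained 0.7511
#>   sweep 2: mean visible 1.499 (n=33352), mean invisible 1.161 (n=33347), retained 0.7496
#>   sweep 3: mean visible 0.9997 (n=50017), mean invisible 1.376 (n=50012), retained 0.7463
#>   sweep 4: mean visible 0.7503 (n=66639), mean invisible 1.638 (n=66634), retained 0.7483
#>   sweep 5: mean visible 0.6019 (n=83076), mean invisible 1.948 (n=83071), retained 0.7516
```

Mean visible spacing tracks λ_t = 3/t (3.02, 1.50, 1.00, 0.75, 0.60) and
each sweep retains about 1 − μ/(ν+μ) = 0.75 of the visible genome.

```r
fs <- fit_summary(collect_lengths(run))
fs
#> Fitted observables (mle): lambda^-1 = 1.66152 (n = 83076), alpha = 0.677543, beta = 0.347892 (n = 83071)
```

Inference on a recorded experiment at these parameters (observed
λ⁻¹ = 1.665595, α = 0.6711252, β = 0.3504422) reproduces its published
candidate table and picks t̂ = 5:

```r
infer(observables(1.665595, 0.6711252, 0.3504422), t_range = 3:7)
#> Fractionation inference
#> Observables: lambda^-1 = 1.66559, alpha = 0.671125, beta = 0.350442
#>                 t=3      t=4      t=5      t=6       t=7
#> mu         1.231662 1.063543 1.021578 1.018616  1.033112
#> nu         1.801158 2.401544 3.001930 3.602316  4.202702
#> beta_t     0.300560 0.338495 0.338655 0.325314  0.306789
#> 100 delta 14.234034 3.409209 3.363624 7.170391 12.456637
#> Estimate: t = 5, mu = 1.02158, nu = 3.00193
```

On the fresh simulation above the same scan lands on a neighboring
candidate — `infer(fs, t_range = 3:7)` gives t̂ = 6 with 100δ of 2.08
against 2.17 at t = 5 — a good illustration of how flat the arg-min
landscape is between adjacent sweep counts; see the methods vignette
(`vignettes/fractionation-model.Rmd`) for the sensitivity analysis and
recommended practice (repeat seeds, inspect the whole table, recalibrate
over the sweep range of interest).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/fractionate.R simulate --nu 3 --mu 1 --sweeps 5 --seed 1 --out out/
Rscript inst/scripts/fractionate.R infer --lambda-inv 1.665595 --shape 0.6711252 --rate 0.3504422 --t-min 3 --t-max 7
Rscript inst/scripts/fractionate.R calibrate --ratios 0.1,0.2,0.3333,0.5 --sweeps 1:7 --seed 1 --out coeffs.json
```

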