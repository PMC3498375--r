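# sealassoc

Detection and analysis of at-sea associations among grey seals carrying
acoustic proximity loggers and archival Fastloc GPS tags.

Animal-borne acoustic transceivers log time-stamped codes from
conspecifics within roughly 300 m; paired with archival GPS they yield
geo-referenced records of when two free-ranging predators were together.
`sealassoc` turns those raw logs into ecological inference, for movement
ecologists working with proximity-logger deployments:

* **Detection cleaning & association definition** — validity-flag
  removal of false detections; greedy pairing of reciprocal records
  (±180 s) so each exchange is counted once; per-dyad clustering with
  the gap rule (a gap > 30 min ends an association; single-detection
  associations last 3 min); association locations by linear
  interpolation of each seal's GPS track at the association midpoint.
* **Track discretisation** — Fastloc quality filtering (≥5 satellites,
  residual ≤ 30), 60-min UTC-aligned time steps with averaged positions,
  travel rates between step centroids, nearest-cell bathymetry,
  association flags per step.
* **Movement states** — a two-state hidden Markov model on hourly
  displacements with exponential emissions
  `f(y_t | λ_j) = λ_j⁻¹ exp(−y_t/λ_j)`, fitted by Baum–Welch EM
  (C++ forward–backward, multiple restarts); the smoothed posterior
  p(ARS) > 0.5 labels a step as slow movement / area-restricted search.
* **Available habitat** — per-seal 2D kernel density surfaces on a
  500 × 220 grid (normal reference bandwidths) used as weights to draw
  density-proportional random locations (5000 total, allocated by track
  length), whose depths form the availability baseline.
* **Inference** — Gaussian mixed models by exact maximum likelihood
  with a per-seal random intercept and AR(1) residual correlation,
  `cov(y_g) = σ_b² J + σ_e² R(φ)`, for depth (Random / No Association /
  Association) and travel rate (No Association / Association); and a
  Williams-corrected G test (`G_adj = G / q`,
  `q = 1 + (k²−1)/(6n(k−1))`) of sex-pair composition (MM/MF/FF).
* **Synthetic deployments** — a first-class generator producing GPS
  logs, acoustic logs, bathymetry and ground truth (latent states, true
  proximity intervals) for a configurable fleet; defaults emulate a
  13-seal, 79-day autumn deployment.

The methods vignette (`vignettes/seal-associations.Rmd`) documents the
models, conventions and design choices in detail.

## Worked example

Simulate a small deployment, run the whole pipeline, and inspect the
fitted movement model and association summary:

```r
library(sealassoc)

cfg <- sim_config(n_seals = 4, duration_days = 7, seed = 42,
                  origin_jitter_deg = 0.004)
make_scenario(cfg, "scratch/demo_scenario")

conf <- pipeline_config("scratch/demo_scenario", "scratch/demo_out",
                        n_random = 1000, hmm_pooled = TRUE, seed = 1)
res <- run_pipeline(conf)
#> [detections] 24 records read, 2 false removed, 22 kept
#> [pairing] 11 events (100.0% two-way)
#> [associations] 2 associations
#> [gps] 2501 fixes read, 139 low-accuracy removed
#> [steps] 672 steps (672 with fixes, 4 associated)
#> [hmm] 419 slow / 249 fast steps
#> [habitat] 1000 availability points sampled

print(res$hmm)
#> Two-state movement HMM (exponential emissions)
#>   lambda (m/h): slow 896.7, fast 4014.3
#>   transition matrix (rows slow, fast):
#>       [,1]  [,2]
#> [1,] 0.914 0.086
#> [2,] 0.132 0.868
#>   loglik -5710.084 after 38 EM iterations (converged)
```

The fleet was generated with emission means 864 and 4320 m/h and
self-transition probabilities 0.9/0.8; the pooled fit recovers them from
668 observed hourly displacements. Two associations were detected (11
detection events in total, all logged reciprocally); they span 4 hourly
steps of the two seals involved:

```r
print(res$summary)
#> 2 associations, 11 detection events
#> detections per association:    min    q25 median    q75    max
#>   5.00   5.25   5.50   5.75   6.00
#> duration (h):    min    q25 median    q75    max
#>  0.048  0.056  0.064  0.072  0.079
#> separation (km):    min    q25 median    q75    max
#>  0.247  0.438  0.630  0.821  1.012
```

(The association *separation* is measured between GPS positions
interpolated at the association midpoint, so on a 15-minute protocol it
carries interpolation error well beyond the 300 m acoustic range.) The
depth model compares seal steps against the availability sample; on this
short scenario the association category is estimated from only 4 steps
and is correspondingly uncertain:

```r
print(res$lmm_depth)
#> Gaussian mixed model, random intercept + AR(1) residuals (ML)
#>       parameter estimate     se     t        p
#>          Random  160.987  7.198 22.37 3.97e-97
#>  No Association  -10.155  8.610 -1.18 2.38e-01
#>     Association   30.452 26.684  1.14 2.54e-01
#>   among-group SD 6.648, residual SD 53.416, phi 0.455, loglik -8832.52
```

## The full analysis

Numbered drivers under `analysis/` run the study-scale workflow (13
seals × 79 days) from scratch, each writing its tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # synthetic deployment + ground truth
Rscript analysis/02_associations.R      # events, gap-rule associations, sex pairs
Rscript analysis/03_steps.R             # hourly steps, rates, depths, flags
Rscript analysis/04_movement_states.R   # HMM p(ARS) per seal, scored vs truth
Rscript analysis/05_habitat.R           # KDE-weighted availability depths
Rscript analysis/06_inference.R         # mixed models + G test
```

The whole sequence takes about 1.5 minutes.

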