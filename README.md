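# cloneburst

Clonal hematopoiesis dynamics from barcoded stem-cell transplants.

## The problem

In rhesus-macaque clonal tracking experiments, CD34+ hematopoietic stem and
progenitor cells are lentivirally barcoded and autologously transplanted;
blood samples drawn over months to years then report, per barcode, how many
mature granulocytes descend from each founding clone. Two puzzles dominate
these data: sampled clone abundances fluctuate far more than small-sample
noise allows, and the number of distinct barcodes (richness) is huge at the
first one or two samples and then collapses to a slowly decaying plateau.

`cloneburst` implements a hybrid stochastic–deterministic model that
explains both, and the statistical machinery to fit it:

* **HSC compartment** — each tagged clone is a discrete birth–death process
  with niche-regulated proliferation r_h(h) = r_h(0)(1 − h/K) and death
  μ_h, coupled to all other clones (and a deterministic untagged pool)
  through the shared carrying capacity K; simulated exactly with the
  Gillespie algorithm (compiled core). Expected clone richness follows
  E[C_h(t)] = C_h(0)/(ψ(t) + φ(t)) with ψ = exp(−∫(r_h − μ_h)),
  φ = ∫ r_h ψ.
* **Differentiation bursts** — clones emit progenitors as an inhomogeneous
  Poisson process of intensity α h_i(t); each founding cell amplifies
  deterministically through L transit-amplifying generations
  (n^(ℓ)(t) = (2 r_n t)^ℓ e^−(r_n+μ_n)t / ℓ!) and, after terminal
  differentiation at rate ω, produces a mature-cell burst
  m(t) = ω ∫ n^(L)(t′) e^−μ_m(t−t′) dt′ of total yield 2^L. Intermittent
  bursts are the proposed origin of the large abundance fluctuations.
* **Observation** — binomial sampling of each clone with fraction
  η(t_j) ~ 1e-5, the source of clone dropout.
* **Clone statistics & fitting** — per-clone mean/SD over all sampling
  times (zeros included), kernel-density estimate of the clone cloud,
  k-means compression with elbow selection, Earth mover's distance between
  weighted cluster sets (exact transportation LP), and a staged estimation
  pipeline: richness → transplanted-HSPC burst → totals least squares →
  per-time η adjustments → EMD refinement.

The early-richness spike is explained by transplanted, partially
differentiated HSPC clones: each fires a single burst and vanishes, leaving
the plateau to the engrafted HSCs.

## Worked example

```r
library(cloneburst)

preset <- makePreset("small_test")        # scaled-down reference system
sim <- generateDataset(preset$params, preset$schedule, seed = 42)
sim$table
#> SampleTable: 284 clones x 8 time points
#>   times (months): 0.5 1 2 3 5 7 9 12
#>   totals S(t_j):   413 255 893 1846 2258 2233 2229 2186
#>   richness C_s(t_j): 206 81 75 75 76 74 75 69
```

The first sample sees 206 clones, almost three times the later plateau of
~75: the 280 planted HSPC clones burst once and disappear, while the ~75
surviving HSC clones (of 120 engrafted) sustain the totals. Summarize each
clone by its mean and SD over the post-2-month samples and attach the KDE
density:

```r
cloud <- kdeDensity(cloneSummary(sim$table))
head(cloneRecords(cloud), 3)
#>    clone_id mean       sd   density density_norm
#> 1 HSC_00002 11.6 5.817216 1.1371282    0.8601392
#> 2 HSC_00003  4.6 2.576820 0.5755489    0.4353529
#> 3 HSC_00005 39.4 8.309031 0.9314001    0.7045237

fit <- fitPipeline(sim$table, defaultFitConfig(preset$params),
                   seed = 1, replicates = 2)
fit
#> FitResult: final EMD = 0.1756 (2 replicates/candidate, seed 1)
#> ModelParams (rates /day)
#>   HSC:        rH0 = 0.08, muH = 0.005, alpha = 0.0139689, K = 8774
#>   clones:     C_h(0) = 87.74 tagged, h_0(0) = 162.946 untagged (tagged fraction 0.35)
#>   progenitor: rN = 1, muN = 0, omega = 0.2, L = 10
#>   mature:     muM = 0.185;  sampling eta = 0.01
#>   HSPC clones: C_n(0) = 45, C_n(1) = 62, C_n(2) = 168
#>   eta multipliers: 1 1.03 1.02 0.982 1.01 0.995 0.993 0.974
```

Against the planted truth (C_h(0) = 120, K = 12000, α = 0.016, HSPC
composition 40/80/160), the fit recovers the clone count and capacity
within a factor ~1.4, the HSPC composition within a factor ~2, and the
composite α·2^L·η/μ_m that sets the sampled totals to within a few percent
— while the individual (r_n, L, ω, η) are only determined up to the
compensation family the fit report records (here the r_n = 1 member was
selected). That identifiability structure is a finding, not a bug; see the
methods vignette (`vignettes/clone-dynamics.Rmd`).

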