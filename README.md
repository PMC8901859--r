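# v1sync

Visual responsiveness, population synchrony, behavioral readout and
dendritic morphometrics for two-photon calcium imaging of mouse primary
visual cortex (V1) — implemented end to end on synthetic data with known
ground truth.

## The science

In layer 2/3 of V1, small visual stimuli normally recruit only a small
fraction of neurons, while large stimuli recruit many. A *hypersensitive*
circuit loses this separation, and the loss shows up in three linked
measurements:

1. **Responsiveness.** The percent of neurons responding to a small (S1,
   10.2°) versus a large (S4, 70.8°) grating, summarized by the normalized
   activity index **NAI = %responsive(S1) / %responsive(S4)**. Typical
   values are ≈ 0.3 in a normal circuit and → 1 in a hypersensitive one.
2. **Population synchrony.** In spontaneous activity, the probability that
   exactly *n* neurons fire in the same imaging frame,
   Correlation_prob(n) = Firing(n) / Totalₙ with Totalₙ = ⌈T·f⌉ frames
   (73.5 s at 20.4 Hz → 1500). Coincidences of **11 or more** neurons are
   compared against a Monte-Carlo null that permutes each neuron's event
   train while preserving its spike count exactly (10,000 shuffles, 97.5th
   percentile). Independent firing stays inside the null; population
   events exceed it.
3. **Behavior.** A piezo sensor under the animal records the visually
   induced fidget ("vidget"): the mean rectified, session-normalized
   voltage in the 0.5 s after stimulus onset, its delay (first sustained
   3-SD crossing), and the slope change of the cumulative signal at onset.

The package also measures pairwise correlation of deconvolved spontaneous
activity versus cortical distance, the spatial dispersion of functional
cell types via a random k-subgroup nearest-neighbor distance (which is
unbiased across groups of different sizes), and a dendritic complexity
index on SWC reconstructions:

DC = (Σ terminal branch orders + #terminals) × (total dendritic length / #primary dendrites).

Because the real quantities are measurements on live animals, `v1sync`
ships a generator (`make_population()`, `simulate_activity()`,
`render_traces()`, `simulate_piezo()`, `make_morphology()`) whose
parameters define the study conditions, and validates every analysis by
parameter recovery, exact enumeration oracles, and null-model calibration.
See `vignettes/v1sync-methods.Rmd` for the model and all numerical
choices.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "v1sync", load_package = "installed")'
```

~2,900 assertions, ~2 minutes on one CPU. The suite includes
hand-enumerated oracle cases, property tests (invariances, conservation,
monotonicity), precision/recall of the transient detector, and calibration
of the shuffle null.

## Worked example

```r
library(v1sync)

prot <- stim_protocol(seed = 1)              # 5x S1 + 5x S4, randomized
cfg  <- sim_config(T_s = prot$total_s)       # 20.4 Hz, tau = 1 s, amp 0.12
pop  <- make_population(60, seed = 2)        # 60 neurons, 517.77 um FOV
gt   <- simulate_activity(pop, prot, cfg, seed = 3)
tr   <- compute_dff(render_traces(gt, cfg, seed = 4))
ev   <- detect_transients(tr)                # 2.5-SD threshold + shape checks

rt <- classify_responsive(ev, prot)
rt$percent
#> [1] 19.00000 33.66667          # % responsive to S1, S4
compute_nai(rt)
#> [1] 0.5643564

sy <- sync_analysis(ev, N = 30, n_subsamples = 5, n_shuffles = 1000, seed = 5)
unlist(sy$observed_ranges)       # coincidence probability by band
#>       1-10     11-Inf
#> 0.03764706 0.00000000          # no high-order events; inside the null

nnd <- knn_subgroup_nnd(pop$positions, assign_types(rt), k = 5, seed = 6)
round(nnd$dispersion, 1)         # um, per functional type
#>     1     2     3     4
#> 131.6 124.8 127.5 131.0

pz <- simulate_piezo(prot, seed = 7)
mean(vidget_score(pz)$score); mean(vidget_delay(pz)$delay_s)
#> [1] 0.2164
#> [1] 0.1

morpho_table(lapply(1:3, function(s) make_morphology(seed = s)))
#>   n_primary n_nodes n_ends total_length_um mean_length_um     dc
#> 1         4       6     10           609.0          152.2 5937.5
#> 2         4       2      6           219.0           54.7  875.9
#> 3         4       6     10           655.9          164.0 6231.2
```

Or run everything at once:

```r
res <- run_pipeline(pipeline_config(seed = 1))
res$summary$nai
#> [1] 0.5675676
```

## Analysis workflow

The numbered scripts under `analysis/` are thin drivers that run the
pipeline for a **baseline** and a **hypersensitive** condition (weak-
stimulus response probability raised to the strong-stimulus level, plus
spontaneous population events) and write tab-separated tables to
`results/`:

```sh
Rscript analysis/01_simulate.R        # per-neuron response table
Rscript analysis/02_responsiveness.R  # percent responsive, NAI, amplitudes
Rscript analysis/03_synchrony.R       # coincidence bands vs. shuffle null
Rscript analysis/04_pairwise_spatial.R
Rscript analysis/05_vidget.R
Rscript analysis/06_morphology.R
```

In the written tables the baseline condition has NAI ≈ 0.48 and no
high-order synchrony, while the hypersensitive condition has NAI ≈ 1.12
and a coincidence probability in the 11+ band that exceeds the shuffle
null's 97.5th percentile.

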