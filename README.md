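# gaitid

Footwear-aware human gait identification from ground reaction forces and
body height.

## The problem

Gait is a usable biometric: the forces a walker exerts on the ground are
individual and stable. They are not, however, stable across *footwear* —
when a woman enrolled in sport shoes walks in 8–10 cm high heels, the
force-plate signature changes enough that a GRF-only identifier degrades
badly. `gaitid` implements a two-stage, two-sensor pipeline that restores
much of the lost accuracy:

1. **Footwear recognition.** The loading-response window of the stance
   (first ~10 % of the gait cycle) of the vertical (Fy) and
   anterior–posterior (Fx) GRF components of both limbs is summarised by
   least-squares 5th-degree polynomial coefficients — a 24-element
   feature vector — and classified sport vs heels with an SVM.
2. **Height-gated identification.** Body height measured by two depth
   sensors from skeleton joint chains is corrected for heels
   (`BH_norm = BH_measured − 5·y` cm) and used to discard every enrolled
   subject whose height differs by more than ±2 cm. Within the reduced
   gallery, each probe stride is compared to every enrolled stride by
   dynamic time warping, giving five distances

   `V = [ρ_MSt,L; ρ_TSt,L; ρ_MSt,R; ρ_TSt,R; ρ_Stride; BH]`

   — mid-stance and terminal-stance phase distances per limb (each the
   sum of three per-component DTW costs) and a whole-stride distance
   (six alignments). Five rank-weighted k-nearest-neighbour voters, one
   per distance, accumulate weights `w_R = (k+1−R)/k` per neighbour
   rank; the subject with the largest total wins, with open-set
   rejection (`NONE`) on ties or totals below a threshold `Th`.

Because no force-plate/Kinect corpus of this kind is openly available,
the package ships a first-class seeded synthetic-gait generator
producing GRF strides with the canonical stance morphology (double
vertical peak ≈ 120 % body weight, anterior–posterior extremes ≈ 20 %
BW, lateral plateau ≈ 10 % BW, stance ≈ 60 % of the cycle) and
two-sensor skeleton streams with heel-height effects
(Δ ≈ 4.99 ± 0.75 cm), within-cycle head oscillation, tracking-state
dropout and sensor noise. Every stage of the pipeline is tested against
this generator.

## Worked example

Simulate a 50-subject cohort and run the standard enrollment/probe
scenarios (a: sport-only gallery and probes, GRF only; b: sport gallery,
mixed probes, GRF only; d: as b plus footwear recognition and the height
gate; e: as d with perfect footwear labels), 10 repetitions each:

```r
library(gaitid)
rep <- run_scenario(c("a", "b", "d", "e"), n_subjects = 50,
                    repetitions = 10, seed = 1)
summarize_scenarios(rep)
#>   scenario n_subjects    CCR  FRR   FAR
#> 1        a         50 100.00 0.00  0.00
#> 2        b         50  37.50 6.03 56.47
#> 3        d         50  49.33 2.40 48.27
#> 4        e         50  49.53 2.37 48.10
```

CCR is the percentage of probe strides assigned to the true subject,
FRR the percentage rejected as `NONE`, FAR the percentage assigned to a
wrong subject; the three always sum to 100. The grid reproduces the
qualitative findings of the footwear-change experiment: same-footwear
identification is near-perfect (a), a heels probe against a sport
gallery collapses (b), and the height gate recovers a large part of the
loss (d), with perfect footwear knowledge an upper bound (e). Absolute
rates depend on the generator's separability settings; the orderings do
not.

Single-probe identification:

```r
pop <- sample_population(population_config(n_subjects = 5, seed = 1))
ds  <- build_dataset(pop, per_subject_strides = 4,
                     footwear_plan = scenario_plan("b"), seed = 3,
                     sampling_rate_hz = 120)
pr  <- ds$probes[[1]]
identify(pr$stride, pr$bh_measured, ds$gallery, footwear_y = pr$true_y)
#> <vote_outcome> decided: S001 (top total 9.000)
```

A command-line interface wrapping the same functions
(`simulate`, `train-footwear`, `enroll`, `identify`, `evaluate`) is
installed at `system.file("cli", "gaitid", package = "gaitid")`.

## Documentation

The methods vignette (`vignettes/gait-identification.Rmd`) describes the
model, the generator's assumptions and limits, the tunable parameters
and the numerical choices in detail.
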