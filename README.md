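# socialsync

Sliding-window phase-synchrony analysis of social brain networks during
naturalistic video viewing.

## The problem

When a monkey (or any subject) watches videos of conspecifics interacting,
how does the *coupling* between regions of the social brain — superior
temporal sulcus, cingulate gyrus, premotor cortex — change from moment to
moment, and which connections care about *what kind* of social behavior is
on screen? `socialsync` implements the full analysis chain for that
question, for researchers working with ROI-level fMRI time series from
event-structured naturalistic designs:

1. **Dynamic functional connectivity.** Per ROI pair, relative phase
   synchrony: band-limit each residualized BOLD series to 0.01–0.5 Hz,
   take the analytic-signal phase φ(t), and compute the phase-locking
   value over 32-s windows offset by 2 s,

   PLV_ij(W) = | (1/N) Σ_{t∈W} exp( i·(φ_i(t) − φ_j(t)) ) |,  N = 16,

   which is 1 under perfect locking, ≈ √(π/4N) ≈ 0.22 for independent
   phases, and blind to signal amplitude by construction.
2. **Nuisance control at every level.** Volume-level residualization
   against CSF and reward-delivery regressors; motion-outlier flagging at
   mean + 2.5 SD of the volume-to-volume variance; fixation masking of
   stimulus regressors before convolution with a gamma hemodynamic kernel
   (mean lag 3 s, SD 1.5 s); window-level cleaning of the synchrony series
   against luminance, motion, gaze change and fixation; arcsine transform;
   averaging across repeated viewings.
3. **Edge-wise condition statistics.** Session-by-condition mean synchrony
   per edge → split-plot repeated-measures ANOVA (subject between,
   social condition within, sessions as units) → one-tailed p→z mapping →
   suprathreshold network at z > 2.05 (equivalently the strongest 15% of
   edges) → degree and eigenvector centrality of the binary network.
4. **Clip-onset-aligned contrasts.** 11-s synchrony segments around each
   social clip onset (4 s pre to 6 s post, 2-s hemodynamic lag), natural
   cubic-spline interpolation to a 0.5-s grid, baseline normalization,
   and per-timepoint t tests and condition contrasts
   (e.g. ambiguous > mean of affiliative and aggressive) within five
   anatomical edge groups, Bonferroni-corrected.

Because the motivating datasets are typically not deposited, the package
ships a first-class synthetic-session generator (`simulate_study()`) that
produces phase-coupled ROI BOLD with known ground truth — controllable
edge-level coupling boosts tied to behavior categories, realistic
schedules, confounds and fixation behavior — so every stage of the
pipeline is testable end to end with no external data.

## Worked example

Simulate a study in which viewing *ambiguous* social interactions boosts
the coupling of 18 designated cingulate–temporal and temporo–temporal
edges (boost Δκ = 0.4), then run the complete analysis:

```r
library(socialsync)
cfg   <- pipeline_config()
spec  <- default_coupling_spec(delta = 0.4)   # ambiguous-condition boost
study <- simulate_study(cfg, spec = spec, sessions_per_subject = 4, seed = 42)
res   <- analyze_study(study)

head(res$edge_stats[order(-res$edge_stats$z), ], 5)
#>    edge        F df1 df2            p        z
#> 93   93 32.71450   2  22 2.561170e-07 5.021673
#> 5     5 32.12682   2  22 2.972335e-07 4.993006
#> 78   78 27.15714   2  22 1.142841e-06 4.726371
#> 56   56 26.97488   2  22 1.204644e-06 4.715660
#> 59   59 25.93489   2  22 1.634987e-06 4.653090
```

Each row is one of the 120 edges: the within-session condition F from the
repeated-measures ANOVA with its degrees of freedom (2, 22 for 12 sessions
of 3 conditions), and the one-tailed z. How many of the 18 truly boosted
edges land in the strongest-15% network (18 edges)?

```r
ed <- edge_index(16)
designated <- paste(ed$i, ed$j) %in%
  paste(spec$designated_edges$i, spec$designated_edges$j)
sum(res$network_proportional$selected & designated)
#> [1] 14
```

14 of 18 recovered from only 12 sessions (the default 36-session design
recovers 15–18). Eigenvector centrality of the socially modulated network
points at the ROIs the boosted edges converge on:

```r
sort(res$eigencentrality, decreasing = TRUE)[1:4]
#>    STSm_R     TPO_L     CGp_L    STSp_R
#> 0.4897649 0.4629831 0.4205624 0.4115563
```

And the clip-aligned contrast shows ambiguous clips driving
cingulate–temporal synchrony above the other behaviors shortly after
onset (estimate on the arcsine-PLV scale; p Bonferroni-corrected over
21 timepoints × 3 contrasts):

```r
subset(res$contrasts, group == "cingulate-temporal" &
       contrast == "ambiguous>others" & time_s %in% c(2, 4))
#>    time_s   estimate        t     p_bonf
#> 76      2 0.01212254 3.294380 0.03537153
#> 80      4 0.01343915 2.744292 0.20427617
```

`write_study()` / `read_study()` persist studies as plain TSV trees;
`run_pipeline()` goes from a study directory (or a seed) to result tables
plus a JSON run manifest; `inst/cli/socialsync.R` wraps both for shell use:

```sh
Rscript inst/cli/socialsync.R simulate --seed 7 --out study/
Rscript inst/cli/socialsync.R run --data study/ --out results/
```

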