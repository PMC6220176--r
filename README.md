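# pulsecoupler

Single-cell imaging shows that ERK — the terminal kinase of the
Ras–MAPK growth pathway — activates in discrete stochastic pulses, and
that each pulse is preceded by a localized protrusion of the cell edge
enriched in active Ras and PI3K. `pulsecoupler` is an R package for
scientists studying this coupling. It provides:

- **A mechanistic model.** A stochastic excitable activator–inhibitor
  network on the cell perimeter (periodic 1-D grid, 300 points),

  ∂X/∂t = D_X ∇²X − a₁X − a₂(Y − R)X + a₃X²/(a₄² + X²) + a₅ + U_N,
  ∂Y/∂t = D_Y ∇²Y + ε(−Y + b₁X),

  integrated by Euler–Maruyama, whose mean inhibitor output U_E = ⟨Y⟩
  drives a zero-order ultrasensitive ERK switch

  dZ/dt = c₁( U_E (c₂−Z)/(c₃+(c₂−Z)) − c₄Z/(c₃+Z) − c₅Z ).

  Two presets reproduce the observed regimes: `high_threshold` (rare
  localized firings → discrete ERK pulses) and `low_threshold`
  (frequent firings → sustained ERK activation), and uniform
  sustained/transient stimuli reproduce growth-factor responses
  (global first activation, refractory-paced oscillation vs a single
  matched peak).

- **The image-analysis pipeline.** Frame-difference (percent-change)
  processing of time-lapse stacks with the published thresholds (100%
  over 6 min for boundary protrusions, minimum duration 5 min; 10% for
  interior flashes after boundary removal), perimeter kymographs,
  automatic cell segmentation, C/N-ratio and FRET-ratio reporter
  quantification, pulse calling at the 20% fractional-increase rule,
  cross-correlation and half-maximum lag analysis.

- **A ground-truthed synthetic generator** (`synth_movie()`,
  `synth_traces()`, `render_from_model()`) so every stage is testable
  without external data.

## Worked example

Simulate the high-threshold regime for a 2-hour-equivalent observation,
couple it to the ERK switch, and count discrete pulses:

```r
library(pulsecoupler)
params <- en_preset("high_threshold")
traj <- simulate_en(params, duration = 240, sample_every = 25, seed = 1)
erk  <- couple_en_to_erk(traj)
traj
#> Excitable-network trajectory: 961 samples x 300 grid points,
#> t in [0, 240] (120 displayed min)
erk
#> ERK trace: 961 samples, Z in [0.0006781, 0.9892] of pool c2 = 1
```

This run fires 12 discrete ERK pulses (Z rising above half of and
returning below 10% of its maximum), i.e. roughly one pulse every ten
displayed minutes, each triggered by a localized activator patch on the
perimeter.

Run the end-to-end synthetic pipeline — render a movie with four
planted protrusions, detect them by frame differencing, quantify the
reporter, and measure the protrusion→ERK coupling:

```r
res <- run_pipeline(list(mode = "synth", seed = 7))
res$protrusions[, c("id", "onset_min", "duration_min", "peak_area_px", "angle_rad")]
#>   id onset_min duration_min peak_area_px angle_rad
#> 1  1        10            7           44  0.000000
#> 2  2        37            6           44  1.570796
#> 3  3        63            7           44  3.141593
#> 4  4        90            7           44  4.712389
res$correlogram
#> Correlogram over lags [-30, 30] min: best lag 11 min (r = 0.764)
res$pulses[, c("onset_time", "peak_time", "fractional_increase", "fused")]
#>   onset_time peak_time fractional_increase fused
#> 1          0        26                 0.4 FALSE
#> 2         40        52                 0.4 FALSE
#> 3         67        79                 0.4 FALSE
#> 4         94       106                 0.4 FALSE
```

All four planted events are recovered at their scheduled onsets and
angles; each drives a reporter pulse whose 40% C/N increase equals the
planted magnitude times the coupling gain, and the positive best lag
says ERK follows protrusive activity.

A thin command-line wrapper lives at `inst/cli/pulse-coupler.R`:

```sh
Rscript inst/cli/pulse-coupler.R --mode synth --seed 7 --out results/
```

See the vignette (`vignettes/protrusion-erk-coupling.Rmd`) for the
model, the parameter calibration, all analysis conventions, and known
limitations.

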