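# iolsim

Programming and validating **temporal-multiplexing simulations of
multifocal and extended-depth-of-focus (EDOF) intraocular lenses**, plus the
defocus-curve analytics used to compare simulated and postoperative vision.

## The problem

Multifocal IOLs (trifocals, EDOFs) trade contrast for depth of focus by
superimposing focused and defocused images on the retina. Temporal-
multiplexing visual simulators reproduce a lens's through-focus behavior by
cycling an optotunable lens through a set of focal states faster than the
eye can follow (50 Hz, 20 ms cycle): the fraction of each cycle spent at an
addition — its *temporal coefficient* — weights that focal state's
contribution to the time-averaged retinal image. Programming a commercial
lens into such a simulator therefore means answering: *given the lens's
published bench optics, which dwell-time profile makes the tunable lens look
like it?*

`iolsim` implements that workflow end to end for users of bench MTF data
(vision scientists, ophthalmic-instrument engineers):

1. **TFVS estimation** — through-focus MTF at 15 cycles/degree (3-mm pupil)
   is normalized by the diffraction-limited MTF
   (`MTF_dl(s) = (2/π)(acos s − s√(1−s²))`, `s = ν/ν_c`), averaged across
   wavelengths with photopic luminous-efficiency weights
   (R/G/B = 0.11/0.99/0.15), and smoothed with a zero-phase Kaiser-window
   low-pass FIR into the estimated through-focus visual Strehl curve
   TFVS(d).
2. **Temporal-coefficient solving** — sparse nonnegative mixture
   decomposition `TFVS(d) ≈ Σ_k c_k · K(d + a_k)`, where `K` is the
   monofocal through-focus kernel (rectified diffraction defocus MTF) and
   `a_k` are candidate additions on a 0.05 D grid. Lawson–Hanson NNLS is
   followed by threshold pruning (dwells < 1% of the cycle) and backward
   elimination under a residual budget, yielding the handful of focal
   states real simulators use.
3. **Focimetry validation** — a simulated high-speed focimeter records the
   optical power of a first-order-lag lens model (deadbeat overdrive
   drive, configurable time constant) through the programmed cycle, bins
   the trace into effective dwell fractions, and compares the resulting
   TFVS against the nominal one.
4. **Defocus-curve analytics** — logMAR defocus visual acuity (DFVA)
   curves on the +1.00 to −4.00 D grid: RMSE-minimizing offset alignment,
   cross-correlation/RMSE/peak-shift agreement, depth of focus (range with
   logMAR < 0.20), and visual benefit/degradation at far (0 D),
   intermediate (−1.5 D) and near (−2.5 D) against a monofocal reference.
5. **Cohort statistics** — mixed-effect regression of depth-of-focus gain
   on monofocal baseline (per-subject random intercept), and
   repeated-measures omnibus tests (RM-ANOVA + Bonferroni, or Friedman +
   Tukey–Kramer on ranks, gated by Shapiro–Wilk normality).
6. **Synthetic data** — deterministic trifocal/EDOF/monofocal bench
   profiles with published add powers, and seeded subject cohorts with
   realistic (0.11 logMAR) inter-subject variability, so everything above
   is testable without any external data.

## Worked example

Program a trifocal-like design (adds +1.75/+3.5 D) from a synthetic bench
curve:

```r
library(iolsim)
curve <- make_synthetic_tfmtf(iol_fixtures()$trifocal_175_350)
res <- program_lens(curve)
print(res)
#> <lens_program> 8 temporal coefficients, validation PASSED
#>   reconstruction: r = 0.9985, RMSE = 0.0183
#>   focimetry:      RMSE = 0.0331, peak shift = 0.000 D
print(res$profile)
#> <temporal_profile> 8 states, 20 ms cycle (50 Hz)
#>  addition_D dwell_fraction dwell_ms
#>       -0.20         0.1536    3.073
#>        0.05         0.1294    2.587
#>        0.25         0.0940    1.879
#>        1.65         0.1928    3.857
#>        2.00         0.0926    1.852
#>        3.25         0.0830    1.660
#>        3.45         0.1190    2.379
#>        3.70         0.1357    2.713
```

The profile clusters around the design's three foci (far, +1.75 D, +3.5 D);
the reconstruction correlates with the estimated TFVS at r = 0.9985 with
RMSE 0.018 (peak-normalized visual Strehl units), and the simulated
focimetry check (τ = 1 ms lens) keeps the peaks in place. `plot_lens_program(res)`
draws the estimated/multiplexed/focimetry TFVS overlay.

A command-line front end wraps the two workflows:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "iolsim", package = "iolsim"))') \
    program-lens --config config.yaml --out outdir
```

with `config.yaml` holding `tfmtf_csv: my_lens.csv` plus any tunables
(`pupil_mm`, `nu_cpd`, `plane_factor`, `time_constant_ms`, validation
thresholds). `analyze-dfva` runs the defocus-curve workflow from a
`subject_id,lens,vergence_D,logmar` CSV.

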