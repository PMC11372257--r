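# tbkin — total-body PET kinetic modeling of dynamic time–activity curves

`tbkin` is an R package for compartmental kinetic analysis of dynamic
positron emission tomography (PET) data, built around 90-min total-body
scans of T-cell tracers such as [¹⁸F]F-AraG.  It is aimed at imaging
scientists who need the full quantification chain behind such studies —
from raw regional time–activity curves (TACs) and an image-derived blood
input to rate constants, macroparameters, and the statistics of paired
pre/post-therapy comparisons — together with the simulation machinery to
ask whether those quantities are actually identifiable at realistic noise.

## The model

The measured regional signal is

    C_m(t) = v_b · C_wb(t − t_d) + (1 − v_b) · C_t(t)

with fractional blood volume `v_b`, regional arrival delay `t_d`, and a
tissue response `C_t` from one of three nested compartment models: the
one-tissue model **1T4P** (`dC_t/dt = K1·C_wb − k2·C_t`), the irreversible
two-tissue model **2T5P** (`k4 = 0`), and the reversible two-tissue model
**2T6P** (`dC1/dt = K1·C_wb − (k2+k3)·C1 + k4·C2`,
`dC2/dt = k3·C1 − k4·C2`).  Fits are bounded multistart nonlinear least
squares with the delay estimated jointly; model selection uses the
small-sample corrected Akaike criterion
`AICc = n·log(RSS/n) + 2k + 2k(k+1)/(n−k−1)`.

From the selected fit the package derives the net influx rate
`Ki = K1·k3/(k2+k3)`, the total volume of distribution `VT = K1/k2`
(1T4P) or `K1/k2·(1+k3/k4)` (2T6P), its blood-volume-corrected form
`VT(vb) = vb + (1−vb)·VT`, windowed tissue-to-blood SUV ratios (SUVR),
and Logan graphical slopes (`K_Logan`, t\* = 30 min).  Blood inputs are
extended to a 10-h equilibrium horizon by a biexponential tail fitted on
14–90 min.  A Monte-Carlo practical-identifiability module reports
bias/SD/RMSE of every parameter from 100 simulated noisy refits, with
fixed-delay and 60-min-truncation variants, and normalized sensitivity
curves.  Exact small-sample statistics (permutation Spearman, enumerated
Wilcoxon signed-rank) cover the surrogacy and paired-comparison analyses.

## A worked example

Simulate a noisy tumor-like TAC at the calibrated noise level, fit all
three models, and select by AICc:

```r
library(tbkin)
sch   <- default_schedule()                  # 30×2 s, 12×10 s, 7×60 s, 16×300 s
input <- generate_input(rv_input_shape(), sch)
truth <- tumor_preset()                      # vb=.05 K1=.4 k2=.3 k3=.06 k4=.03
obs   <- generate_region_tac(list(params = truth), input, sch,
                             noise_scale = 0.202, seed = 7, region = "tumor")
fit   <- fit_all_models(obs, input, seed = 1)
summary(fit)
#> Kinetic fit (2T6P)
#>   vb=0.1135  K1=0.4457  k2=0.3617  k3=0.08495  k4=0.036  td=0.104 min
#>   RSS 128.3 on 65 frames, AICc 57.630
#>   Ki=0.08478 mL/min/mL  VT=4.141  VT(vb)=3.784
round(attr(fit, "delta_aicc"), 2)
#>  1T4P  2T5P  2T6P
#> 10.46  0.15  0.00
```

AICc picks the reversible two-tissue model (the generating kind), and the
fitted `VT = 4.14` sits within 4% of the true value 4.0 at this noise
level; the individual rate constants scatter more, which is exactly what
the identifiability module quantifies.  The Logan slope from the same
noisy data,

```r
logan(obs, extrapolate_input(fit_biexp_tail(input), 600), 30)
#> K_Logan = 3.765  (12 points after t* = 30 min)
```

agrees with the blood-volume-corrected `VT(vb) = 3.85` of the ground
truth, illustrating why the Logan slope and late-window SUVR serve as
surrogates for `VT` in low-blood-volume regions.

Cohort-scale runs use `run_simulate()` → `run_fit()` →
`run_identifiability()` / `run_stats()`, or the thin command-line wrapper:

```sh
exec/tbkin all --outdir results/demo --seed 42
```

which writes TAC tables, per-region fit and macroparameter CSVs, the
identifiability report, surrogacy correlations, paired exact Wilcoxon
tests, and a JSON manifest per stage.

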