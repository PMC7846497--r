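# lvattention

Infer time-varying competitive interactions among topics of public
attention from relative search-interest time series (Google-Trends-style
0–100 weekly panels), using an integrable nonautonomous Lotka–Volterra
model of attention shares.

## Who this is for

Researchers in infodemiology, computational social science and
epidemiological modelling who want to ask, from search-volume data alone:
*does rising attention to one topic feed or suppress attention to
another, and does that relationship change over time?* A canonical use
case is the COVID-19 outbreak, where attention to unemployment, disease
symptoms and news consumption became tightly coupled within weeks.

## The model

Attention is treated as a market share. With `N` tracked topics plus an
*outside search* option absorbing everything else, the share of topic `i`
at time `t` is a logit discrete-choice model in latent utilities `f_i(t)`:

```
S_i(t) = exp(f_i(t)) / (1 + Σ_j exp(f_j(t)))        i = 1…N
S_0(t) = 1         / (1 + Σ_j exp(f_j(t)))
```

If the `f_i` are twice continuously differentiable, these shares are the
unique global solution of the nonautonomous Lotka–Volterra system

```
dS_i/dt = g_i(t) S_i (1 − S_i) − Σ_{j≠i} g_j(t) S_j S_i ,   g_i(t) = df_i/dt
```

— logistic growth plus competition, with time-varying interaction
coefficients `g_i(t)`. The pipeline inverts this construction:

1. **Shares** — the 0–100 panel is renormalized per week and scaled by a
   coverage constant `α` (outside share `1 − α`); all scientific outputs
   are provably invariant to `α`.
2. **Utilities** — recovered pointwise as log-odds,
   `f_i = ln S_i − ln S_0`.
3. **Smoothing** — each utility is fitted by least squares with a Fourier
   series of order `n` (or a polynomial), giving an analytic `f_i(t)`.
4. **Coefficients** — `g_i(t)` is the exact analytic derivative of the
   fit.
5. **Roles** — at each time, the sign pattern of `(g_A, g_B)` classifies
   every topic pair: competition `(+,+)`, predator–prey `(+,−)` with the
   positive topic as predator, mutualism `(−,−)`, commensalism `(−,0)`,
   amensalism `(+,0)`, neutralism `(0,0)`; signs are banded by a
   scale-adaptive threshold `eps`.
6. **Intensity** — `Σ_i |g_i(t)|`, with a window-ratio changepoint
   detector for regime shifts.
7. **Diagnostics** — per-topic mean squared error between observed and
   fitted shares.

A synthetic-data generator produces Trends-like panels from known
ground-truth utilities (regimes, C²-blended changepoints, observation
noise, joint 0–100 normalization), so the entire pipeline is testable
end to end without any live data source.

## Worked example

```r
library(lvattention)

scenario <- pandemic_preset(noise_sd = 2, seed = 1)  # known ground truth
gen <- generate_trends(scenario)                     # Trends-like panel
res <- run_analysis(gen$series)                      # full pipeline
print(res)
```

```
<lv_analysis> 4 topics x 52 weeks
  fit: fourier order 3 | eps: 0.03781 | changepoint week: 45
  share-scale MSE:
unemployment     symptoms         news         porn
   7.151e-05    2.087e-05    3.044e-05    3.907e-05
  final-week roles:
    unemployment ~ symptoms : predator-prey (predator: unemployment)
    unemployment ~ news : predator-prey (predator: unemployment)
    unemployment ~ porn : predator-prey (predator: unemployment)
    symptoms ~ news : mutualism
    symptoms ~ porn : mutualism
    news ~ porn : mutualism
```

Reading this: the automatic order selection chose a Fourier order of 3;
the zero-threshold `eps ≈ 0.038` per week is 10% of the largest
coefficient magnitude observed; the intensification changepoint was
located at week 45, one week after the generator's true regime change at
week 44. The per-topic MSEs (share² scale, here ~10⁻⁵–10⁻⁴) measure how
closely the fitted logit system reproduces the observed shares. The role
table recovers the generator's late-regime structure: the "unemployment"
topic predates every other topic while the remaining three are in
pairwise mutualism.

`run_analysis(..., out_dir = "results/", plot = TRUE)` additionally
writes `report.csv` (per-week pair roles and coefficients), `mse.csv`,
`intensity.csv`, a reproducibility `manifest.json` and diagnostic plots.
Real Google Trends "multiTimeline" CSV exports are read directly:
`run_analysis("multiTimeline.csv", ...)`.

A command-line wrapper is installed under `inst/cli/`:

```sh
lv-attention synth   --out synth/ --seed 5
lv-attention analyze --input synth/trends.csv --out results/
lv-attention report  --input results/report.csv
```

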