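---
title: "Methods: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(hepadyn)
```

`hepadyn` quantifies three live-cell stress-response readouts of hepatocyte
reporter lines — NF-kB (GFP-p65) nuclear translocation oscillations, Srxn1-GFP
(Nrf2 target) induction, and Annexin-V-labelled cell death — plus a companion
transcriptomics arm (gene-set filtering, clustering, enrichment). Because the
original microscopy and expression data are not redistributable, the package
ships a synthetic-data generator with exact ground truth; every analysis stage
is validated against what was planted. This vignette documents the models, the
estimators, and the numerical decisions, in enough detail to re-derive them.

## 1. The trace model

A cell's NF-kB activation is summarized as the nuclear-to-cytoplasmic
GFP-p65 intensity ratio \(r(t)\). The generator models a TNF&alpha;-driven
oscillatory response as a baseline of 1 plus damped Gaussian bumps:

\[
r(t) = 1 + \sum_{k=0}^{K-1} A\, d^{\,k}\,
       g\!\left(\frac{t - \mu_k}{w}\right) + \varepsilon(t),
\qquad g(x) = e^{-4\ln 2\, x^2},
\]

where \(g\) is a unit-height bump with full width at half maximum \(w\)
(`peak_width_min`, default 30), \(A\) is the first-peak amplitude
(`amplitude`, 1.0) and \(d\) the per-peak damping (`damping`, 0.5).
Peak centres are
\(\mu_k = t_1 + k\,\Delta + \delta_{k>0}\,\tau + \eta_k\) with first peak
\(t_1\) = `first_peak_min` (30 min), inter-peak interval \(\Delta\) =
`inter_peak_min` (120 min), treatment delay \(\tau\) =
`treatment_delay_min` (applied to every peak after the first — drug
pre-exposure retards the feedback-driven second translocation, not the
initial response), and cell desynchronization
\(\eta_k \sim N(0, (k \cdot \texttt{desync\_sd\_min})^2)\), which grows with
peak index because timing variability accumulates through successive
IkB&alpha;/A20 feedback cycles. \(\varepsilon\) is white Gaussian noise
(`noise_sd`). Defaults (30/120 min, 6-min sampling over 6 h) mirror the
published control timing: population maxima near 30 and 150 min.

```{r traces}
cfg <- sim_config(seed = 1, n_cells = 50)
sim <- simulate_ratio_traces(cfg)
summ <- population_summary(sim$traces)
plot_mean_trace(summ)
c(mean_second_peak = summ$mean_second_peak_min,
  fraction_ge3 = summ$histogram$fraction_ge3)
```

## 2. Rendering and image-based measurement

`render_p65_stack()` turns traces into a two-channel stack (Hoechst-like
nuclei + GFP) on a jittered grid: each cell is a nuclear disk (radius
`nucleus_radius_px`) inside a cytoplasmic disk, with nuclear intensity
\(b + r(t)\,c\) over cytoplasm level \(b + c\) (background \(b\), cytoplasm
contrast \(c\)), optional Poisson noise. The rendered cytoplasm extends two
ring-widths plus 2 px beyond the nucleus so that the *measured* ring (below)
always sits inside true cytoplasm; with a ring exactly as wide as the
measured one, ring pixels straddle the cell edge and the recovered ratio is
biased upward by ~15%.

Measurement reverses the rendering without using ground truth:

* **Segmentation** — Otsu threshold on the nuclei channel, distance-map
  watershed (`EBImage::watershed`, tolerance 1) to split touching nuclei,
  small components removed.
* **Tracking** — greedy nearest-neighbour assignment in ascending distance,
  gated at `max_disp_px`; tracks covering under 80% of frames are dropped.
* **Cytoplasm** — a ring of width `ring_width_px` around each nucleus,
  assigned by `EBImage::propagate` so adjacent cells partition shared
  territory instead of double-counting it.
* **Ratio** — per frame, the median intensity outside dilated nuclei is the
  background; the ratio is (nuclear mean − background)/(ring mean −
  background), `NA` when the denominator is not positive.

On rendered stacks the full chain recovers input traces with a mean absolute
error below 2% of the trace level.

## 3. Peak detection and oscillation features

Traces are min-max normalized per cell (degenerate constant traces flagged,
not silently scaled), smoothed with a 3-point moving average — enough to kill
single-sample noise spikes at 6-min sampling without displacing 30-min-wide
peaks — then scanned for strict local maxima. Each candidate gets a
topographic prominence (height above the higher of the two minima separating
it from taller neighbours); candidates below 0.1 (10% of the normalized
range) are discarded. A 30-min minimum separation is enforced tallest-first
(earliest on ties), i.e. one physiological translocation cannot be counted
twice. Accepted peak times are refined by quadratic interpolation through
the three samples around the maximum, giving sub-frame resolution; the
refinement is clamped to ±half a frame.

Per-cell features: peak count, times, heights, width at half prominence
(the per-peak "period"), successive inter-peak delays (notably peak 1 →
peak 2), and nuclear entry/exit rates. Entry and exit are defined as the
extremal first differences of the normalized signal per minute within one
period around the peak (largest rise; largest magnitude of fall), averaged
over peaks — a deliberately simple, derivative-based definition chosen over
model fitting because it needs no convergence diagnostics and behaves
monotonically with the underlying bump width.

Population readouts: the 0–5 peak-count histogram (≥5 capped, preserving
the published class layout), the fraction of cells with ≥3 translocations,
and `population_delay_shift()` — the treated-minus-control difference in
mean second-peak time over cells with at least two detected peaks. The
per-cell mean is the default (it weights every responding cell equally and
has a standard error the tests can reason about); a `mean_trace` variant
detecting peaks on the population-mean trace is provided for comparison.
With 300 cells per arm, a planted 26-min delay is recovered to within one
6-min frame:

```{r delay}
control <- simulate_ratio_traces(sim_config(seed = 1, n_cells = 300))
treated <- simulate_ratio_traces(
  sim_config(seed = 2, n_cells = 300,
             oscillation = list(treatment_delay_min = 26)))
population_delay_shift(treated$traces, control$traces)
```

## 4. Srxn1-GFP reporter scoring

The Nrf2-activity score of a frame is: connected components (8-connectivity)
of pixels above a detection level, components under 45 px discarded (about a
quarter of a cell — sub-cellular speckle is not induction), then

\[
\text{score} = \frac{\#\text{pixels} \times
  \overline{(\text{intensity} - \text{background})}}{\#\text{nuclei}}.
\]

The detection level and the density baseline are deliberately separate: the
mask uses background + 3 robust s.d. (median + 3 MAD) so camera noise cannot
percolate into components, while densities are measured relative to the
background median so the score stays linear in true signal. Fold induction
is the treated/control score ratio at the 24-h endpoint (nearest sampled
frame) — an endpoint ratio rather than an AUC ratio because induction
plateaus and the endpoint is where the published per-drug values are read.

The generator drives per-cell logistic induction
\(I(t) = P / (1 + e^{-(t - t_0)/\tau})\) with onset \(t_0\) jittered across
cells and \(\tau = P/(4\,\text{rate})\), so `rate` is the maximal slope in
intensity/min. A 4× plateau ratio between arms is recovered as a fold
induction within 10% across replicate wells.

## 5. Death curves and the TNFα synergy statistic

Cell death times are drawn from a piecewise-exponential hazard: baseline
`baseline_hazard_per_h`, multiplied by `tnf_multiplier` after TNF&alpha;
addition (`tnf_add_min`, default 480 = the 8-h pre-exposure). Sampling
inverts the cumulative hazard of a uniform draw, and cells whose integrated
hazard never reaches the draw survive the movie. Annexin-V labelling is
cumulative: once positive, always positive.

The measured curve is the percent of occupied cell area that is
Annexin-positive per frame, capped at 100. Occupied area comes from the
transmission channel by local-variance texture: cells are textured,
background is flat; the variance image is split by Otsu's threshold (robust
when background variance is numerically zero, where a relative-to-median
rule collapses). Curves are summarized by the endpoint percentage and a
trapezoidal AUC in %·h. The synergy statistic is a plain difference,

\[
\text{synergy} = \%\text{dead}_{\text{drug+TNF}\alpha} -
                 \%\text{dead}_{\text{drug}},
\]

in percentage points — not a ratio, so a drug with near-zero solo toxicity
but strong co-toxicity (the sensitization phenotype of interest) is not
inflated to an unstable fold. `dili_summary()` ships a 15-drug reference
table whose synergy column is reproduced exactly by `tnf_synergy()`.

```{r synergy}
d <- dili_summary()
all.equal(tnf_synergy(d$pct_dead, d$pct_dead_tnf), d$pct_increase)
```

## 6. Gene sets, filtering, clustering, enrichment

Gene-set catalogs (GMT, parsed with `fgsea::gmtPathways`) are pooled by
`union_catalog()` with per-gene provenance. `filter_responsive()` keeps a
candidate gene when, for at least one model treatment, adjusted p ≤ 0.05,
average log2 expression ≥ 5, and |log2FC| meets a category-specific cutoff
— 1.5 for the oxidative-stress set, 2.0 for the inflammatory set. All
comparisons are inclusive (a gene at exactly the threshold passes); the two
cutoffs differ so the filtered sets end up comparable in size, and
`sweep_lfc_threshold()` exposes the size-versus-cutoff curve used to make
that choice. DEG selection for enrichment uses |log2FC| ≥ 1.3, p ≤ 0.05,
expression ≥ 7.

Clustering is Manhattan distance with Ward linkage, default `"ward.D"`:
applied directly to an (unsquared) Manhattan matrix it reproduces the legacy
"ward" behaviour of older clustering stacks, which is what heatmaps of this
kind historically used; `"ward.D2"`/Euclidean are available for the textbook
criterion. Missing (gene, treatment) fold changes are imputed as 0 for
clustering only — never for filtering — with a warning.

Enrichment is the right-tailed Fisher exact test,
\(p = P(X \ge k)\) computed as `phyper(k - 1, m, u - m, s, lower.tail =
FALSE)`, with the pathway intersected with the universe first and the
selected list required to be a subset of it. Raw p-values (as −log10 p) are
the headline statistic to match the published presentation;
Benjamini–Hochberg q-values across tested pathways are attached alongside.
Overlap genes are summarized as an arrow: mean |log2FC| magnitude and the
sign of the mean signed log2FC.

The DEG generator plants an antioxidant block (induced by oxidative model
compounds and severe hepatotoxicants) and an inflammatory block (induced by
cytokine models, suppressed by hepatotoxicants) on a background of null
genes. Its adjusted p-values are a deterministic monotone function of the
planted signal-to-noise ratio — this module *consumes* differential
expression results, it does not re-derive them from replicates.

## 7. Determinism, sizes and what the generator does not model

All generators are seeded; distinct stages use distinct seed offsets so
enabling one stage never perturbs another's draws. Pipeline runs
(`run_simulate()` / `run_analyze()`) write a manifest with configuration,
seed, package version and MD5 of every artifact; identical configurations
are byte-identical. Default problem sizes (50 cells, 512-px frames, 300
traces per arm for timing claims) are the package's own choices: large
enough that population means beat the one-frame tolerances, small enough to
run in seconds on one CPU.

The generator is a measurement-validation instrument, not a biophysical
model: it does not simulate IkB&alpha;/A20 feedback kinetics (bump trains
stand in for them), cell division, migration or crowding beyond grid
jitter, photobleaching, or spectral crosstalk. Claims about real biology
should rest on real images; claims about this package's estimators rest on
what was planted here.
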