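---
title: "Quantifying junctional protein dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying junctional protein dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frapkit)
```

## The measurement problem

Adherens-junction proteins such as E-cadherin exchange between a mobile,
diffusing membrane pool and a pool stably anchored at cell-cell contacts.
Fluorescence recovery after photobleaching (FRAP) measures that exchange: a
small region of a GFP-tagged junction is bleached and the return of
fluorescence is imaged over minutes. Two quantities summarize the kinetics:

* the **recovery rate** $\tau$ (per second), usually reported as the
  half-life $t_{1/2} = \ln 2 / \tau$, and
* the **mobile fraction** $M$, the proportion of the tagged pool that
  exchanges into the bleached region; its complement $1 - M$ is the
  immobile fraction.

Published reference points for junctional E-cadherin span the full range:
roughly 90% mobile at brand-new cell contacts, about 50% once clusters
engage the cytoskeleton, and under 10% at mature junctions. These three
regimes are the recovery targets the synthetic benchmark in this package is
built around.

The same imaging experiments also ask a simpler question - *how much*
protein sits at a junction - which `frapkit` answers with per-pixel
intensity quantification against a reference cell population, plus ordinary
densitometry and replicate statistics (ANOVA) for the surrounding assays.

## The FRAP model

Intensities are processed per cell (trace) in three steps.

**1. Photofading correction.** Repeated imaging bleaches the whole cell, so
the ROI signal decays even without molecular exchange. The whole-cell mean
intensity measures that fading directly, and each ROI frame is divided by
the whole-cell signal expressed relative to its pre-bleach mean:

$$\tilde I_i = \frac{I_i}{C_i / \bar C_{\text{pre}}}.$$

This assumes fading acts as a shared multiplicative factor on both
channels - the simplest model under which the correction is exact, and the
one the synthetic generator implements. A constant whole-cell signal leaves
the trace untouched (identity), which the tests assert.

**2. Pre-bleach normalization.** All values are converted to percent of the
mean pre-bleach ROI intensity, so the pre-bleach level is 100 by
construction. Any constant factor left over from step 1 cancels here; that
is why the corrected-and-normalized trace of a noiseless faded simulation
equals the ideal trace to machine precision even though the corrected trace
alone is only proportional to it.

**3. Single-exponential fit.** Post-bleach frames only ($t \ge 0$, with
$t = 0$ at the first post-bleach frame) are fitted to

$$I(t) = P - (P - I_0)\,e^{-\tau t},$$

with the plateau $P$, the immediate post-bleach level $I_0$, and $\tau$ all
free. Pre-bleach frames serve normalization only; a one-phase kinetic
description is used throughout (no reaction-diffusion modelling, no
two-component exponentials).

From the fit, $t_{1/2} = \ln 0.5 / (-\tau) \equiv \ln 2/\tau$, and the
fractions follow one of two conventions:

* `full_scale` (default, standard FRAP practice): recovery rescaled to the
  bleached amplitude, $M = 100\,(P - I_0)/(100 - I_0)$. This is the only
  convention under which the generator's ground-truth $M$ is recovered
  exactly, which is why it is the default.
* `percent_of_prebleach`: the literal reading "percentage recovery at
  plateau", $M = P$. Selectable because the phrase is genuinely ambiguous
  in common methods descriptions; nothing downstream depends on the choice.

In both conventions the immobile fraction is defined as $100 - M$, so the
two always sum to 100 exactly.

## Numerical choices

* **Optimizer.** Levenberg-Marquardt (`minpack.lm::nlsLM`) with box bounds
  $\tau \in [10^{-5}, 10]$ s$^{-1}$ and $P, I_0 \in [0, 200]$ percent.
* **Initialization.** $I_0$ from the first post-bleach frame; $P$ from the
  mean of the last three frames; $\tau$ from the empirical time at which
  the trace first crosses $(I_0 + P)/2$, falling back to 0.05 s$^{-1}$
  when it never does.
* **Degenerate fits.** A fit is flagged `converged = FALSE` - and excluded
  from condition summaries while remaining in the per-trace table - when
  the optimizer fails, $\tau$ lands on a bound, the amplitude $P - I_0$ is
  negligible (a flat trace makes $\tau$ unidentifiable), or $P < I_0$.
  Flag-and-exclude was chosen over failing the batch because single
  uninformative cells are routine in FRAP sessions.
* **Pooling.** Condition summaries report mean ± SEM (sample sd over
  $\sqrt{n}$) across converged cells, and a warning is logged when fewer
  than 12 cells contribute, the customary minimum per condition.
* **Plateau.** The fitted asymptote $P$ by default; `plateau = "empirical"`
  substitutes the mean of the last three frames for workflows that define
  the plateau directly off the curve.

## Junction intensity quantification

Junction measurement takes a channel image plus an integer label mask
(0 = background). Per junction it reports the **per-pixel mean** - total
intensity over pixel count - which calibrates junctions of different
size/area onto one scale. Hand-drawn ROIs were deliberately replaced by
label masks: a mask is data, reproducible and versionable, while interactive
line scans are not. A percentile thresholder (`threshold_junction_mask`) is
included for exploration but is not part of the quantitative surface.

Junctions are classified marker-positive when their per-pixel marker-channel
mean exceeds a threshold (ties count as negative, a deterministic rule).
The default threshold, background mean plus five background standard
deviations (`suggest_marker_threshold`), is an explicit, data-driven choice;
no universal criterion for "marker-positive" exists. All records are pooled
across images before normalization (per-image normalization is available by
simply running images separately); the pooled convention matches how
multi-image junction datasets are usually reported.

Normalization divides every junction's per-pixel mean by the mean over
marker-negative junctions, pinning the reference population's average at
exactly 1 and expressing marker-positive junctions as fold differences.
Densitometry follows the same pattern one level up: band / loading-control
ratios expressed as percent of the control-condition mean.

## Assay statistics

One- and two-way ANOVA are computed from explicit sums of squares - cell,
marginal and grand means - rather than delegated, so every term is
auditable; the only special-function dependency is the F-distribution upper
tail (`stats::pf`, i.e. the regularized incomplete beta). The two-way
decomposition is restricted to balanced designs, where it is unambiguous
and the effect sums of squares add exactly to the total; unbalanced tables
raise an error instead of silently picking a Type-I/II/III convention. No
post-hoc tests are provided: the assays this serves report omnibus
significance only. Permeability is summarized as fold change over the basal
condition (`lower / reference`), since raw lower-chamber fluorescence has
no natural units.

```{r anova}
anova_one_way(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
```

## What the synthetic generator does (and does not) emulate

`simulate_frap_traces` reproduces the acquisition design of a junctional
FRAP session: three pre-bleach frames 10 s apart, post-bleach frames at
0 s and 5 s, then every 15 s to 300 s; a 4 x 4 µm bleach ROI (metadata);
pre-bleach intensity 1000 AU; bleach depth 0.2; recovery at a known
$(\tau, M)$; whole-cell photofading at 0.002 s$^{-1}$ as a shared
multiplicative exponential; and multiplicative Gaussian noise with sd a
fixed fraction (default 2%) of the ideal intensity, matching the
intensity-proportional scaling of fluorescence shot noise at these count
rates (an additive-Poisson mode is available behind `noise_model`).
Junction images place 1-2 px wide straight segments of known per-pixel
intensity on a non-overlapping grid; assay tables are cell means plus
Gaussian noise.

Real data differ in ways the generator deliberately ignores: bleach-spot
diffusion profiles and optics (PSF), junction curvature and drift,
segmentation error, spatially correlated noise, and any coupling between
fading and expression level. Passing the parameter-recovery tests therefore
shows the *arithmetic* of the pipeline is right under its stated model; it
does not validate the model against microscope physics.

Generator defaults are the benchmark's study conditions and are not tuned:
12 cells per condition (the customary pooling minimum), 2% noise, bleach
depth 0.2, $\tau = 0.05$ s$^{-1}$ ($t_{1/2} \approx 14$ s, mid-range for
junctional E-cadherin), fading 0.002 s$^{-1}$ (about 45% whole-cell loss
over the 330 s session - strong enough that an uncorrected analysis fails).

## Problem sizes and runtime

The test-suite simulations are sized for interactive use: 12-24 traces of
25 frames per FRAP scenario, 256 x 256 px junction images with 30
junctions, 200-2000 replications for the distributional checks (null
rejection rates, permutation agreement at 10,000 shuffles). The whole suite
runs in well under a minute; the demo pipeline
(`run_pipeline(system.file("extdata", "demo-config.json", package =
"frapkit"))`) completes in a few seconds.

```{r demo}
est <- analyze_frap_experiment(
  simulate_frap_traces(sim_frap_config(mobile_fraction_true = 0.9,
                                       seed = 1))$traces,
  rep("new_contact", 12))
subset(est$summary, metric == "mobile_pct")
```

## Known limitations

* One-phase exponential kinetics only; junctions with distinct fast/slow
  exchanging pools will be summarized by an effective rate.
* The photofading model is multiplicative and shared between channels;
  fading that differs between the ROI and the rest of the cell (local
  bleaching, focus drift) is not corrected.
* Junction segmentation is an input, not a product, of the package.
* Two-way ANOVA requires balance; unbalanced designs need a different tool
  (e.g. linear models with explicit contrasts).
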