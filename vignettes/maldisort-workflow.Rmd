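---
title: "Dichotomous sorting of MALDI-TOF spectra: models, parameters and operating regime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dichotomous sorting of MALDI-TOF spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Whole-cell MALDI-TOF mass spectrometry reduces a biological sample to a
centroid peak list: discrete (m/z, intensity) pairs, singly charged by
assumption. Two-class ("dichotomous") questions — species A or B, resistance
gene present or absent, toxin producer or not — can then be answered by
supervised learning on those peak lists: a training plate of labelled spots
builds a model, a separate scoring plate evaluates it, and performance is
summarized by diagnostic sensitivity, specificity, and the Youden index

$$J = \mathrm{sens} + \mathrm{spc} - 1,$$

with $J = 1$ perfect sorting, $J = 0$ chance, and $J < 0$ a systematically
inverted classifier.

The scientific crux is *which molecules the instrument can see*. Signal per
spotted amount falls steeply with analyte mass — empirically close to a power
law, about two orders of magnitude of signal lost per decade of molecular
weight — so intact-protein (linear TOF) spectra of a bacterial lysate show a
few dozen peaks, almost all below 10 kDa, although roughly 80 % of the
proteome is heavier than that. Tryptic digestion moves every protein into
peptide fragments of roughly 0.7–1.5 kDa, where the instrument is most
sensitive and reflectron acquisition resolves sub-Da differences. Under a
power-law attenuation of magnitude $s$, replacing a parent of mass $M$ by a
fragment of mass $m$ gains

$$E = (M/m)^{s},$$

i.e. 100-fold for a 10 kDa parent and a 1 kDa fragment at $s = 2$
(`enhancement_factor()`). Whether that chemistry step actually improves
machine-learning sorting — and when it is worth the effort — is what this
package lets you study end-to-end without an instrument.

## The workflow

1. **Peak-list I/O** (`read_peaklist()`, `read_manifest()`): two-column
   comma-delimited centroid exports plus a manifest tying spot files to class
   labels and train/score roles.
2. **Binning** (`bin_scheme()`, `assign_bin()`, `build_feature_table()`):
   the m/z axis is divided into ranges, each with fixed bin centers every
   $\delta M$ Da and an acceptance tolerance (full window `width`). A peak is
   assigned to the nearest center of its containing range iff its distance is
   at most `width / 2`; peaks in coverage gaps are dropped. Feature tables
   are spots × bins, binary (peak present) or intensity (max within bin).
3. **Classification** (`train_sorter()`, `run_grid()`): gradient-boosted
   decision trees (xgboost, histogram method), over a grid of
   ensemble sizes {50, 101, 401, 701}, feature-histogram granularities
   {20, 40} and learning rates {0.01, 1e-4, 1e-5} — 24 trials
   (`default_grid("full24")`), or the documented 12-trial subset at 20 bins
   (`"paper12"`).
4. **Evaluation** (`sens_spc_j()`, `roc_scatter()`,
   `compare_conditions()`): per-trial sens/spc/J; ROC scatter of the
   dichotomous trials with multiplicities (not threshold-swept curves — each
   trial is a single operating point); Welch's two-sample t-test on the
   per-trial J values of two conditions plus the ratio of their means.
5. **Simulation** (`sim_config()`, `render_dataset()`): a synthetic
   two-class proteome and its intact/digested spot spectra, below.

`run_pipeline()` wires 2–4 together for any dataset;
`inst/scripts/maldisort.R` exposes `simulate` and `run` subcommands for
shell use.

## Binning choices

The default schemes encode mode-specific m/z reproducibility:

* intact (linear TOF), 500–20,000 Da in five ranges with widths
  1.25 / 2.2 / 3.5 / 8 / 35 Da and spacings 1 / 2 / 5 / 10 / 50 Da
  (3060 bins);
* digested (reflectron), 200–6,999 Da in six ranges, all 0.5 Da wide with
  1 Da spacing (6794 bins).

Three details are deliberately pinned down because they are easy to get
subtly wrong:

* **Anchor.** Bin centers start at each range's printed start and step by
  $\delta M$; the label is the center formatted as text. Anchoring at the
  range start is reproducible and auditable.
* **Overlap and ties.** In the first intact range the tolerance (1.25 Da)
  exceeds the spacing (1 Da), so acceptance windows overlap;
  nearest-center assignment resolves the overlap deterministically and an
  exact midpoint tie goes to the lower center.
* **Gaps.** Ranges are half-open `[start, end)` and tolerances narrower
  than the spacing leave uncovered slivers (e.g. 30 % of the 2500–7000 Da
  range; the 998.25–999.75 Da seam of the digested scheme). Peaks there are
  dropped, exactly as a tolerance-based grouping implies.

The guiding principle — a bin must be wider than the m/z wobble of the same
peak across spots — is audited by `check_jitter()`: it warns whenever
`width < 4 * sigma_jitter` at a range midpoint.

## The synthetic generator

`sim_config()` fixes a generative model with these defaults:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 5445 | proteome size (proteins > 3 kDa) |
| `mass_mu`, `mass_sigma` | 4.46, 0.55 | log10-mass normal, truncated to 3–200 kDa; puts ~80 % of proteins above 10 kDa |
| `abundance_sigma` | 0.8 | log10 relative molar abundance ~ Normal(0, 0.8) |
| `slope_magnitude` | 2 | attenuation decades lost per decade of mass |
| `spots_per_class` | 48 | per role → 192 spots per mode |
| `preset` | easy / hard | 50 unrestricted vs 5 high-mass bottom-quartile class-specific proteins per class |
| noise: `intensity_sigma_log` | 0.7033 | lognormal spot noise ⇒ replicate RSD = 80 % |
| noise: `jitter_intact`, `jitter_digested` | 1.8e-4, 2e-5 | m/z sd per Da of mass |
| noise: `lod_intact`, `lod_digested` | 1.0, 0.1 | per-mode detection floors |
| noise: `max_peaks` | 2000 | centroid export capacity |
| digestion | N(1100, 300) clipped to 500–3000 Da, min fragment 200 Da | tryptic fragment mass distribution |

A spot is rendered as: one candidate peak per protein (intact) or per
tryptic fragment (digested) at the jittered mass, expected height
`abundance * (mass/1000)^(-slope_magnitude)`, multiplied by the lognormal
spot noise; candidates survive if the noisy height reaches the mode's
detection floor and the m/z lies inside the acquisition window (500–20,000
Da linear, 200–7,000 Da reflectron), and the `max_peaks` most intense
survivors are exported. Noise-free renders recover the attenuation slope
exactly, which the test suite asserts.

Design decisions worth spelling out:

* **Mass-level digestion.** Fragments are drawn from a mass distribution,
  not from in-silico cleavage of sequences; every quantity the workflow
  uses lives in mass space, and sequence-level trypsin rules (cleave after
  K/R, not before P) are an extension point, not a need. Crucially the
  fragment list is sub-seeded by protein id, so a protein produces the
  *same* fragments in every sample — otherwise no cross-sample peptide
  pattern would exist to learn.
* **Per-mode detection floors.** Linear and reflectron acquisitions have
  different sensitivities, so one threshold cannot describe both. The
  intact floor is calibrated so a default intact spot keeps at most ~10
  peaks above 10 kDa (a handful is typical; the tests assert ≤ 10); the
  reflectron floor places a median-abundance 1 kDa peptide one decade above
  it.
* **Per-mode jitter.** A single jitter coefficient cannot satisfy the
  bin-width principle for both schemes: 4σ of a 2e-4 coefficient is 3.8 Da
  at the 2500–7000 Da intact midpoint (width 3.5) and 4.8 Da at the top
  digested range (width 0.5). The defaults (1.8e-4 linear, 2e-5
  reflectron) are the largest round values passing `check_jitter()` for
  their schemes, consistent with how the tolerances were chosen from
  observed variability in the first place.
* **Export capacity.** Without a cap, a full-proteome digested render can
  emit > 10^5 candidate peaks above the floor — no centroiding software
  exports that. `max_peaks = 2000` keeps peak lists in the realm of real
  exports.
* **Abundance model.** No empirical abundance distribution is available
  for the emulated organism; lognormal with 0.8 log10 decades of spread is
  a modelling choice, and everything downstream of it should be read with
  that in mind (see the operating regime below).

What the generator does *not* emulate: profile spectra and peak picking,
isotope envelopes, adducts and matrix clusters, ion suppression beyond the
lognormal noise, biological replicate structure (every spot is an
independent redraw), or digestion chemistry variability. Passing tests on
this generator therefore validate the *workflow* — binning, learning,
evaluation, and the mass-selectivity mechanism — not instrument physics.

## Operating regime and the saturation limit

The digested feature space has ~2500 usable bins (fragments live in
500–3000 Da; 0.5 Da tolerance, 1 Da spacing). A proteome of $P$ proteins of
mean mass $\bar M$ contributes about $P \bar M / 1100$ distinct fragment
masses; at the full default scale (5445 proteins, $\bar M \approx 55$ kDa)
that is ~2.7e5 fragments — two orders of magnitude more than bins. Any
detection floor low enough to see low-abundance marker fragments then
lights essentially every bin in every spot, and binary features saturate;
with the export capacity in place the exported subset churns from spot to
spot instead. Either way, class-specific fragments of *bottom-quartile*
proteins cannot out-compete the shared background at full proteome
complexity, and end-to-end mean J for the digested condition hovers near
chance (the intact condition is equally blind to the hard preset's
> 20 kDa markers, which sit outside its acquisition window entirely).

The mechanism the workflow is built to demonstrate is cleanly visible in
the generator's *resolvable regime*: proteomes small enough that the
fragment count is comparable to the bin count ($P \lesssim 60$ at the
default digestion model). There, across seeds and presets, digested
sorting reaches $J = 1$ while intact sorting of the hard preset stays at
chance — digestion rescues exactly the high-mass, low-abundance class
differences it is supposed to rescue. The property suite pins this down at
60-protein proteomes with 16 spots per class; the acceptance suite also
measures the full default scale and reports it as found. A fragment-level
identity feature space (real peptide masses at reflectron resolution,
rather than 0.5 Da bins) would push the saturation limit out by orders of
magnitude; that is the natural extension if full-scale synthetic studies
are needed.

```{r regime-demo}
library(maldisort)
cfg <- sim_config(seed = 1, preset = "hard", n_proteins = 60,
                  n_specific = 3, spots_per_class = 16)
ds <- render_dataset(cfg)
res <- run_pipeline(ds, encoding = "binary", grid = "single")
sapply(res$trials, function(t) mean(t$J))   # digested ~1, intact ~0
```

## Numerical and statistical choices

* **Aggregates from full precision.** Mean J per condition is the
  arithmetic mean of per-trial J values; applying $J = s + p - 1$ to
  *rounded averaged* sens/spc can differ in the second decimal, so
  reported aggregates are always computed from the per-trial results.
* **Welch's t-test** (two-sided, unequal variances) compares per-trial J
  sets; the test name is stored in the result object for audit. Two
  identical zero-variance inputs return p = 1 by convention.
* **Dichotomization.** The positive-class score threshold is 0.5; the
  booster's base score is pinned at 0.5 so the threshold coincides with
  zero boosted margin even at learning rate 1e-5, where leaf updates move
  scores by ~1e-5.
* **Determinism.** Training rows are canonically sorted by spot id;
  fitting is single-threaded; every stochastic component (proteome,
  partition, fragments, spot noise) is sub-seeded from the master seed by
  a stable string hash, so a dataset is a pure function of its config.
* **Duplicate centroids** at identical m/z merge by maximum intensity at
  read time — idempotent and order-independent.
* **Test problem sizes.** Unit and property tests run on reduced sizes
  (40–400-protein proteomes, 2–16 spots per class, single-config or
  12-trial grids); the acceptance checks use the full defaults (5445
  proteins, 48 + 48 spots per role, 24-trial grid) and 10,000-draw
  calibration samples.

## Known limitations

* Binary-feature saturation bounds the usable proteome complexity of the
  *synthetic* digested condition (previous section); real digested spectra
  are sparser than the model's candidate set because real abundance spans
  more decades and peptide ionization is sequence-specific.
* Intensities are arbitrary units; no TIC or quantile normalization is
  applied anywhere (by design — the binary encoding is the robust path,
  and the intensity encoding is deliberately exposed to spot-to-spot
  noise).
* The attenuation power law is an empirical contract fitted over
  1–66 kDa calibrants; nothing physical is claimed about
  desorption/ionization.
* `compare_conditions()` treats trials as independent samples; trials of
  one grid share training data, so its p-values compare *conditions under
  the protocol*, not independent replicates.
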