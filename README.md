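# maldisort

Machine-learning dichotomous sorting of samples from MALDI-TOF centroid
peak lists, with an end-to-end synthetic benchmark of the question: *does
tryptic digestion before acquisition improve two-class sorting?*

## Who it is for

Mass-spectrometry and clinical-microbiology groups building two-class
classifiers (species vs serovar, resistance gene present vs absent,
toxin-producer vs not) from MALDI-TOF spot spectra, and anyone who wants to
study — without an instrument — when the extra chemistry of a tryptic
digest pays off.

## What is inside

* **Peak-list and manifest I/O** — two-column `mz,intensity` centroid CSVs
  plus a manifest of spot files, class labels and train/score roles.
* **Fixed m/z binning** — ranges with per-range tolerance (`width`) and
  center spacing (`δM`); nearest-center assignment within tolerance, ties
  to the lower center. Defaults: 3060 intact bins (500–20,000 Da), 6794
  digested bins (200–6,999 Da, all 0.5 Da wide / 1 Da apart). Binary or
  intensity feature encodings.
* **Gradient-boosted tree trials** (xgboost backend) over the standard
  grid: trees {50, 101, 401, 701} × feature-histogram bins {20, 40} ×
  learning rates {0.01, 1e-4, 1e-5} (24 trials, or the 12-trial preset).
* **Diagnostic evaluation** — sensitivity `tp/(tp+fn)`, specificity
  `tn/(tn+fp)`, Youden index `J = sens + spc − 1`; ROC *scatter* of
  dichotomous trials with multiplicities; Welch comparison of per-trial J
  between conditions with the `J_digested/J_intact` ratio.
* **Attenuation & enhancement model** — OLS fit of
  `log10(height/amount) ~ log10(mass)` over 1–66 kDa calibrants (slope ≈
  −2: two decades of signal lost per decade of mass) and the implied
  digestion enhancement `(M_parent/m_fragment)^|slope|`.
* **Synthetic spectrum generator** — two-class bacterial proteomes
  (log10-mass Normal(4.46, 0.55) on 3–200 kDa; ~80 % of proteins above
  10 kDa), mass-level tryptic digestion with per-protein deterministic
  fragments, power-law attenuation, per-mode detection floors, 80 %
  replicate intensity RSD, m/z jitter, and easy/hard class-difference
  presets (hard = few, heavy, low-abundance marker proteins).

## Worked example

The hard preset hides the class difference in five proteins per class that
are heavier than 20 kDa (outside the intact acquisition window) and in the
bottom abundance quartile. In the generator's resolvable regime (small
proteome; see the vignette for why complexity matters) digestion rescues
the sorting completely:

```r
library(maldisort)

enhancement_factor(c(10^3.5, 1e4, 1e5))       # vs a 1 kDa fragment, slope 2
#> [1]    10   100 10000

fit_attenuation(simulate_calibrants(sigma_log10 = 0.1, seed = 1))
#> <attenuation_fit> slope -2.0418 log10-signal per log10-Da (r^2 0.9930)

cfg <- sim_config(seed = 1, preset = "hard", n_proteins = 60,
                  n_specific = 3, spots_per_class = 16)
ds  <- render_dataset(cfg)
res <- run_pipeline(ds, encoding = "binary", grid = "paper12")
res
#> <pipeline_result> binary encoding
#>   intact: 12/12 trials ok, mean J 0.000, max J 0.000
#>   digested: 12/12 trials ok, mean J 1.000, max J 1.000
#> <comparison_result> mean J digested = 1.000, intact = 0.000 (ratio Inf)
#>   Welch two-sample t-test (two-sided): p = 0 (significant at alpha = 0.05)
```

Reading it: every one of the 12 digested trials sorts the scoring plate
perfectly (J = 1) while every intact trial is stuck at chance (J = 0) —
the class markers are invisible to linear-TOF acquisition but their
~1 kDa tryptic fragments are easy prey for the classifier. The
`enhancement_factor` line is the mechanism: a 10–100 kDa parent's fragment
carries 10²–10⁴ times its parent's signal. On an easy class difference
(preset `"easy"`) both modes sort well and digestion buys little.

A shell front-end wraps the same pipeline:

```sh
Rscript inst/scripts/maldisort.R simulate --preset hard --seed 7 --out data/
Rscript inst/scripts/maldisort.R run --manifest data/manifest.csv --out results/
```

`run` writes per-trial CSVs, a `summary.json` (per-mode mean/max J, J
ratio, Welch p) and an ROC scatter figure; result directories are
versioned, never overwritten.

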