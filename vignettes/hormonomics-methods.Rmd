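---
title: "Methods: mass-shift screening, retention scoring and benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass-shift screening, retention scoring and benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hormonomics)
```

## The annotation model

An untargeted LC-MS experiment, after peak picking and alignment, yields a
feature table: one row per (m/z, retention time) feature with per-sample
intensities. `hormonomics` annotates such tables against a curated hormone
catalogue by a two-stage procedure:

1. **m/z stage.** The catalogue is expanded into theoretical m/z values
   under a rule set (identity, [M+H]+, 7 electrospray adducts, or 27
   synthetic biotransformations). A feature matches an expanded entry when
   |m/z~obs~ − m/z~theo~| ≤ tolerance; isobars all match, deliberately —
   resolving them is the user's judgement, not the matcher's.
2. **RT stage.** Matches are ranked within each feature by the percent
   retention-time match against the parent compound's predicted RT.

Annotations are putative (MSI level 3): two orthogonal physicochemical
properties, no reference standard. For a biotransformed entry the predicted
RT belongs to the *parent* compound — the modified molecule elutes
elsewhere — so the %RT score for biotransformation hits is a weak prior, not
evidence.

### The mass-shift calculus

A rule such as `M-OH+CH3` is a signed multiset of moieties. Moiety masses
are monoisotopic masses of the neutral group, computed from IUPAC atomic
masses carried to ≥ 6 decimals (four-decimal theoretical m/z values require
at least four-decimal inputs). Two conventions deserve comment:

* **Neutral-shift default.** `apply_shift()` adds the net moiety delta to
  the neutral monoisotopic mass; `mode = "protonated"` additionally adds a
  proton (1.007276 Da). The neutral convention is the default because it is
  the one under which the published worked examples for biotransformed
  hormones reproduce exactly (e.g. abscisic acid under `M-OH+CH3`:
  264.1362 − 17.0027 + 15.0235 = 262.1569).
* **No electron correction.** Ionic adducts (`M+Li`, `M+K`, `M+NH4`, `M+H`)
  use neutral-moiety masses; the electron mass (~0.00055 Da) is far below
  both the printed precision of the values screened against and the 0.02 Da
  default tolerance. The constant is a named object (`PROTON_MASS`) so the
  convention is explicit.
* **`M+CH3OH-H` as printed.** The methanol adduct rule is implemented
  exactly as enumerated (net +31.0184 Da), although `M+CH3OH+H` is the more
  common electrospray species; fidelity to the published rule list wins.

### Tolerances and numerical guards

Tolerances are `± value` in Da or ppm. A ppm tolerance is evaluated at the
*theoretical* (database) m/z, giving every entry a single deterministic
window. The boundary is inclusive; to keep `|delta| == tol` cases stable
under floating-point rounding the comparison allows a guard of 1e-9 Da
(one nano-Dalton, far below any instrument's precision). Matching uses a
sort + binary-search window per entry, and the test suite holds it equal to
an exhaustive double-loop oracle over hundreds of random instances.

### %RT match

The published description of retention scoring ("how close the experimental
RT is to the predicted RT") does not fix a formula. We use

100 × (1 − |RT~obs~ − RT~pred~| / RT~pred~), clipped to [0, 100],

a relative deviation anchored at the predicted RT. It is consistent with the
meta-analysis thresholds: >70 % corresponds to |ΔRT| < 0.3 × RT~pred~,
about 1.5 min for a mid-gradient analyte on the 25-minute reference method.
The formula lives in one replaceable function (`rt_match_percent()`); any
alternative (e.g. normalising by run length) can be swapped in without
touching the matcher.

### Deduplication and match rate

Duplicate removal keys on the (compound, rule) pair — the same compound
reached through two different biotransformations is two distinct hypotheses
and is kept as two rows. `match_rate()` reports
100 × (deduplicated annotations whose feature m/z also matches a reference
compound) / (number of reference compounds); because matching is m/z-first,
isobars can push the rate above 100 %, which is expected behaviour rather
than an error.

## Retention-time model

`train_rt_model()` fits a random forest from structure descriptors to
observed RT. Featurization is a pluggable deterministic strategy; the
default (`featurize_matrix()`, schema `pchem-1`) combines OpenBabel bulk
properties (MW, logP, TPSA, molar refractivity, H-bond donors/acceptors)
with element counts and simple topology counts from the canonical SMILES.
The descriptor stack behind the published predictions is not documented
anywhere reproducible, so the package treats the descriptor set as a
versioned implementation detail rather than a contract; consequently the
published model metrics are not asserted anywhere — model quality is
instead established by parameter recovery on synthetic data (below).

Defaults: 500 trees; `mtry` equal to the number of descriptors, appropriate
for a small curated descriptor set in which most columns are informative
(classical p/3 subsampling costs accuracy when half the columns are noise);
a mandatory, logged seed makes training reproducible. Only the random-forest
backend is provided: of the algorithm families commonly tried for this task,
it was the one selected upstream, and a Bayesian-regularised network backend
would add a dependency without changing the package's contracts.

Metrics (`evaluate_rt_model()`): RMSE, MAE, R², and a 95 % band on the
residuals. The band is the 95th percentile of |residuals| by default; the
normal-theory alternative 1.96 × sd is a flag. The definition of the
corresponding published interval is not stated, and 1.96 × RMSE is ruled out
by its own numbers, so neither definition is asserted against it.

For the packaged 46-standard training mixture, tabulated predicted and
experimental RTs correlate at r ≈ 0.95 with an observed-on-predicted slope
of ≈ 1.40 — both recomputed by the test suite, with the slope treated as a
soft diagnostic band (1.39 ± 0.15), not a gate. The signed deviation
convention is ΔRT = RT~pred~ − RT~obs~.

## Meta-analysis filtering

`apply_retention_rules()` implements the pooling filters, with strict
comparisons exactly as stated (>70 %, >50 %, >1 min):

| gradient status      | rule                                          |
|----------------------|-----------------------------------------------|
| `same_as_reference`  | keep RT match > 70 %                          |
| `different`          | keep RT match > 50 %                          |
| `not_provided`       | keep 1 min < RT < re-equilibration start      |
| `direct_injection`   | keep all                                      |

The re-equilibration start defaults to 15 min: on the reference 25-minute
gradient the last compositional change ends at 15–20 min, after which the
column re-equilibrates isocratically; no published number exists, so the
default is configurable per study in the manifest. Studies acquired in both
polarities are listed as two manifest rows (one peak table per polarity),
mirroring how pooled results are reported per ionization mode. Annotations
lacking a %RT score under a percentage rule are dropped with a warning
rather than an error, because biotransformed entries legitimately lack
predicted RTs. Class summaries count deduplicated compounds, are invariant
to annotation order, and bin uncatalogued compounds as `unclassified`.

Acquiring the external study tables is a documented manual step; the
pipeline consumes local CSVs only, so no test and no analysis step touches
the network.

## Synthetic benchmark generator

`simulate_peak_table()` emulates the *output* of peak alignment — not raw
spectra, peak shapes or isotope envelopes. Spikes are placed at theoretical
m/z + N(0, σ~mz~) with RT = parent predicted RT + N(0, σ~rt~); decoys are
uniform on m/z 100–1000 (the reference scan range) and rejected until they
lie ≥ `decoy_min_distance` from *every* theoretical m/z of the fully
expanded catalogue (all four rule sets, both shift conventions), so a decoy
annotation can only ever be the matcher's fault. Intensities are log-normal
(meanlog 10, sdlog 1) and never influence matching. All randomness flows
from one seed through a single stream in a documented draw order, making
outputs byte-identical across runs.

Defaults chosen once as realistic study conditions: σ~mz~ = 0.005 Da
(typical QTOF accuracy relative to the 0.02 Da search tolerance),
σ~rt~ = 0.25 min, decoy distance 0.05 Da.

Two exact consequences anchor the test suite: with zero noise and decoy
distance above the tolerance, recall is 1.0 and the false-annotation count
is 0 on every seed; with σ~mz~ equal to the tolerance, expected recall is
P(|N(0, σ)| ≤ σ) ≈ 68.3 %, and observed recall over 1000 spikes stays
within ±5 points of it.

## What the tests do and do not establish

The synthetic generator produces well-separated, Gaussian-perturbed
features. Real peak tables contain correlated m/z errors, RT drift,
co-eluting isomers, in-source fragments and missing values; passing the
recovery benchmarks therefore demonstrates the correctness of the matching,
ranking and filtering machinery, not field performance on any particular
instrument. Likewise, the packaged catalogue is a small curated fixture;
screening sensitivity on a full catalogue scales with its size and density.

Problem sizes used by the default test run — 200 random matcher instances
(≤ 60 features × ≤ 60 entries), 1000-spike recall experiments, a 200-point
regression recovery with an 80/20 split — were chosen to exercise every code
path at comfortable statistical power.

## Known limitations

* No MS/MS spectral matching, isotope-envelope scoring, charge states > 1,
  or negative-mode adduct chemistry.
* No structure-aware feasibility checking: a rule like `M-C6H12O6+H` is
  applied to every compound heavy enough to survive it, including compounds
  that carry no sugar; biotransformation hits must be assessed for chemical
  plausibility by the analyst.
* Retention predictions transfer only to chromatography close to the
  reference gradient; for other methods the meta-analysis filters fall back
  to the coarser rules.
* A handful of packaged training-set structures for exotic analytes are
  best-effort curations; they affect only descriptor values, never
  mass or identity assertions.
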