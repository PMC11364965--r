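# hormonomics

Untargeted phytohormone screening for LC-MS peak tables.

## The problem

Plant hormones (auxins, cytokinins, gibberellins, abscisic acid, jasmonates,
indolamines, ...) occur at trace levels, are chemically labile, and are
stored and transported as conjugates — methylated, hydroxylated,
glycosylated, aminated or carboxylated forms of the parent molecule. In an
untargeted LC-MS experiment the bioactive parent is often invisible while a
modified form is detectable. Broad metabolite databases return large numbers
of improbable identities for such features; a small, hormone-focused
database combined with in-silico prediction of plausible modifications gives
sharper, hypothesis-generating annotations.

`hormonomics` implements that workflow for anyone with an aligned peak
table (CSV: m/z, retention time, per-sample intensities):

* **Mass-shift calculus.** A compound catalogue is expanded by the identity
  rule, the [M+H]+ adduct, 7 common electrospray adducts
  (`M+H-2H2O`, `M+H-H2O`, `M+NH4-H2O`, `M+Li`, `M+NH4`, `M+CH3OH-H`, `M+K`)
  and 27 synthetic biotransformations (`M+CH3`, `M+C6H12O6`, `M-OH+NH3`, ...).
  For a parent of monoisotopic mass *M* and a rule with signed moiety terms,
  the theoretical m/z is *M* + Σ ±(coefficient × moiety mass), optionally
  + 1.007276 Da for the protonated ion.
* **m/z-first matching.** Every feature within ±tolerance (Da or ppm,
  inclusive) of a theoretical m/z is annotated; isobars all return. Matches
  are ranked by percent retention-time match,
  100 × (1 − |RT_obs − RT_pred| / RT_pred) clipped to [0, 100],
  and reported at MSI (Metabolomics Standards Initiative) level 3.
* **Retention-time prediction.** A random forest on physicochemical
  descriptors (OpenBabel properties + composition/topology counts), trained
  on a packaged 46-standard mixture run on a 25-minute
  water/acetonitrile gradient.
* **Meta-analysis.** Per-study screening with gradient-dependent retention
  filters (>70 % match for the reference gradient, >50 % for a different
  one, 1 min < RT < re-equilibration when chromatography is unreported,
  everything for direct injection), deduplication, and class-binned
  summaries across studies.
* **Synthetic benchmarks.** A peak-table simulator with spiked true
  positives and distance-guarded decoys, so recall and false-annotation
  counts are measurable without external data.

## Worked example

```r
library(hormonomics)

db <- fixture_compounds()           # packaged hormone catalogue
peaks <- peak_table(
  mz  = c(262.1596, 234.1195, 369.1448, 266.0744, 512.2000),
  rt  = c(3.6688, 5.7546, 3.4826, 5.4249, 9.10),
  intensities = data.frame(leaf_1 = c(8.1e4, 2.3e4, 5.5e3, 1.2e4, 9.9e2)))

hits <- screen(peaks, db, ruleset = "biotransformations",
               tol = tolerance(0.02, "da"))
head(hits[, c("compound", "rule", "theoretical_mz", "mz", "rt_match_pct")], 3)
```

```
             compound     rule theoretical_mz      mz rt_match_pct
1 Abscisic acid (ABA) M-OH+CH3        262.157 262.160      65.9856
2  2-hydroxymelatonin M-NH2+H2        234.113 234.119      86.4970
3  2-hydroxymelatonin  M-CH3+H        234.100 234.119      86.4970
```

The feature at m/z 262.1596 is annotated as a methylated, dehydroxylated
form of abscisic acid (theoretical m/z 262.1569, Δ = +2.7 mDa); the feature
at 234.1195 matches several isobaric hydroxymelatonin biotransformations,
ranked by how close its observed RT (5.75 min) is to each parent's predicted
RT. Four of the five features yield 15 annotations in total; the decoy at
m/z 512.2 matches nothing. Columns `leaf_1`, `delta_mz` and `msi_level`
(always 3) are carried along, and `write_screen_csv()` exports the table
with the conventional display headers ("Compound name", "Actual m/z", ...).

Retention-time model quality on the packaged 46-standard mixture, comparing
tabulated predicted and experimental RTs:

```r
tr <- rt_training_set()
evaluate_rt_model(tr$rt_predicted, tr$rt_observed)
#> RMSE 0.807 min | MAE 0.588 min | R2 0.825 | 95% band +/- 1.732 min (quantile, n = 46)
```

A command-line wrapper ships in `inst/exec/hormonomics`
(`screen`, `build-db`, `validate-db`, `predict-rt`, `meta`, `simulate`);
see `?hdb_cli`.

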