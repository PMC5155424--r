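---
title: "From protein stability to residual enzyme activity: the methods behind cyp21act"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From protein stability to residual enzyme activity: the methods behind cyp21act}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyp21act)
```

## The problem

Congenital adrenal hyperplasia is most often caused by deficiency of
21-hydroxylase (CYP21A2), a microsomal cytochrome P450 of steroid
biosynthesis. The residual activity of a missense variant tracks the
clinical form: near-complete loss with salt wasting (SW), roughly 2% with
simple virilizing disease (SV), and 10–60% with the mild non-classical
form (NC). Most reported variants, however, have never been assayed in
vitro.

For the large subset of missense variants whose only plausible mechanism
is destabilization of the folded protein, a structure-based shortcut is
available: predict the folding free-energy change ΔΔG (kcal/mol, positive
= destabilizing) from a structure with an empirical force field such as
FoldX, and convert ΔΔG to an expected residual activity through an
empirical calibration. `cyp21act` implements that pipeline: variant
parsing and bookkeeping, structural classification that isolates the
stability subset, replica aggregation of predictor output, the
calibration itself, pathogenicity and severity calls, and an additivity /
synergy analysis for two variants in cis. The package consumes predictor
*output*; it contains no force field and never runs FoldX.

## The calibration model

The core model is log-linear:

$$\ln(\mathrm{activity\ \%}) = a + b\,\Delta\Delta G$$

fitted by unweighted least squares (`stats::lm`) on pairs of predicted
ΔΔG and measured residual activity (% of wild type). Two numerical
conventions matter.

* **The fit cap (5.5 kcal/mol).** Measured activities saturate near 0%
  once destabilization reaches about 5.5 kcal/mol; beyond that, larger
  predicted ΔΔG carries no information about the line. X-values are
  therefore clamped to `min(ddg, 5.5)` *before fitting only*. Predictions
  use the raw ΔΔG, which is why two strongly destabilized variants with
  ΔΔG 7.55 and 12.31 still receive distinct (tiny) predicted activities.
* **The activity cap (100%).** Stabilizing variants (ΔΔG < 0) can push
  the exponential above 100%; predictions are clamped to 100% and flagged,
  and reports render them as "≥100".

Activities of exactly 0 cannot enter the fit (their logarithm is
undefined) and are excluded with a logged message; the saturation
behaviour they represent is carried by the cap instead.

Diagnostics reported with every fit: R² of the least-squares fit,
Spearman's rank correlation with midrank ties, and two-sided permutation
p-values for both the rank correlation and the regression slope. The
permutation test enumerates all $n!$ label permutations exhaustively for
$n \le 7$ (the p-value is then exact); for larger $n$ it draws `n_perm`
(default 10,000) random permutations under a fixed seed and uses the
add-one estimator $p = (1 + k)/(1 + n_\mathrm{perm})$, which never
returns an impossible $p = 0$. Degenerate inputs (constant x or y) yield
a flagged `NA` correlation and $p = 1$.

### The shipped reference fit

The package ships the published table of 32 stability-class variants with
their bovine-template ΔΔG and printed in-silico activities
(`cyp21a2_table2()`). Because those printed activities derive from the
original calibration line, refitting on the informative rows recovers
that line. `table2_fit_set()` applies the selection rule: printed
activity in [0.05, 100) and ΔΔG ≤ 5.5, giving 19 rows. Rows printed as
100 are cap-saturated and rows below 0.05 are rounding-degenerate; both
would only leak display-rounding error into the slope. The refit gives
$a \approx 5.39$, $b \approx -1.55$, reproducing the printed cells at
their display precision (0.1 at ΔΔG 4.94, 0.06 at 5.34, 2.9 at 2.8, 1.0
at 3.51) and saturating at ≥100% for the stabilizing ΔΔG of −2.16. One
printed cell (0.2 at ΔΔG 4.44) back-predicts at 0.229 — a 14% relative
gap, the one place where display rounding of the original 30-pair fit is
visible in our 19-row refit.

## Thresholds and calls

* **Destabilization cutoff, 1.6 kcal/mol** (`analysis_config()`): twice
  the stability predictor's standard deviation (0.8 kcal/mol). The
  comparison is *strict*: a mean ΔΔG of exactly 1.6 is not called
  destabilizing, because the rule is "above the threshold".
* **Non-pathogenic threshold, 75%**: predicted activity strictly above
  75% is called non-pathogenic.
* **Severity bands** (`severity_bands()`): <1% SW-like, 1–5% SV-like,
  10–60% NC-like, >75% normal-like; the gaps (5–10%, 60–75%) are
  reported as indeterminate rather than silently assigned. All edges are
  configurable.
* **Replica aggregation**: arithmetic mean and *sample* (n−1) SD over the
  canonical five predictor runs; a single value gets SD 0. A replica
  count other than five warns but proceeds.

## Structural classification

Each variant receives exactly one class, applied in precedence order:
(1) non-missense kinds (nonsense/frameshift/indel); (2) positions
annotated as poorly resolved, or missing from the structure; (3)
heme/ligand contact; (4) POR (P450 oxidoreductase) interface; (5)
protein-degradation motif; (6) meander/ERR-triad motif; (7) otherwise
**stability** — the only class that enters the calibration. Functional
categories precede stability because a variant at a functional residue
tells us nothing through ΔΔG alone. Where a residue satisfies both the
heme and POR rules we apply heme first — the stronger, more local
functional claim — and record the firing rule in the evidence columns so
the choice is auditable.

The geometric predicates (`geometry_config()` defaults):

* **Heme/ligand contact**: minimum side-chain heavy-atom distance to the
  heme ∪ ligand atom set ≤ 5 Å (boundary counts as contact), *and* the
  side chain points toward it. "Pointing towards" has no published
  formula, so it is formalized as the angle at the Cα between the
  Cα→side-chain-centroid vector and the Cα→nearest-atom vector being
  ≤ 90°; the evidence record exposes distance, nearest atom and angle.
  Glycine uses its Cα as side-chain proxy, and its orientation is treated
  as indeterminate (the distance clause alone decides).
* **POR interface**: the nine core charged residues (124, 140, 320, 341,
  356, 366, 369, 431, 444) qualify by position alone; additionally, an
  arginine or glutamic acid — tested with the *replacement* identity, so
  a substitution that introduces a charge counts — qualifies when its
  side chain is within 8 Å of a core side chain, its relative side-chain
  accessibility is ≥ 0.25, and it faces the same surface (positive
  projection of its outward direction onto the mean outward direction of
  the core side chains, with the protein's centroid as origin). The 8 Å,
  0.25 and same-face constructions are package choices — the source
  material says only "close proximity and exposed to the same surface" —
  and all are configurable.
* **Exposure** is computed by a Shrake–Rupley accessible-surface
  calculation (120 sphere points, 1.4 Å probe) over the chain plus
  cofactors, summed over side-chain atoms and normalized by standard
  per-residue maximum side-chain areas, clamped to [0, 1]. No external
  accessibility program is required.

Structures are read with `bio3d` (PDB format, first model, coordinates
as-is); heme heteroatoms default to residue name `HEM`, ligand names are
configuration because deposition het-codes for progesterone /
17-hydroxyprogesterone vary.

## Double variants in cis

For two variants on the same allele the additive baseline is the exact
sum of the single ΔΔG values; the synergy score is
`ddg_double − (ddg_1 + ddg_2)` when a combined estimate from a
multi-substitution predictor run is available (the package never tries to
predict it from the singles). The published taxonomy of scenarios is
descriptive, not a partition, so `classify_double()` fixes a total,
mutually exclusive decision tree, in precedence order: both singles above
the cutoff (`both_above`); significant synergy crossing the cutoff
upward (`positive_synergy`, or `synergy_subthreshold_pathogenic` when
neither single is above it) or downward (`negative_synergy`); one single
above but the effective combined value below (`combined_rescue`);
effective combined value above (`additive_pathogenic`); everything below
(`additive_nonpathogenic`). The effective combined value is `ddg_double`
when present, else the sum.

Synergy requires `|ddg_double − sum|` to exceed a tolerance, default 0.8
kcal/mol — one predictor SD; no synergy-significance rule is published,
so the tolerance is explicit and configurable. When the combined estimate
equals the sum exactly, no synergy scenario can ever fire, at any
tolerance. Pairs whose effective combined ΔΔG lies within half a
tolerance of the cutoff are flagged `near_cutoff`: the canonical example
is the common polymorphism pair p.K102R + p.S268T, individually benign
(0.81 and 0.74 kcal/mol) but summing to 1.55, a whisker below 1.6.

## What the synthetic generators emulate

`generate_calibration_pairs()` draws ΔΔG uniformly on (−2, 10) kcal/mol —
the observed range of the reference tables — and activities from the
log-linear model with Gaussian ln-scale noise (default SD 0.35, chosen so
the synthetic scatter resembles the published calibration spread; a
cosmetic choice, not an inferential one) and the 100% clamp.
`generate_replicas()` draws Normal(ΔΔG, 0.8²) replica sets.
`generate_toy_structure()` builds minimal PDB files: a heme proxy group
at the origin and one residue per placement on its own radial direction,
with a three-atom side-chain proxy whose nearest atom sits exactly at the
requested distance and whose orientation (toward/away) is fixed by
construction; toward-pointing tips are nudged 0.003 Å inside the request
so the PDB format's 0.001 Å coordinate precision cannot flip a placement
at exactly the 5 Å cutoff onto the wrong side.
`generate_double_variant_set()` samples each requested scenario directly
from the ΔΔG region the classifier maps to it, so generator and
recognizer are exact inverses by construction.

What these generators deliberately do **not** emulate: realistic protein
geometry (no rotamers, no packing), correlated errors between replicas,
substrate-specific activity differences, or any biology beyond the
log-linear mean model. Green tests therefore certify the machinery —
parsing, geometry predicates, aggregation, fitting, permutation
inference, scenario logic — not the biological accuracy of a stability
predictor on real structures.

## Numerical choices and degenerate inputs

* Sub-seeds for each pipeline stage are derived deterministically from
  one top-level seed and kept inside the 32-bit integer range; RNG state
  is always restored, so generators are pure functions of (spec, seed).
* Permutation comparisons use `|stat| ≥ |observed| − 10⁻¹²` to keep ties
  stable under floating-point noise.
* Boundary conventions: distance ≤ cutoff is a contact; ΔΔG > threshold
  (strict) is destabilizing; activity > 75 (strict) is non-pathogenic.
* A residue with no side-chain heavy atoms (other than glycine) is
  flagged incomplete; geometric predicates on it raise an error, which
  `classify_table()` converts to a per-row note instead of aborting the
  batch.
* A structure without heme heteroatoms loads with a warning and all heme
  predicates return false; classification then falls through to the
  remaining rules, so a stability-only analysis still runs without any
  structure at all.

## Problem sizes

The test suite and the reproduction script run at desk scale: the 19-row
reference refit, exhaustive permutation tests up to n = 7 (5,040
permutations), sampled permutation checks at 4,000–5,000 draws, parameter
recovery at n = 10/100/1,000 synthetic pairs, toy structures of three to
five residues, and a scenario grid of a few thousand ΔΔG triples. The
full suite completes in well under a minute on a single CPU.

## Known limitations

* The original 30-pair training set and the survey of 343 classified
  variants live in supplementary material that is not machine-readable
  here; the published R² (0.79/0.60) and Spearman (−0.894/−0.829) values
  therefore cannot be recomputed, only the machinery that would compute
  them is provided (and is oracle-tested).
* Motif membership (degradation, meander, ERR triad) must be supplied via
  configuration; the package ships empty sets.
* Homology-model building and quality assessment, force-field energetics,
  electrostatic surfaces, conservation alignments and mmCIF parsing are
  out of scope.
* The length bound for variant positions defaults to 495 but is
  configurable, since the reference protein is variously given as 494 or
  495 residues.
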