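---
title: "Methods: simulating and analysing ER reporter-gene qHTS screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing ER reporter-gene qHTS screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qhtsER)
library(data.table)
```

## The problem

Quantitative high-throughput screening (qHTS) tests every compound of a
large library as a full concentration series rather than at a single dose,
so each compound yields a concentration-response curve in every assay. For
nuclear-receptor endpoints such as estrogen receptor alpha (ERα), a typical
campaign runs two reporter-gene assays — here a β-lactamase reporter driven
by the ERα ligand-binding domain in a one-hybrid configuration (`bla`,
fluorescence readout) and a luciferase reporter downstream of a full-length
receptor (`luc`, luminescence readout) — each in *agonist mode* (no
co-stimulation; activation is scored) and *antagonist mode* (wells
co-stimulated with a reference full agonist; suppression is scored).
Antagonist-mode assays are multiplexed with a cell-viability readout in the
same well, and a separate counter-screen measures compound autofluorescence
in the reporter's detection channels, because cytotoxicity and fluorescence
are the two dominant artifact routes that masquerade as receptor activity.

`qhtsER` implements the full analysis chain for such a campaign —
normalization and plate QC, curve fitting and grading, counter-screened
activity calling, replicate reconciliation, reference-panel and
binding-assay scoring, and structure-class enrichment — together with a
synthetic screen generator that provides ground truth for every stage, so
the chain is testable end to end without any external data.

## The synthetic screen

`generate_library()` draws a compound library from a configurable mixture
of truth classes. The defaults describe a desk-scale stand-in for an
environmental-chemistry campaign: 1,000 compounds, of which 8% are full
agonists, 5% partial agonists, 5% antagonists, 5% cytotoxic-only, 2%
autofluorescent, 2% selective modulators (opposite directions on the two
receptor constructs) and 73% inactive — an active fraction in the 5–10%
range typical of nuclear-receptor screens. Potencies are drawn log-uniform
over 10^-8.5^–10^-5.5^ M (inside the tested range), full-agonist efficacies
over 80–120% of the positive-control maximum and partial-agonist
efficacies over 15–60%, so that the borderline-efficacy and
borderline-potency behaviour that dominates real call disagreements is
represented.

Each compound also carries: a log relative binding affinity (logRBA)
derived from its potency relative to a 3×10⁻¹⁰ M endogenous-agonist
reference with 0.4 log units of assay scatter (binding-inactive compounds
fall below the conventional logRBA −3 cut-off); a reference-panel label for
an embedded 39-chemical evaluation set (3 strong, 1 strong-moderate, 5
moderate, 15 weak and 4 very-weak agonists, 6 moderate antagonists, 5
negatives), assigned consistently with the drawn potencies; and a 512-bit
binary fingerprint generated from a per-family prototype with a 5% per-bit
flip rate, giving clusterable structure without a chemistry toolkit. Two
families are planted deterministically to validate the enrichment stage:
a 30-member full-agonist family and a 30-member family mixing antagonists
with cytotoxic compounds — the classic cytotoxicity-confounded antagonist
cluster.

`assemble_runs()` lays the library out as an inter-plate titration: within
a run each sample owns a fixed well slot and the stack of 15 plates per
assay carries the 15-point titration (1.1 nM – 92 µM, geometric spacing —
the spacing is a package choice; only the endpoints and point count are
given by convention). Well slots are permuted independently across the
three runs, 88 compounds are plated twice per run as internal duplicate
controls, and every plate carries 16 negative-control wells plus a 16-point
positive-control titration in duplicate. Antagonist-mode wells are
pre-stimulated at ~EC80 of the reference agonist (a standard antagonist-
mode design point; the stimulation level is configurable via `stim_frac`).

The noise model has three parts, calibrated so that simulated plate
quality statistics land in the working band of a good screen (mean Z′
roughly 0.5–0.8): multiplicative log-normal well noise with 7% CV, additive
noise at 1% of the plate baseline, and a per-plate log-normal multiplier
with 3% CV standing in for batch effects. What the generator does *not*
emulate: real chemical structures, spatial (row/column) plate gradients,
carry-over, dispensing failures, luciferase inhibition or fluorescence
quenching. Passing tests therefore demonstrate that the analysis chain is
correct *given* this data-generating process, not that it is robust to
every artifact of a physical screen.

## Normalization and plate QC

`normalize_screen()` converts raw signals to percent activity per plate:
0 at the negative-control mean (for antagonist-mode plates the stimulated,
uninhibited wells; for viability plates untreated cells) and magnitude 100
at the mean of the embedded control titration's top two concentrations.
Activation is positive; inhibition runs to −100, so efficacies compare
across modes by magnitude (reports take absolute values). Using the top two
control concentrations as the "full effect" level is a package choice; it
averages four wells and is insensitive to the exact control AC50.

Plate statistics come from the same controls: S/B = μ_top/μ_neg (larger
over smaller), CV = 100·σ_neg/μ_neg, and Z′ = 1 − 3(σ_pos+σ_neg)/|μ_top −
μ_neg|. Plates failing the conventional thresholds (S/B > 3, CV < 10%,
Z′ > 0.5) are flagged but never dropped — screens routinely retain a
usable assay with Z′ near 0.4, and dropping plates would silently bias
activity rates. `control_titration_ac50()` fits the embedded control curve
on every plate and reports the geometric SD as a fold factor per assay; a
well-behaved screen stays under 3-fold.

## Curve fitting and grading

`fit_hill()` fits the four-parameter Hill model
$y = b + (t - b) / (1 + (\mathrm{AC}_{50}/c)^h)$
by bounded least squares (L-BFGS-B) with three AC50 starts at the log-grid
quartiles. Bounds: AC50 within 1/100× to 100× of the tested range, Hill
slope 0.3–8, asymptotes ±150%. A fit that fails to beat the flat model by
at least 5% of the total sum of squares is reported unconverged
(`direction = "none"`). One point may be masked as an outlier, but only
when masking improves R² by at least 0.2 — a deliberately high bar so that
masking never manufactures activity. AC50s are aggregated geometrically
(log10 domain) everywhere.

`classify_curve()` grades each titration into the curve-class taxonomy
used throughout the federal qHTS screening programs (1.1, 1.2, 2.1, 2.2,
3, 4), which the downstream caller consumes as a confidence weight. The exact
thresholds are package choices, exposed as arguments: class 4 requires all
responses under max(3·noise_sd, 20%); classes 1.x require a complete curve
(fitted AC50 inside the tested range, ≥90% of the fitted span reached at
the top tested concentration) and R² ≥ 0.9; classes 2.x cover incomplete
curves with R² ≥ 0.6; the `.1`/`.2` split is at 80% efficacy; class 3
catches significant but unfittable responses (R² < 0.6, unconverged, or a
single responding top concentration). The per-assay `noise_sd` is
estimated from the normalized negative-control wells.

## Activity calling with counter-screens

`call_assay()` integrates the three replicate curves per (compound, assay)
with the counter-screens. Majority logic (2 of 3) drives the primary
branch: a majority of class-4 curves with no conclusively active replicate
is *inactive*; a majority of conclusively active curves (1.1/1.2/2.1) in
one direction is a candidate active. Candidates are then demoted — never
promoted — by the counter-screens:

* a candidate antagonist whose matched viability readout declines with an
  AC50 within 3-fold of the antagonist AC50 (the `cytotox_window`), or
  that has lost ≥50% viability at the antagonist AC50, becomes
  *inconclusive antagonist (cytotoxicity)*;
* a candidate agonist in the fluorescence-read `bla` assays whose
  autofluorescence in the blue/green detection channels exceeds 3·noise_sd
  at active concentrations becomes *inconclusive agonist
  (autofluorescence)*; the luminescent `luc` readout is never
  autofluorescence-demoted;
* activation observed in antagonist-mode assays carries agonist labels,
  and with concurrent viability loss becomes *inconclusive agonist
  (cytotoxicity)* — a category that only exists in antagonist mode.

Weak-curve majorities (2.2/3) and active-vs-flat replicate disagreement
yield the direction's *poor curve quality* inconclusive; conclusive
activity in both directions yields plain *inconclusive*. The tree is total
and deterministic: every combination of curve-class triple, viability
state and autofluorescence state maps to exactly one of the nine outcome
categories, and this is enumerated exhaustively in the test suite.
Majority logic is the simplest reconciliation rule consistent with the
sub-1% replicate mismatch rates such screens report; the 3-fold
cytotoxicity window is a package choice exposed in the configuration.

`reconcile_replicates()` summarises triplicate reproducibility per sample
(active match / inactive match / inconclusive / mismatch, with the AC50
fold change over matched actives), where a *mismatch* requires a
high-quality active curve (1.1/1.2) against a class-4 curve, or conclusive
actives in opposite directions. `duplicate_concordance()` applies the same
categories pairwise to the 88 intra-plate duplicates and reports the R² of
log10 AC50 over active-matched pairs.

## Evaluation

`reference_performance()` scores calls against the embedded reference
panel. Agonist-mode endpoints take the agonist reference classes as
expected positives (the six reference antagonists are excluded from the
agonist positive class) and the negatives as expected negatives;
antagonist-mode endpoints use only the six antagonists plus the negatives.
Inconclusive reference calls are excluded by default; the
`include_inconclusive` mode requires an explicit caller-supplied
resolution table, because the manual review it mirrors is not algorithmic.
Sensitivity, specificity and accuracy come with a two-sided Fisher exact
p on [[TP,FP],[FN,TN]] (`fisher_exact_2x2()`, which is cross-checked in
the tests against a from-scratch hypergeometric enumeration oracle).

`binding_concordance()` compares functional calls (active agonist or
antagonist in either mode of a platform) with binding labels, treating
logRBA < −3 — binding weaker than 1/1000 of the endogenous agonist — as
binding-inactive, excluding inconclusives, and reporting the concordance
(CP+CN)/(CP+DP+CN+DN) with a Fisher p on [[CP,DP],[DN,CN]]. Report-scale
rounding helpers (`as_report_percent()`, `as_report_p()`) round to whole
percent and two significant figures, the precision at which such tables
are conventionally printed.

## Structure-class enrichment

`train_som()` is a compact batch self-organizing map: the codebook is
initialised from sampled fingerprint rows, trained with a Gaussian grid
neighbourhood whose radius decays linearly to 0.5, and finally thresholded
at 0.5 so that cluster assignment is by Hamming distance with lowest-index
tie-breaks — the natural semantics for binary fingerprints. The default
grid allocates roughly one node per 13 compounds, the granularity at which
a ~8K-compound library yields several hundred structure clusters; at the
default 1,000 compounds this is a 9×9 map. Training is deterministic given
the seed, and the two-family separation behaviour is cross-checked against
k-means in the tests.

`cluster_enrichment()` tests each node for over-representation of an
activity category with the two-sided Fisher exact test (enriched: p < 0.01
and in-node rate above background). For antagonist endpoints,
`assay_enrichment()` additionally flags nodes that are *also* enriched in
cytotoxicity-demoted antagonist calls as `confounded` and excludes them
from the reported enriched set — structure classes whose apparent
antagonism travels with cytotoxicity are not credible receptor
antagonists. `enrichment_matrix()` exports the signed log10 p matrix
(positive = enriched, negative = depleted) across the four reporter
endpoints, ready for a heatmap.

## Numerical choices and degenerate inputs

* Fits with fewer than 4 points, plates without both control types, and
  empty replicate sets are errors; a plate whose controls coincide gets an
  undefined (NA) Z′ and NA activities rather than an Inf.
* A Fisher table with an empty margin returns p = 1, flagged.
* Fit convergence is defined by relative improvement over the flat model
  (5%), not by optimizer status, so a "converged" flat line never acquires
  a direction.
* All seeds are derived from the single configuration seed via a fixed
  affine map modulo 2³¹−1, so every stage is independently reproducible.

## Problem sizes used in the checks

The package's own verification uses desk-scale screens: unit tests run
screens of 20–250 compounds on 384-well geometry; the acceptance script
runs the full default screen (1,000 compounds, 1536-well geometry, three
runs, nine readouts — about 460,000 wells) plus a 500-compound
parameter-recovery study. These sizes were chosen so the whole suite
verifies the complete pipeline, including the slow nonlinear-fitting
stage, in a few minutes on one CPU.

## Known limitations

* The curve-class thresholds and reconciliation weights of the original
  screening programs are not public in full detail; the rule set here is a
  documented, configurable interpretation of that convention, and absolute
  outcome rates will shift with those thresholds.
* No spatial detrending is applied before normalization; the generator
  correspondingly models only a scalar per-plate effect.
* The luciferase-inhibition and fluorescence-quenching artifact routes are
  named but not counter-screened, matching the two counter-screens
  actually modelled (viability, autofluorescence).
* Real-data import is limited to the plain-file stage interfaces (any
  stage can be fed a CSV in the documented dialect); no PubChem download
  or parsing is included.
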