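---
title: "Methods: comparative metabolomics and deuterium tracer-fate modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative metabolomics and deuterium tracer-fate modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deutrace)
```

This vignette documents the models behind `deutrace`, the parameters that
matter, the design choices made where the design was genuinely open, and
what the synthetic-data tests do and do not demonstrate about real data.

## The scientific setting

*C. elegans* reared on *E. coli* accumulates C11 β-branched fatty acids
from two parallel routes. Bacterial cyclopropane fatty-acid synthase (CFA)
bridges the *cis* double bond of vaccenic acid (cis-11 18:1) with a CH2
unit; nematode β-oxidation then shortens the chain by four two-carbon
units until the β-cyclopropyl substituent blocks the cycle, parking
becyp#1 (C11H20O2). In parallel, the endogenous C-methyltransferase FCMT-1
performs CFA-like chemistry on the same substrate — methyl transfer with
double-bond migration to *trans* — and four β-oxidation rounds yield the
isomeric β-methyl acid bemeth#1. α-oxidation (PHYH homologs plus HACL-1)
degrades it, and its 2-hydroxy and distally hydroxylated shunt metabolites
(bemeth#2, bemeth#3) accumulate when the lyase step is lost. Both end
products act on the NHR-49/PPARα axis that drives desaturase expression.

The package implements the three computational pillars of that argument:
the differential feature-table statistics that find such metabolites, the
isotopologue matching that ties them to a fed deuterium label, and a
deterministic bookkeeping model that predicts exactly how many deuteriums
each product should retain.

## Exact-mass arithmetic

All masses derive from the NIST monoisotopic isotope masses in
`isotope_masses`, with deuterium carried as its own element symbol so that
formula arithmetic on labeled species is integer-exact. Two numerical
choices matter:

* **The electron mass is included in ion m/z.** For singly charged
  adducts, m/z([M−H]⁻) = M − m(¹H) + m(e⁻) and m/z([M+H]⁺) = M + m(¹H) −
  m(e⁻). The electron term (0.00055 Da, about 3 ppm at m/z 180) is what
  makes computed values agree with instrument-reported ones at four
  decimals: C11H20O2 → 183.1391, C11H20O4 → 215.1289. Many casual
  calculators omit it.
* **Matching uses ppm windows, not 4-decimal equality.** Computed and
  instrument values can disagree in the fourth decimal within normal mass
  accuracy: the D11 isotopologue of the dihydroxy acid computes to
  226.1979 against an observed 226.1982 (≈1.3 ppm). Annotation therefore
  treats agreement within 2–3 ppm as a match; four-decimal display is a
  reporting convention, with full double precision kept internally.

The per-deuterium shift Δm_D = m(²H) − m(¹H) = 1.0062767 Da is exposed as
`deuterium_shift(n)`; three substitutions give the diagnostic 3.0188 Da.

## Feature tables

`feature_table` holds post-peak-picking data: features (m/z in Th, RT in
seconds, one ion mode per table) by samples, plus a manifest mapping
samples to groups. Retention times are stored in seconds (the filtering
windows are second-denominated); minute-scale files convert on ingest.
Tables are expected dense — zeros are true zeros and missing cells are an
ingest error, as produced by peak-filled processing. Negative- and
positive-mode data are kept in separate tables because each mode is
normalized to a different internal reference. `query_mz` provides
EIC-style lookups inside closed ppm windows and is tested against a
brute-force linear scan.

## The differential pipeline

`run_differential` applies the stages in a fixed order; each stage's
survivor set is a subset of the previous one, and per-stage counts are
recorded. Defaults in `pipeline_config()`:

| parameter | default | meaning |
|---|---|---|
| `rt_window` | 180–1080 s | closed retention-time cull; 60–1080 s for early-eluting analytes |
| `blank_fold_threshold` | 5 | keep features ≥ 5-fold over the blank mean |
| `blank_pseudo_intensity` | 1 AU | denominator when the blank mean is 0 |
| `min_group_mean_intensity` | 10,000 AU | closed mean-intensity floor |
| `fdr_q` | 0.15 | BH significance threshold |
| `reference_exclusion_deltas` | +1.00336 Da | ¹³C offset excluded around the reference |
| `exclusion_ppm`, `exclusion_rt_tol` | 3 ppm, 5 s | window for reference degenerates |
| `log2fc_pseudo_intensity` | 1 AU | floor keeping fold changes finite |

Open choices, resolved as follows:

* **Thresholds are closed** (≥ at the boundary): the conventional reading
  of an intensity "threshold".
* **Blank subtraction pools all biological groups** and precedes genotype
  regrouping; it is a keep-rule, so a zero blank mean is replaced by a
  1 AU pseudo-intensity and detected-only-in-samples features survive.
  Blank injections are dropped from the table once the stage has used
  them.
* **Normalization** divides each sample by `reference[s] /
  geometric_mean(reference)`. Anchoring to the reference's geometric mean
  preserves the intensity scale. A consequence worth stating precisely:
  rescaling a single sample is corrected up to one global constant shared
  by all samples (the anchor itself moves by c^(1/n)), which cancels in
  every downstream statistic; per-sample ratios to the reference are
  restored exactly. The reference feature and anything within 3 ppm and
  ±5 s of its configured isotope/adduct offsets are excluded from testing,
  automating what is otherwise a manual cleanup of
  reference-normalization degenerates.
* **The Welch test runs on log2 intensities by default.** The noise model
  for LC-MS intensities is multiplicative (log-normal), under which
  log-scale data are normal and the test is as calibrated as Welch can
  be; on raw log-normal intensities the test is noticeably conservative
  at small n. Fold changes are always reported as the ratio of raw group
  means, per the usual volcano convention; `welch_on_log = FALSE`
  restores raw-scale testing. Degenerate zero-variance features with
  equal means get t = 0, p = 1.
* **BH adjustment** uses `stats::p.adjust(method = "BH")`; significance
  is q ≤ `fdr_q`.

A caveat the test suite quantifies: Welch's *t*-test with
Welch–Satterthwaite degrees of freedom is intrinsically conservative at
n = 6 per group — its true size at nominal 0.05 is below 0.05 even on
exactly normal data, a small-sample property of the Satterthwaite
approximation rather than of this implementation. The calibration check in
the acceptance suite measures this directly; the direction of the
deviation (fewer false positives than nominal) is benign for the
screening use the pipeline serves.

## Tracer matching

`find_label_pairs` tests every feature u against every deuterium count n
in the design (default 1–13): candidates lie within 3 ppm of
u.mz + n·Δm_D and within a **signed** co-elution window for
rt(labeled) − rt(unlabeled), default −10 to +2 s, since deuterated species
elute slightly earlier on reversed phase. The best candidate per (u, n) is
chosen by absolute ppm error (ties by |ΔRT|), and each labeled feature is
then assigned to at most one pair, greedily by mass error, so one observed
isotopologue never supports several deuterium hypotheses.

Enrichment scoring uses a detection floor (default 10,000 AU, the same
intensity scale as the pipeline filter) and a fold rule (default 5):
*enriched* means detected in the labeled condition and absent — or at
least 5-fold lower — in the control; detection in both at an intermediate
ratio is *ambiguous*; no elevation (ratio ≤ 1) or non-detection is
*not-enriched*. Matching itself uses only m/z and RT, so it is invariant
to uniform intensity rescaling; the verdicts are not, because the floor is
absolute by design.

## The tracer-fate model

`labeled_chain` stores a fatty acid as carbons numbered from the carboxyl
(C1), with per-carbon deuterium counts. Hydrogens are never stored:
each carbon's hydrogen slots follow from its bonding, and every slot not
holding a D holds an H. This makes valence a structural invariant —
operations cannot leak hydrogens, and deuterium moves only when a rule
explicitly removes it.

* **The D13 label** on vaccenic acid is two deuteriums on each of C13–C17
  and three on C18, the commercial 13,13,…,18,18,18-d13 pattern; the
  constructor exposes the per-carbon vector so alternative patterns are
  testable.
* **Methyl transfer** (cis-specific) adds an unlabeled CH3 at the
  proximal olefinic carbon, migrates the double bond one position distal
  with *trans* geometry, and abstracts one hydrogen from the carbon that
  turns sp² — a deuterium when present. Isotope effects are ignored
  throughout: abstraction and hydroxylation remove D preferentially
  because the bookkeeping tracks the maximal-label species.
* **Cyclopropanation** (cis-specific) replaces the double bond with an
  unlabeled CH2 bridge; nothing is abstracted. Its products are
  constitutional isomers of the methyl-transfer products — identical
  formulas and m/z, distinguishable only by the transformation trace.
* **β-oxidation** is collapsed to its net effect: remove C1 and C2 (with
  their deuterium), strip the new carboxyl carbon of its H/D (lost to the
  redox steps of the cycle), renumber by −2. A methyl branch, ring, or
  hydroxyl at C2/C3 blocks the round — the termination condition that
  makes C11 β-branched acids end products after exactly four rounds from
  C18. Modeling the CoA intermediates would add nothing to the formula or
  deuterium predictions, so all species are treated as free acids.
* **α-oxidation** is two stages: 2-hydroxylation (taking an H when one is
  present) yields the isolable 2-hydroxy intermediate; cleavage plus
  aldehyde oxidation removes C1 and strips the new carboxyl carbon.
* **Hydroxylation** accepts a carbon index or `"omega"`/`"omega-1"`.
  Which distal position the dihydroxy acid carries is not fixed by the
  deuterium data — any deuterated distal carbon predicts the same D
  count (11 from the D13-cis precursor) — so the position is an explicit
  parameter defaulting to ω−1, matching the one distal position that has
  been assigned structurally in this family.

The diagnostic chain of D counts from the D13-cis precursor — 13 in the
substrate, 12 after methyl transfer (one abstraction), still 12 after four
β-oxidation rounds but with a single D at product carbon 5, and 11 after a
distal hydroxylation — falls out of these rules with no fitted parameters,
and the *trans*-labeled substrate is rejected at the first step.
Stereochemistry is carried as annotation only; masses are
stereochemistry-blind.

## Synthetic data and what the tests show

`generate_differential_table` emulates the two-genotype design:
per-feature base intensities log-uniform over 10^3.5–10^6 AU,
multiplicative log-normal noise with σ = 0.2 (≈20% CV, a typical
replicate-level figure for this kind of data), m/z uniform over the
117–1000 Th scan range, RT uniform over the filter window, a 10% stratum
of blank-contaminated features sitting below the 5-fold rule, a
low-variance reference feature absent from blanks, and differential
features at a configurable fold change whose base means sit above the
intensity filter so planted truth is recoverable. `generate_tracer_table`
plants labeled partners at exact n·Δm_D offsets with configurable ppm
jitter and an RT shift (default −2 s), intense only in the labeled
condition. Both generators are pure functions of their arguments
including the mandatory seed.

The test suite uses these problem sizes: 200 null tables of 1,000
features (n = 6/6) for test calibration; 100 seeded tables of 200
features with 10 planted 8-fold changes for recovery and empirical FDR;
100 seeded null tracer tables for enrichment specificity, with the
labeled condition an exact copy of the control so that any "enriched"
verdict is a coding error rather than sampling noise.

What passing these tests does **not** show about real data: the generator
plants independent features (no shared-pathway correlation, no
adduct/isotope degeneracy beyond the reference's), no retention-time
drift, no batch or injection-order structure, no heteroscedastic
ionization suppression, and no partial-labeling isotopologue envelopes
(matching scores full-shift species only). Survivor counts on real
feature lists depend on the acquisition and peak-picking upstream of this
package and are not reproduced here.

## Reporter quantification

`normalize_gfp` implements per-experiment background subtraction (the
mean of all animals' minimum intensities) and anchoring to the untreated
control mean, so control animals average to exactly 1 in every
experiment; corrected intensities are floored at zero with a warning for
animals dimmer than background. `ddct_expression` averages technical
replicates before any ΔCt arithmetic, centers ΔCt on the mean of the
control samples, and reports 2^(−ΔΔCt); the control aggregation uses the
arithmetic mean of ΔCt, equivalently the geometric mean of folds, which
is therefore exactly 1 over controls. Amplification-efficiency
corrections beyond the pure ΔΔCt model are out of scope.

## Known limitations

* Only singly charged [M−H]⁻/[M+H]⁺ adducts; no isotope-abundance
  envelopes (monoisotopic and explicit-D species only).
* Two-group Welch designs only; no mixed models, batch correction, or
  multi-factor layouts.
* The β-oxidation block condition is structural (β-substituent), not
  kinetic; enzyme kinetics, flux, and elongation/desaturation reactions
  are not modeled.
* Isomer naming (RT-resolved isomer families) is out of scope; query
  windows support isomer splitting but assignment is left to the analyst.
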