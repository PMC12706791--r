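---
title: "Revising pyranoxanthone structures from carbon-13 shifts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Revising pyranoxanthone structures from carbon-13 shifts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyranoshift)
library(dplyr)
```

## The problem

Pyranoxanthones are xanthones carrying a fused 2,2-dimethylpyran ring formed
by prenyl cyclisation. Because the pyran can fuse at several positions of the
tricyclic core, regioisomers abound, their ¹³C spectra are deceptively
similar, and the literature contains many structures whose reported shifts do
not actually fit the drawn molecule. `pyranoshift` implements a desk workflow
for auditing such assignments: subtype classification from diagnostic
markers, empirical correction of DFT-calculated shifts, candidate ranking by
RMSD/maximum deviation and DP4 probabilities, database-style dereplication,
and an end-to-end revision verdict.

Compounds are organised by a subtype code: a letter A–D for the prenylation
site (C-1 through C-4), a first digit for the core carbon bonded to the pyran
oxygen, and a second digit for the position of an extra oxygenated
substituent on the pyran-fused ring (0 when absent). `"B31"` is the linear
isomer (prenyl at C-2, pyran oxygen on C-3, hydroxyl at C-1); `"D31"` is its
angular twin.

## Data model

Everything flows through one tidy table: one row per assigned carbon with
`compound_id`, `label` (IUPAC xanthone numbering; pyran olefinic carbons are
normalised to `C-1'`/`C-2'` whatever prime convention the source used),
`shift_ppm`, `carbon_class` (a closed vocabulary distinguishing aromatic
CH/quaternary, carbonyl, the two pyran olefinic roles, the pyran-oxygen
quaternary, methyl, methoxy), and provenance columns. Shifts are stored at
source precision and never silently rounded; rounding to 0.1 ppm happens only
in presentation. Solvent is recorded but takes no part in scoring.

## Boltzmann averaging

Calculated shifts for flexible molecules are conformer-population averages.
`boltzmann_average()` weights conformer *i* by
\(w_i \propto \exp(-(E_i - E_{\min})/RT)\) with energies in kJ/mol
(*R* = 8.314 J mol⁻¹ K⁻¹, *T* = 298.15 K by default). The result is
invariant to a constant energy offset, and the high-temperature limit is the
unweighted mean — both asserted in the tests.

## Empirical correction factors

Across a modeling set of trusted structures, calculated shifts are
systematically high at the carbonyl-flanking positions C-1/C-8 and at the
pyran olefinic C-1′, and low at C-2′. `derive_corrections()` estimates one
additive offset per correction class as the untrimmed mean of (experimental −
calculated) over all matched carbons; C-1 and C-8 are pooled into a single
class because of their symmetry-equivalent environments. Untrimmed means are
used because the derivation procedure we mirror reports means without a
stated outlier-trimming step. Applying the factors back to the derivation set
zeroes the class-wise mean residuals exactly — a property the tests assert to
1e−9. The packaged defaults are the gathered-scope values −2.9 (C1/C8),
−3.7 (C-1′), +2.8 (C-2′) ppm; per-type scopes are supported but not default.
No slope/intercept rescaling of calculated shifts is performed in the
correction step — the systematic errors here are additive and local, not
global scale errors (an opt-in linear rescaling exists in the scoring layer
for users wanting the original DP4 formulation).

## Scoring and DP4

`shift_deviations()` aligns an experimental and a calculated entry on
normalised labels (corrections applied first when supplied), reporting
unmatched labels rather than dropping them silently. RMSD and maximum
absolute deviation summarise the vector. `dp4_probabilities()` implements the
Bayesian candidate probability built from Student-t survival functions of
scaled errors, with the published ¹³C parameters σ = 2.306 ppm, ν = 11.38 as
defaults; likelihoods are accumulated in log space so 20-carbon products
cannot underflow, and the tests check log-space results against a direct
product oracle to 1e−10. DP4 operates on correction-applied deviations by
default, which is the workflow the corrections were derived for; the
linear-rescaling alternative is off by default.

A lone aberrant deviation amid otherwise good agreement usually means a typo,
a misread spectrum or contamination rather than a wrong structure:
`flag_single_outlier()` flags the largest |Δ| only when it reaches `t_major`
(default 5 ppm) while every other |Δ| stays at or below `t_rest` (default
3 ppm). Those defaults are heuristics chosen so that the narrated pattern —
one 8.2 ppm deviation against residuals under ~2–3 ppm — is flagged while
ordinary noise is not.

## Subtype classification

The marker table (`markers.json`) records, per subtype, expected shifts for
the carbons adjacent to the pyran ring plus the carbonyl. Values anchored in
reported narrative are tagged `source: "narrative"`; the remainder are
implementer interpolations within typical pyranoxanthone ranges, because the
full reference figure is not machine-readable. Default tolerance is ±1.5 ppm
per marker: matching literature cases agree to under 1 ppm while true
mismatches run 6 ppm and more, so the midpoint band is uncritical.

`classify_subtype()` matches each marker greedily to the nearest unconsumed
shift, with two restrictions applied in order: a shift bearing the marker's
own carbon label is preferred when the entry reports one (assignment labels
are information, and the published arguments we mirror reason from them), and
otherwise candidates are restricted to compatible carbon classes, the way
DEPT/HSQC multiplicities constrain real assignments. Greedy matching with
consumption is adequate at ≤6 markers per subtype and keeps the engine
transparent. Subtypes rank by fraction matched, then mean absolute deviation,
then code — fully deterministic. No subtype is asserted below a 0.6 matched
fraction. Dual-pyran compounds are classified in two passes with the first
ring's consumed shifts removed. Subtypes without recorded ¹³C markers are
simply absent from the table and raise a lookup error when claimed — we
exclude rather than guess wide tolerances for them.

The carbonyl is an independent witness: it resonates near 176 ppm without
intramolecular hydrogen bonding and up to ~186 ppm when chelated on both
sides. `carbonyl_hbond_state()` bands the shift at 178 and 184.5 ppm —
interpolations between those anchors and the narrated one-bond cases near
180–183 ppm — and both boundaries are configurable.

## Dereplication

`search_by_shifts()` matches a query shift list against each reference entry
as multisets of ppm values — deliberately label-free, because the assignments
themselves are what is under suspicion. The matching is an exact dynamic
program over the two sorted lists (non-crossing optimality holds for sorted
sequences under absolute difference), maximising matched carbons and then
minimising the summed difference under a 0.5 ppm default tolerance. The
tests and the acceptance script verify it against exhaustive bitmask
assignment enumeration on hundreds of random instances. `find_conflicts()`
flags both literature failure modes: identical data under distinct
structures, and divergent data under one compound name (tolerance 1.0 ppm,
overlap 0.9 by default). `detect_swapped_assignments()` searches single
transpositions only — the classic C-8a/C-9a reversal — which keeps the scan
O(n²) and matches the observed failure mode; general permutations are out of
scope.

## Synthetic data

No public shift tables accompany the study this workflow mirrors, so the
package generates its own test universe with the statistical structure the
analysis assumes. `generate_subtype_compound()` draws marker carbons at their
expected values plus Gaussian jitter (σ = 0.8 ppm by default, a realistic
between-compound spread for diagnostic positions given that matching cases
agree to under 1 ppm); filler core carbons sit at typical pyranoxanthone
positions, perturbed deterministically per subtype within ±3 ppm and clamped
to documented per-class ranges (`filler_carbons.json`). Fillers are
scaffolding, not literature claims. `generate_modeling_set()` (default n =
76, the modeling-set size) adds the systematic class offsets (+2.9/+3.7/−2.8
ppm as calculated-minus-experimental) and Gaussian residual noise (σ = 1.0
ppm by default, matching the 1–3 ppm accuracy regime of corrected DFT
shifts) to produce calculated twins. Noise is independent per carbon — the
simplest model consistent with a mean-offset correction; a Student-t option
mirrors the DP4 error model. Within-compound error correlations are not
modelled, and conformer ensembles are not simulated. Every generator is a
pure function of (config, seed) via `withr::with_seed()`.

What passing synthetic tests shows — and what it does not: the pipeline
provably recovers injected offsets, separates marker-distinct subtypes and
reaches its verdicts under the assumed error model. Real spectra add
solvent/referencing shifts, correlated DFT errors, overlapping and missing
signals; performance there rests on the parameter anchors, not on these
simulations.

## Marker-distinct subtypes

Top-1 recovery under jitter is only a fair expectation for subtypes whose
markers actually separate them. `marker_distinct_subtypes()` formalises this:
a subtype qualifies iff, on its noise-free prototype, no competing subtype
can match at least (1 − 1/n) of the prototype's markers after widening every
tolerance by one jitter SD. With the shipped table this yields A20, A23, B13,
C40 and D31; the near-twin pairs (linear/angular B31/D31 from the B31 side,
B34/D32, C21/C24) are excluded by construction — exactly the pairs whose
discrimination requires full candidate scoring rather than markers alone.
Classification recovery for the distinct set exceeds 95% at 200 draws each
(asserted in the acceptance tests); the pairwise analogue
(`marker_distinct_pairs()`) supplies discriminable true/claimed pairs for the
verdict benchmark.

## The revision pipeline and its decision rule

`revise()` runs, in order: subtype diagnosis, consistency check of the
claim, dereplication (always, even when the claim looks consistent —
conflicts have been found behind apparently fine assignments), candidate
correction + scoring, swap diagnostics against the top candidate, verdict.
The source decisions were expert judgement; the packaged rule is an explicit
operationalisation stated in `revision_config()`:

* **reassign** when a non-claimed candidate reaches DP4 ≥ 0.95 *and*
  RMSD ≤ 4.0 ppm, or when a dereplication hit matches ≥ 90% of the entry
  while the claimed subtype has at least one marker violation;
* **unresolved** when violations exist but no candidate or hit passes;
* **consistent** otherwise.

The RMSD gate exists because DP4 is relative across the offered candidates: a
lone poorly fitting candidate would otherwise win with probability 1. Its
4.0 ppm default sits between the corrected-structure RMSDs seen for correct
candidates (≈2–3.6 ppm) and the smallest narrated wrong-candidate value
(≈4.2 ppm). The DP4 threshold of 0.95 is policy: decisive literature cases
report 100% but state no cutoff. Reports serialise to JSON without
timestamps, so identical inputs give byte-identical output.

On the packaged synthetic benchmark — 100 consistent and 100 misassigned
cases over marker-distinct pairs, jitter 0.8 ppm, candidate noise 1.5 ppm —
verdict accuracy exceeds 99% with the default policy (asserted ≥90% in the
acceptance tests, a property-based substitute for results that would need
the original DFT outputs).

## Numerical choices and degenerate inputs

* DP4 in log space; an all-candidate underflow to −∞ raises a numeric error
  rather than returning NaNs.
* Ties in candidate ranking break by lower RMSD then lexicographic id; ties
  in classification by mean deviation then subtype code.
* Empty correction factors are an identity; classes with no matched carbons
  are omitted with a warning, never zero-filled.
* Duplicate labels are rejected unless flagged `double` (one double-intensity
  signal legitimately read twice).
* Problem sizes in tests and the acceptance script — 76-compound sets for
  offset recovery over 100 seeds, 200 draws per subtype for recovery, a
  200-case verdict benchmark, 500 random instances for the matching oracle —
  were chosen to estimate each property comfortably within its tolerance.

## Known limitations

* Subtype codes are the only structural representation: no connection
  tables, no substituent inference beyond the code, no ¹H scoring (¹H
  arguments appear only as free-text evidence in the source material).
* The marker table mixes narrative-anchored and interpolated values; users
  with access to richer reference data should replace `markers.json`.
* The registry and modeling-set catalog are curated from the running text of
  the source study; per-entry deviation statistics that exist only in
  figures are not transcribed.
* Dereplication is a stand-in for a curated database service: the matching
  objective is stated and tested here, but it is not a reimplementation of
  any service's internal scoring.
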