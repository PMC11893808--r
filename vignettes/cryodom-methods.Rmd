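---
title: "Methods: molecular OM dynamics in glacier algal habitats"
author: "cryodom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular OM dynamics in glacier algal habitats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Surface blooms of glacier ice-algae and red snow-algae fix carbon into
dissolved and particulate organic matter (DOM and POM). Under continuous
summer light and heterotrophic activity, individual molecular formulae
can move from POM into DOM, be photoproduced or photo-degraded, be
consumed or produced by heterotrophs in the dark, or persist untouched.
Ultrahigh-resolution mass spectrometry resolves thousands of exact-mass
peaks per sample; assigning each peak an elemental composition and
following its relative abundance through a light/dark incubation time
series turns the spectra into a process-level budget of the organic
matter pool.

`cryodom` implements that analysis end to end, and — because it must be
testable without deposited field data — a synthetic-experiment generator
whose planted process classes serve as ground truth for every downstream
stage.

# Formula assignment

Peaks are treated as singly charged deprotonated ions; the neutral mass
of a peak is m/z + 1.00727646 Da. Candidates are enumerated over the
element box C 0–100, H 0–200, O 0–50, N 0–4, S 0–2, P 0–1 with chemical
validity (integer DBE ≥ 0, C ≥ 1, H ≥ 1) and, by default, the common DOM
plausibility screens H/C ∈ [0.3, 2.5] and O/C ≤ 1.2. The enumeration
solves for the hydrogen count per (C, N, O, S, P) cell, so it is exact
with respect to a brute-force scan of the box (the test suite verifies
set equality against an independent nested-loop oracle on random
masses).

Stages per spectrum, in order:

* **MDL filter.** The noise level is the median intensity of the lowest
  decile of peaks (a user-supplied constant may replace it); peaks below
  `mdl_factor` (default 2) times that level are discarded. The estimator
  is a deliberate simplification of detection-limit procedures that
  operate on raw spectra, which are out of scope here; it is monotone
  and overridable, which is all the downstream stages require.
* **Recalibration (optional).** Calibrant ions matched within 0.5 ppm
  and with signal/MDL ≥ 5 define a mean signed ppm error that is removed
  from all peaks ("mean" recalibration mode); fewer than three matches
  is an explicit error so a spectrum is never silently recalibrated on
  too little evidence. The operation is idempotent to < 1e-6 ppm.
* **Series-network assignment.** All candidates of the spectrum form a
  graph with an edge wherever two candidates differ by exactly one
  homologous building block (CH₂, CO₂, H₂, H₂O, O, as element-count
  steps, not mass windows). A candidate needs at least
  `min_series_links` partners (default 1) to survive — natural organic
  matter is dominated by homologous series, and an isolated candidate at
  a single mass is most likely a false hit.
* **Candidate ranking.** The default rule is parsimony first: among
  surviving in-tolerance candidates, the fewest heteroatoms (N+S+P)
  wins, ties broken by smaller absolute mass error. We measured the
  alternative (smallest error first) on the constraint box: above
  ~500 Da, 30–53 % of adjacent valid formulae lie within 0.5 ppm of each
  other, and the near-coincident pairs always involve S/P swaps or
  O-extreme compositions. With realistic mass error (0.1 ppm), an
  error-first winner therefore flips between duplicate measurements of
  the same sample, and the duplicate rule then deletes the formula
  entirely — a failure mode invisible on any single spectrum. Parsimony
  ranking is deterministic across replicates and matches long-standing
  CHO-preference practice in DOM assignment; `ranking = "error"`
  restores the error-first rule.
* **Isotopologue check.** If a peak exists at +1.0033548 Da with
  signal/MDL > 5, the observed ratio is compared with 0.0107 × C;
  deviations above 1000 ‰ remove the assignment. Missing isotope peaks
  never penalize an assignment. The tolerance is interpreted on the
  intensity ratio (the alternative reading — a tolerance on the isotope
  mass position — would make the stated 1000 ‰ meaningless).

Across samples, spectra are aligned by identity of elemental
composition: two peaks belong to the same matrix row exactly when they
received the same formula. m/z-cluster alignment of unassigned peaks is
out of scope.

Finally, every formula detected in any procedural blank is removed from
all samples, each replicate is normalized to total intensity 1, a
formula counts as present only when detected in all replicates of a
sample, merged values are means of the normalized replicate intensities,
and each merged column is re-normalized to sum 1 (asserted to 1e-9).

# Molecular descriptors and categories

For each formula with C ≥ 1:

* AI<sub>mod</sub> = (1 + C − 0.5·O − S − 0.5·(H + N + P)) /
  (C − 0.5·O − S − N − P), set to 0 when the numerator is negative or
  the denominator non-positive and capped at 1.
* NOSC = 4 − (4C + H − 3N − 2O − 2S)/C.
* DBE = 1 + (2C − H + N + P)/2 and DBE−O.

Elemental classes CHO/CHON/CHOS/CHOP are made exclusive with precedence
P > S > N (preserving the rarest heteroatom), so class shares always sum
to 100 %. Categories are evaluated in a fixed first-match-wins order:
condensed aromatics (AI<sub>mod</sub> ≥ 0.67), aromatics (0.5 ≤
AI<sub>mod</sub> < 0.67), highly unsaturated (AI<sub>mod</sub> < 0.5 and
H/C ≤ 1.5), unsaturated aliphatics (1.5 < H/C < 2.0), saturated
(H/C ≥ 2.0). The CRAM flag uses the DBE-ratio windows DBE/C 0.30–0.68,
DBE/H 0.20–0.95, DBE/O 0.77–1.75 (O ≥ 1); the oxy-aromatic
phytochemical flag defaults to O/C ∈ [0.1, 0.85], AI<sub>mod</sub> ≥ 0.5
and mass ≤ 800 Da. All windows live in a configuration object
(`category_windows()`) precisely because the published numeric
conventions vary between studies; the phytochemical box in particular is
a stand-in to be replaced with a study-specific definition. Categories
indicate composition only — a matching formula need not share the
structure of any named compound class.

Pool summaries weight each descriptor by the formula's normalized
intensity in a reference sample, re-normalized over the subset
(`weighted_summary()`); composition shares are unweighted counts.

# Time-course classification

"Consistent decrease/increase" is operationalized by `monotone_rule()`:

* `tolerance_rel` (default 0.10): a step against the trend direction is
  tolerated while it stays strictly below 10 % of the running extremum.
* `min_points` (default 3): shorter series are never classified.
* `zero_eps` (default 0): presence threshold; a formula is absent only
  when it failed detection or the duplicate rule upstream.
* `min_change` (default 0.2): the net change over the series must exceed
  20 % of the initial value (a series starting at absence passes with
  any positive final value). Without a net-change floor, a *constant*
  series with vanishing noise would be classified as degraded or
  produced about half the time — any infinitesimal drift satisfies
  "final below initial" — and the refractory pool would empty as data
  quality improves, which is the wrong limit. The floor sits an order
  of magnitude above duplicate-level variability (CV 0.05 per
  measurement, averaged over duplicates) and an order of magnitude
  below every planted net change (≥ 80 %).

The decision families are independent, per habitat:

* **Dark:** a consistent dark-series decrease starting from DOM-T0
  presence is HETERO_DEGRADED (with reached-zero flag and event time —
  the first time the series hits zero and stays there, otherwise the
  last observation); a consistent increase is HETERO_PRODUCED. Light
  behavior does not veto either ("not exclusively" heterotrophic).
* **Light:** PHOTOPRODUCED requires a light-series increase *and* no
  dark-series increase; PHOTO_DEGRADED a light decrease and no dark
  decrease. A formula trending in both conditions gets its dark label
  only.
* **Transfer:** membership in a particulate extract at T0, presence in
  DOM under light at some t > 0, and (strict mode, the default) absence
  from DOM in the dark at every t > 0. The relaxed mode
  (`transfer_mode = "relaxed"`) tolerates dark presence in up to 20 % of
  dark timepoints. The extract of origin (water-soluble vs
  water-insoluble) is recorded. POM-T0 membership alone defines the
  particulate side — simultaneous later presence in POM is not required,
  matching the normalization of transfer counts by the POM-T0 total.
* **Refractory:** present in every measured sample of every pool the
  formula occupies at T0, and no degraded label from either family.
  Restricting the check to *measured* samples makes sparse particulate
  series (e.g. a habitat whose POM could only be measured at the first
  and last timepoint, supported via `pool_timepoints`) behave sensibly.

Pool percentages divide transferred counts by the POM-T0 formula count,
produced/degraded counts by the DOM-T0 count, and refractory counts by
all formulae of the habitat. Note that the light-production pool
deliberately includes POM-released formulae that rise in DOM only under
light — the two processes overlap by definition, and the per-family
label table keeps them distinguishable (`transfer` column vs `light`
column).

# The synthetic generator

`sample_formula_pool()` draws formulae as homologous chains (default
length 5): a weighted random core is extended by CH₂/CO₂/H₂/H₂O/O steps.
Chains guarantee that every planted formula has series partners in every
spectrum where its class is present — without this, chain-isolated
formulae would be rejected by the network filter for reasons that have
nothing to do with the planted dynamics. Since the blocks carry no
N/S/P, each chain stays in one elemental class. Cores are drawn with
per-atom weights (default 0.35/0.10/0.06 for N/S/P) giving a
CHO-dominated pool with minority CHON/CHOS/CHOP shares, as in natural
organic matter, and each member must be *identifiable*: no box formula
within 1 ppm may match it with an equal or smaller heteroatom count, so
planted formulae are unique parsimony winners of their own mass
neighborhoods. Masses default to 100–800 Da.

`planted_truth()` assigns whole chains to classes (default fractions:
transferred 0.15, photoproduced 0.10, photo-degraded 0.10,
hetero-produced 0.10, hetero-degraded 0.20, refractory 0.15, remainder
unclassified background). With these defaults the particulate-T0 pool is
transferred + refractory + background, so the planted transfer share of
POM-T0 is exactly 30 %.

Planted dynamics (in relative-abundance pattern space):

* Degraded formulae deplete **linearly** to a residual floor (10 % of
  initial) by the end of the incubation; a to-zero subset (half of each
  degraded class, whole chains) depletes linearly to zero at the
  extinction time (day 15). Linear depletion keeps every step of the
  trend well above duplicate noise; saturating forms (exponential decay
  mirrored into logistic-like production) were evaluated and rejected
  because their late-time increments (~1 % per step) fall below the
  noise floor, making the planted trend genuinely undetectable — a
  property of the planted data, not a classifier defect.
* Produced formulae split the *exact* abundance lost by the degraded
  formulae of their series (weights proportional to their base
  intensities): hetero-produced rise in both dark and light from absence
  at T0; photoproduced rise only under light; transferred rise in DOM
  only under light while present in one POM extract at T0 (depleting to
  zero there by the end, as leached material does).
* Refractory formulae are constant everywhere; background formulae
  follow a strict up/down alternation (±25–60 % steps, random phase)
  that fails both monotonicity tests deterministically, and each is
  absent from exactly one random non-T0 sample so that "always present"
  cannot hold for them.

Because production exactly mirrors degradation and the background block
is re-scaled per sample, every DOM column has the same total intensity.
This matters: classification happens after closure (per-sample
normalization to 1), and any monotone drift of the column totals would
superimpose a spurious trend on *constant* formulae — with zero noise, a
0.1 % systematic drift would be enough to mislabel every refractory
formula. With constant totals, planted shapes pass through normalization
unchanged and the zero-noise configuration recovers the truth table
exactly.

Measurement effects: intensities carry multiplicative lognormal noise
(CV 0.05 per measurement), m/z values a Gaussian error (sd 0.1 ppm,
truncated at 4 sd), each spectrum receives junk peaks below the
detection limit (so the MDL stage has something to do), blanks contain
contaminant chains partially spiked into real samples (so blank removal
is observable), and a 2 % fraction of formulae loses its peak in one
replicate of one uniformly chosen sample slot (exercising the duplicate
rule). The dropout slot is uniform over the sample grid rather than over
the formula's presence set: sporadic detection failure does not know
where a formula "should" be, and conditioning on presence would
concentrate all damage on classes with small footprints.

What the generator does *not* emulate: raw transients or resolution
effects, chromatography, adducts beyond [M−H]⁻, multiply charged ions,
isotopologue fine structure (the default truth contains monoisotopic
peaks only — the paper-style formula counts exclude isotopic peaks — and
the isotope-verification stage is exercised by constructed fixtures),
correlated noise between formulae, or compositional differences between
habitats beyond independent class assignment. Passing tests therefore
demonstrate correct recovery of planted monotone dynamics under
independent multiplicative noise, not performance on raw instrument
data.

# Ordination

Bray–Curtis dissimilarities (vegan::vegdist) feed a seeded
best-of-restarts two-dimensional NMDS (vegan::metaMDS, no
autotransformation, Kruskal stress, monotone regression). Formula
loadings are intensity-weighted averages of the sample coordinates;
sample scores and loadings are rescaled per axis so sample scores span
[−1, 1], which puts the habitat-signal threshold (default 0.45) on a
stable scale — the raw NMDS axis units are arbitrary. A threshold
selecting `loadings ≤ −0.45` vs `loadings ≥ +0.45` necessarily refers to
opposite signs; the sides are named by the habitat centroid falling on
them. Intensities (not presence/absence) enter the dissimilarity, in
line with using mean normalized intensities throughout.

# Numerical choices and degenerate inputs

* Exact masses: C 12 (exact), H 1.00782503, N 14.00307401, O
  15.99491462, S 31.97207069, P 30.97376200; proton 1.00727646; ¹³C−¹²C
  1.0033548; ¹³C abundance 0.0107 per carbon.
* Tolerance comparisons in the enumeration and assignment carry a 1e-9
  Da absolute slack so that a zero-width tolerance still accepts exact
  floating-point round trips.
* Backstep comparisons are strict: a backstep of exactly
  `tolerance_rel` fails.
* Ties between equally parsimonious candidates fall back to mass error;
  exact ties beyond that are broken by table order (sorted by mass) and
  are not expected within any realistic tolerance.
* Empty peak lists pass through the MDL filter unchanged; an empty
  formula subset, a zero denominator (no DOM-T0/POM-T0 formulae), a
  missing replicate, or an all-zero sample column raise immediate errors
  naming the offending sample.
* Problem sizes: the validation suite runs the full design (2 habitats ×
  3 pools × 7 timepoints × 2 replicates ≈ 170 spectra) with a
  1000-formula pool for the end-to-end checks and 40–300 formulae for
  unit-level properties; the enumeration oracle sweep uses 200 random
  masses at 1 ppm.

# Known limitations

* The MDL noise estimator and the cross-sample alignment are desk-scale
  approximations of procedures that, in the original software chain,
  operate on raw spectra.
* Parsimony-first ranking will misassign a genuinely heteroatom-rich
  formula whose exact mass is shadowed by a simpler composition within
  the tolerance; such formulae are rare in CHO-dominated material but
  real. The `ranking = "error"` mode is available when mass accuracy is
  good enough (≪ 0.1 ppm) to separate such pairs.
* Category and phytochemical windows are conventions, not measurements;
  they are configurable and reported in the output metadata.
* The classifier sees closed (relative) data; a strong absolute trend in
  total DOM load is invisible to it, and a formula constant in absolute
  terms appears anti-correlated with the rest. This is inherent to
  normalized intensities, not specific to this implementation.
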