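---
title: "Detecting transmembrane helix packing from evolutionary couplings"
author: "covhelix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transmembrane helix packing from evolutionary couplings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covhelix)
```

## The problem

Polytopic membrane proteins are hard to crystallize, and for many families
the only abundant data are sequences. When two residues are in physical
contact, substitutions at one position are compensated at the other over
evolutionary time, and this co-variation is detectable in a deep multiple
sequence alignment. For a helical membrane protein the contact signal is
strongly structured: an interacting helix pair leaves a *stripe* in the
residue-residue coupling matrix — diagonal for parallel packing,
anti-diagonal for antiparallel packing — with bumps every ~3.5 residues,
the helical turn, because only one face of each helix meets the partner.

`covhelix` implements the full path from an alignment to a crude
three-dimensional helix bundle: coupling estimation, stripe detection with
Bayesian evidence aggregation and posterior calibration, ranking and
filtering of residue pairs into distance restraints, ideal-helix bundle
construction, structure-comparison geometry, and the membrane observables
used to interrogate a simulated bilayer around such a model. A
synthetic-data module generates seeded inputs with the statistical
structure every stage assumes, so the whole pipeline is testable with no
external downloads.

## Coupling estimation

Two estimators are provided behind one interface
(`compute_couplings()`).

* `mi_apc` — plug-in mutual information between column pairs with the
  average-product correction (APC) subtracted and negatives clamped to
  zero. Cheap, and adequate for strongly covarying columns.
* `mf_dca` (default) — a mean-field direct-coupling estimator: empirical
  single-site and pairwise frequencies over 21 states (the gap is a
  state; the gap state is also the reference state dropped from the
  covariance), a small frequency pseudocount (0.01), a ridge on the
  covariance of `0.5 * mean(diag(C))`, coupling blocks from the negative
  inverse, zero-sum gauge, Frobenius norms, APC.

The exact estimator used in the original analysis of YidC is an external
program and its regularization details are not part of this package;
`mf_dca` reproduces the qualitative stripe structure the detector needs,
and a precomputed matrix can be supplied as TSV (`read_couplings()`),
which round-trips bit-exactly against `write_couplings()`. Alignments can
be redundancy-filtered with a greedy 90%-identity pass
(`filter_redundancy()`), matching the usual preprocessing; optional
80%-identity clustering weights exist but are off by default, since
redundancy filtering already serves that purpose.

A column in which only one symbol is observed carries no information; its
couplings are defined as zero rather than raising an error.

## The sliding-pattern detector

The detector (`scan_helix_pair()`, `predict_all_pairs()`) slides a
17 x 17 weighted pattern (289 cells) over the inter-helix block of the
coupling matrix. In diagonal coordinates — offset `o = u - v` selecting a
diagonal, `s = (u + v)/2` the position along it — the parallel weight
grid is

w(u, v) = max(0, cos(2&pi; d(o)/p)) &middot; max(0, cos(2&pi; d(s)/p)),

with `p = 3.5` and `d(.)` the distance to the nearest multiple of `p`:
cosine ridges on the main diagonal and on diagonals every ~3.5 cells to
either side, with bumps every ~3.5 cells along each ridge. The weights
are normalized so `sum(|w|) = 1`, and the antiparallel grid is the row
reversal of the parallel grid (rows index the first helix N to C,
columns the second, so reversing rows turns diagonals into
anti-diagonals).

At every window position Bayes' rule converts the 289 coupling strengths
into a raw interaction probability:

logit(p) = logit(&pi;) + &Sigma;<sub>cells</sub> w &middot; [log f(s) − log g(s)],

where `f` and `g` are two-parameter gamma densities fitted by maximum
likelihood (`fit_strength_distributions()`) to coupling strengths at
interacting and non-interacting helix pairs of a labelled training set,
and &pi; is the prior interaction probability. Strengths are floored at
`eps = 1e-6` before density evaluation because exact zeros arise from
clamping and from zero-padding. Windows that overhang the inter-helix
block are zero-padded (a padded cell contributes the evidence of a zero
strength, i.e. background-typical); truncation is available via explicit
submatrix windows but padding is the default because it keeps every
center position comparable.

Evidence is aggregated over window positions with the **maximum** — a
pair interacts if it interacts at *some* register — with log-sum-exp soft
aggregation available (`aggregate = "logsumexp"`). The best position and
orientation are reported alongside the score.

### Calibration

Raw maxima over hundreds of windows are optimistic, so they are mapped to
honest probabilities by a monotone four-parameter curve

cal(r) = a + (b − a) &middot; sigmoid(c &middot; (logit(r) − d)),

fitted by Bernoulli maximum likelihood on unbinned labelled predictions
(`fit_calibration()`). We read the published description of a
"transformed Bernoulli distribution with 4 parameters" as exactly this
family: a Bernoulli likelihood whose success probability is a
four-parameter transform of the raw score; the binning (60 predictions
per bin) is only the reliability diagnostic, not the fit. Constraints
`0 <= a <= b <= 1`, `c > 0` are enforced by reparameterization, and the
optimizer is started from a small grid of data-driven initial values for
`(c, d)` because the transition location is poorly identified when the
raw scores concentrate far from logit zero. Calibrations fitted on
several datasets are combined as a size-weighted average of the curves
(`combine_calibrations()`), mirroring the published protocol of averaging
the calibrations of two held-out collections weighted by their sizes.

The decision thresholds quoted for the YidC analysis — confident above
57%, background below 15% — are configuration defaults here, not claims:
reproducing the published posteriors would require the original
2366-sequence alignment and the CATH-derived training sets, which are not
redistributable.

## Restraints

`select_top_pairs()` ranks off-diagonal couplings (ties broken by
ascending residue pair, `i < j` normalized). `apply_exclusions()` assigns
each ranked pair a status in priority order:

1. **indel** — either residue sits in an alignment indel column, or the
   partner residue has no reference position at all (such rows print no
   partner in the published table, which is why indels outrank the other
   rules: the pair cannot even be stated);
2. **intrahelical** — both residues in the same *helical* segment (loop
   pairs are kept: the published retained list contains many
   hairpin-internal pairs);
3. **topology violation** — the two residues cannot be near each other in
   a membrane: both outside the membrane on opposite sides, or further
   apart than `z_threshold` (default 12 A) under a per-residue membrane
   depth assignment.

The quantitative criterion behind the published "topology violation"
labels is not stated in the published record, so the packaged
transcription of the top-50 pair table carries the printed labels and a
*strict mode* honors them verbatim; the rule-based path is exercised on
synthetic annotations where ground truth is constructed. On the packaged
table the rule-derived indel and intrahelical calls coincide with the
printed ones, and strict mode reproduces the published 39 retained / 11
excluded split.

Retained pairs become C&beta;-C&beta; restraints, 0-8 A by default (the
community convention for covariation contacts; the published record does
not print its restraint form), written as CASP-RR records
(`write_restraints()`).

## Bundle construction

`place_helices()` positions helix axes in the membrane plane by
minimizing a stress: predicted contacts pull toward a target axis
distance (10 A), non-contacts repel when closer than that distance.
Multi-start BFGS (one circular layout plus seeded random starts; ties
resolved toward the earlier start so the deterministic circular layout
wins among equal optima) makes the outcome reproducible, and a gauge fix
— centroid at the origin, first helix on +x, reflection chosen so the
second helix has y &le; 0 — makes it byte-comparable. With the
cytoplasmic side at −z, this chirality convention lets the synthetic
pentagon fixture assert a definite cyclic order when viewed from the
cytoplasm.

`orient_by_exposure()` rotates each helix about its axis so
lipid-labelled residues face away from the bundle and protein-labelled
residues face it. The objective
&Sigma;<sub>lipid</sub> cos &theta;<sub>r</sub> −
&Sigma;<sub>protein</sub> cos &theta;<sub>r</sub> is a single cosine in
the phase, so the optimum is the circular-mean closed form; azimuthally
balanced labels make it degenerate, which is reported as a warning with
phase 0. The exposure *predictor* is out of scope — labels are inputs.

`build_ideal_bundle()` then writes backbone plus C&beta; coordinates on
ideal helix geometry: rise 1.5 A/residue, twist 100&deg;/residue,
C&alpha; radius 2.3 A (giving the canonical 3.8 A C&alpha;-C&alpha;
step), N/C/O from cylindrical offsets and C&beta; from the standard
tetrahedral construction, axis perpendicular to the membrane plane,
direction alternating with the annotated N-terminal side. Loops are not
built: the published pipeline delegates full-chain modeling to an
external restrained-modeling program, and this module deliberately stops
at the TM core.

## Structure geometry

`cb_distance()` (glycine falls back to C&alpha; — the published pair
table includes glycines), `superpose_rmsd()` (closed-form Kabsch with the
proper-rotation determinant correction; the test suite checks it against
an independent quaternion eigenvalue oracle to 1e-9),
`smoothed_ca_profile()` (per-residue C&alpha; distances after
superposition, centered moving average with shrinking edges), and
`pair_distance_table()` (per-pair distances with row-level error
reporting and the mean appended). Cross-species residue mappings come
from a Needleman-Wunsch global alignment (BLOSUM62, gap open 11, gap
extend 1) of the C&alpha;-derived sequences, optionally restricted to
annotated TM segments; an explicit mapping can always be supplied
instead. The exact TM-core residue ranges behind the published RMSD
table are not printed, so alignment-derived ranges are the default and
those comparisons are approximate by construction.

The deposited coordinate files needed for the published distance and
deviation tables (the YidC TM-region model and the two BhYidC2 crystal
forms) are not redistributable inside the package;
`analysis/04_structure_comparison.R` documents a one-line fetch-and-
reduce recipe and runs the full comparison when the files are present.

## Membrane observables

All trajectory analyses take a `bilayer_trajectory` (frames of
coordinates plus per-atom role/leaflet metadata; multi-model PDB plus a
metadata TSV is the file interface).

* `thickness_map()` — per 2 A grid cell and frame: the nearest
  same-leaflet phosphate within the bin radius, then the minimum 3D
  distance from it to any opposite-leaflet phosphate; occupancy-weighted
  time average; unoccupied cells are NA, never zero. Whether the
  published thickness used 3D or z-projected separations is ambiguous in
  the text; 3D minimum is the default and `project_z = TRUE` selects the
  alternative. Minimum-image wrapping applies in-plane when box
  dimensions are present (never in z — the slab separation must not be
  imaged away).
* `positional_variance()` — per residue, the mean over backbone atoms of
  the time-variance of position about the trajectory mean, **without**
  prior superposition: rigid-body helix motion is deliberately included,
  which distinguishes this flexibility measure from an RMSF.
* `hydrogen_bonds()` — geometric criterion only: donor-acceptor distance
  &le; 3.8 A and the H-D&middot;&middot;&middot;A deviation from
  linearity, measured as the angle at the donor between D&rarr;H and
  D&rarr;A, &le; 20&deg;; both boundaries inclusive. The angle convention
  is stated explicitly because the published record names only the two
  thresholds.
* `hydropathy_height_profile()` — residues binned by C&alpha; height
  across the membrane slab; hydrophobic iff the Kyte-Doolittle index is
  positive; out-of-range residues land in overflow bins rather than
  being dropped.
* `local_energy_average()` — per-residue energies are an *input* (force
  fields are not reimplemented; the defined computation is the
  averaging): time average per residue, then the mean over residues
  whose C&alpha; lies within 10 A, self inclusive.

## The synthetic generators and what they do not show

`gen_coupling_matrix()` plants, for each interacting pair, foreground
gamma draws on a coherent stripe: interface-facing positions recur every
3.5 residues on each helix, and a cell is planted when both residues face
the interface within one residue of the register diagonal
(anti-diagonal for antiparallel pairs). Background cells are iid gamma.
The defaults — background gamma(shape 1, scale 0.05), foreground
gamma(shape 4, scale 0.25) added on top, 18-residue helices — were
chosen once so that the planted pairs separate cleanly under the default
detector, mirroring the published decision thresholds (planted
posteriors above 57%, background below 15%) as a *self-consistency
fixture*; they are a statement about the generator, not about YidC.

`gen_bilayer_trajectory()` builds two phosphate grids at &plusmn;19 A
with an optional Gaussian depression applied symmetrically to both
leaflets (each moves depth/2 toward the mid-plane, so the planted total
thinning equals the nominal depth — matching the observation that
thinning is similar in both leaflets), plus per-frame isotropic jitter.
`gen_toy_bundle()` arranges ideal helices on a regular polygon.

What passing on this synthetic data does **not** show: real coupling
matrices have correlated noise (phylogeny, under-sampled clades) that iid
gamma backgrounds lack, so real-data error rates will be worse than the
synthetic recovery rates; orientation calls for weak in-register stripes
are close to chance even on synthetic data, because the two orientations
share full-weight pattern anchors every seven residues (two helical
turns) — pair *detection* is robust to this, orientation assignment is
not; and the planted bilayer has no protein, so the thinning recovery
exercises the estimator, not hydrophobic-mismatch physics. The published
membrane-thinning magnitude and interaction energies require the
original half-microsecond trajectory and are explicitly out of reach at
this scale.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run on deliberately small
problems chosen as representative: 7-helix systems with 18-residue
helices (L = 150), 15/25/25 proteins for the train/calibrate/test
splits, 100 detection replicates, 5-frame bilayers with ~340 phosphates,
and 10<sup>4</sup> frames only for the closed-form flexibility check.
Gamma fitting floors strengths at 1e-6; calibration clips raw scores to
[1e-9, 1 − 1e-9] before the logit; the placement optimizer treats
stress improvements below 1e-9 as ties; PDB coordinates round-trip at
the format's 1e-3 A precision. Scan ties between orientations resolve
to parallel, then to the smaller window center, so outputs are
deterministic.
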