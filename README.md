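# covhelix

Helix–helix contact detection from evolutionary couplings, and the
downstream analyses that turn such contacts into a structural model of a
polytopic membrane protein and interrogate it in a lipid bilayer.

When a transmembrane helix pair packs together, compensatory mutations
leave a periodic stripe in the residue–residue coupling matrix of a deep
sequence alignment: diagonal for parallel packing, anti-diagonal for
antiparallel, with bumps every ~3.5 residues (one helical turn).
`covhelix` implements:

* **Couplings** — MSA reading (FASTA/A3M/Stockholm), greedy 90 %-identity
  redundancy filtering, and coupling matrices via mutual information +
  APC or a regularized mean-field direct-coupling estimator; TSV
  round-trip for matrices computed elsewhere.
* **Detection** — a sliding 17 × 17 weighted pattern (289 cells, cosine
  ridges with 3.5-residue periodicity) scores every window of the
  inter-helix block by Bayes' rule,
  `logit(p) = logit(prior) + Σ w · [log fg(s) − log bg(s)]`,
  with gamma strength models fitted on labelled data; the per-pair
  maximum over positions and orientations is calibrated to a posterior by
  a monotone 4-parameter curve `a + (b−a)·σ(c·(logit r − d))` fitted
  under a Bernoulli likelihood, with size-weighted averaging of
  calibrations from several datasets.
* **Restraints** — top-k coupling pairs with exclusion rules
  (indel > intrahelical > topology violation) and CASP-RR Cβ restraint
  output; the package ships a transcription of the published top-50 pair
  table for *E. coli* YidC TM2–TM6.
* **Bundle building** — contact-graph stress placement of helix axes,
  closed-form exposure-driven rotation, ideal α-helix backbone + Cβ
  geometry, PDB output.
* **Structure geometry** — Cβ distances (Gly → Cα fallback), Kabsch
  superposition RMSD, smoothed Cα deviation profiles,
  alignment-derived cross-species residue mappings (BLOSUM62 global
  alignment).
* **Membrane observables** — leaflet-resolved bilayer thickness maps,
  positional-variance flexibility (global motion included), geometric
  hydrogen bonds (3.8 Å / 20°), height-resolved hydropathy, 10 Å local
  energy smoothing.
* **Synthetic data** — seeded generators for coupling matrices with
  planted stripes, labelled helix-pair datasets, ideal bundles and
  two-leaflet bilayers with a planted thinning depression, so the whole
  pipeline runs and is tested without any download.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
inputs and write tables under `results/`. Step 2 trains the detector on
15 simulated proteins, calibrates it on 25 more, and applies it to a
7-helix system with 7 planted contacts:

```
$ Rscript analysis/01_simulate.R
coupling matrix: 150 x 150, planted pairs: 7
bilayer: 5 frames x 338 phosphates, planted thinning 8 A

$ Rscript analysis/02_detect_contacts.R
strength models: fg gamma(0.66, rate 8.40), bg gamma(1.00, rate 20.01)
calibration: a=0.000 b=1.000 c=2431.01 d=1.35 (286 scores)
held-out separation: AUC 1.000 over 318 pairs
predictions: 21 pairs, 7 above the 57% threshold,
  14 below the 15% threshold
```

Seven helices give 21 candidate pairs; exactly the 7 planted ones exceed
the upper decision threshold and all 14 others fall below the lower one —
the bimodal posterior histogram that makes this detector usable for model
building. Step 3 filters the packaged published pair table and builds the
bundle:

```
$ Rscript analysis/03_restraints_bundle.R
top-50 pair table: 39 retained, 11 excluded (indel 5, intrahelical 2, topology_violation 4)
printed distance means over the 39 restraints: 9.3 A (model), 8.2 A (3WO6)
placing 7 helices from 7 confident contacts
bundle written: 630 atoms, stress 17.157
```

The 39/11 split and the per-reason counts match the published table
exactly. Step 5 recovers the planted 8 Å bilayer thinning from the
trajectory within the stated tolerance:

```
$ Rscript analysis/05_membrane_analysis.R
upper leaflet: bulk 38.9 A, minimum 30.3 A (thinning 7.7 A)
lower leaflet: bulk 39.3 A, minimum 30.4 A (thinning 7.6 A)
```

Step 4 reproduces the published distance/RMSD tables when the deposited
coordinate files (the YidC TM-region model and the two BhYidC2 crystal
forms, reduced to CA/CB records) are placed under `analysis/pdb/`; the
script header contains the one-line fetch-and-reduce recipe. Without
them it demonstrates the same geometry operations on the synthetic
bundle.

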