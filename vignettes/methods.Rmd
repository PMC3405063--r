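---
title: "Predicting carbohydrate-binding sites from interacting-atom density maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting carbohydrate-binding sites from interacting-atom density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Non-covalent protein–carbohydrate recognition is driven by hydrogen
bonding between sugar hydroxyls and protein polar groups, and by stacking
of the sugar ring against aromatic side chains. The geometry is diverse:
shallow lectin platforms, deep enzyme crevices, antibody combining sites.
`glycosurf` predicts where on a protein surface a carbohydrate is likely
to bind, given only the structure.

The core idea is to describe each solvent-exposed protein atom by the
*expected spatial distribution of interacting atoms around it*, learned
from a database of known structures:

1. **Atom typing.** Protein heavy atoms are grouped into 30 chemical
   classes (backbone NH, carbonyl C, aromatic CH, hydroxyl O, ...);
   carbohydrate atoms into 5 classes (ring O, ring C, hydroxyl O,
   exocyclic C, N-acetyl N); water is its own class. Each class carries a
   van der Waals radius used for surface and occupancy calculations.
2. **Interacting-atom pair database.** For every surface atom (the
   *center*), every non-covalently contacting typed atom within 5 Å whose
   type pair passes a chemical admissibility filter contributes one pair,
   recorded as a displacement in the center atom's local covalent frame.
   The filter encodes that aliphatic carbons do not hydrogen-bond to
   polar oxygens/nitrogens; everything else (C–C, polar–polar,
   polar–aromatic, sulfur with anything) is admissible.
3. **Density templates and PDMs.** Pair displacements are histogrammed
   per (center type, partner type) on a 1 Å grid over `[-5, 5]^3`,
   Gaussian-smoothed and normalised by pair count. Projecting each
   surface atom's templates through its local frame onto a common global
   grid yields the query's 36-channel probability density map (PDM). All
   pairs contributed by the query itself are excluded
   (*leave-query-out*), so the encoding never sees its own answer.
4. **37 attributes per atom.** For atom *i* and channel *j*, the raw sum
   `S[i, j]` adds PDM values over grid points within 5 Å, weighted by
   `1 - r/5`; neighbour aggregation produces
   `A[i, j] = sum over surface atoms k within 5 Å of w(d) S[k, j]` with
   `w(d) = 1/(1+d)`. Attribute 37 is the fraction of a 10 Å sphere not
   occupied by protein van der Waals volume — low in concave pockets.
   All 37 are rescaled to `[0, 1]` by clamp-and-interpolate between
   corpus-level bounds: the medians over training proteins of the
   per-protein minima and maxima.
5. **One classifier per atom type.** Three families are supported: a
   37–76–1 feed-forward network trained by plain back-propagation
   (learning rate 0.01, momentum 0.1, mean-absolute-error convergence
   stop), a radial-kernel SVM with grid-searched cost/gamma, and a bagged
   ensemble of 20 resilient-propagation networks, each bag holding every
   positive case plus 1.5 times as many sampled negatives, with the
   stopping iteration chosen by validation MCC (checked every 10
   iterations, at most 1000). Single models train on all positives plus
   twice as many sampled negatives.
6. **Confidence, patches, residues.** Validation outputs are binned
   (width 0.1) and each bin's true-positive fraction becomes the
   confidence level, making different atom types comparable. Atoms with
   confidence above 0.5 seed patches, collecting surface atoms above 0.1
   within 5 Å; seeds within 10 Å of one another merge transitively. A
   residue is predicted to bind when strictly more than 30% of its
   surface atoms fall inside a patch; ground truth applies the same rule
   to atoms within 5 Å of the ligand, with SASA computed on the apo
   protein.

A positive training case is a surface atom within 5 Å of any sugar atom;
atoms contacting only the aglycone (the non-sugar part of a
glycoconjugate) are negatives. Cross-validation splits *proteins*, never
atoms, into 10 folds of 80% train / 10% validation / 10% test, so
near-duplicate spatial neighbours cannot leak across folds.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| contact / summation / member radius | 5 Å | every contact-scale cutoff of the method |
| geometry sphere, patch merge radius | 10 Å | concavity probe; seed merging |
| contact-filter threshold | −0.1 | pair admissibility (scores −1/0 by default) |
| template spacing / smoothing σ | 1 Å / 1 Å | density-map resolution |
| SASA probe / points | 1.4 Å / 1920 | Shrake–Rupley sampling |
| hidden nodes / lr / momentum | 76 / 0.01 / 0.1 | network architecture and training |
| bags / bag ratio / single ratio | 20 / 1.5× / 2× | imbalance handling |
| confidence bins / seed / member cut | 0.1 / 0.5 / 0.1 | calibration and clustering |
| residue rule | > 30% | atom patch to residue conversion |

All of these live in one configuration list (`default_config()`); model
bundles embed a hash of it and refuse to predict against features built
under a different configuration.

### Choices the source leaves open

* **Distance weights.** The summation and aggregation weights are not
  fully specified upstream; the package uses `1 - r/5` (linear decay to
  the cutoff) and `1/(1 + d)` (inverse-distance), both explicit
  configuration entries. The middle branch of the attribute rescaling is
  linear interpolation, the natural completion of its 0/1 clamps.
* **Contact filter.** Only the admissibility principle is stated, not
  the score matrix; the default matrix scores admissible pairs −1 and
  forbidden pairs 0 against a −0.1 threshold, and can be replaced
  wholesale.
* **Patch merging.** Any two seeds within 10 Å already form a merging
  subset, so "merge subsets whose pairwise distances are within 10 Å"
  reduces to connected components of the 10 Å seed graph; merged patches
  union their member sets.
* **PDM normalisation.** Templates are normalised per pair count, so a
  heavily-populated type pair does not dominate by corpus frequency
  alone; the absolute scale is absorbed by the attribute rescaling.

## Numerical choices

* **SASA.** Shrake–Rupley sampling with 1920 antipodally-paired
  golden-spiral points per atom. The paired set halves directional bias;
  at this density per-atom SASA varies by less than 1% under rigid
  rotation, which the package treats as the acceptable determinism bar.
  A plain 960-point set misses that bar (~2%).
* **Geometry attribute.** Occupancy is evaluated on a fixed 0.5 Å voxel
  grid; at 1 Å the estimate deviates from a continuum Monte-Carlo
  reference by ~0.02, at 0.5 Å by well under 0.01.
* **Back-propagation.** Gradients are summed over the batch (the
  aggregate of per-pattern updates, so the stated per-pattern learning
  rate keeps its meaning). The convergence stop (|ΔMAE| < 1e-4 over 10
  iterations) arms only after 100 iterations: networks can sit on a flat
  error stretch before learning starts, and stopping there yields a
  constant predictor.
* **Resilient propagation.** Standard Rprop⁻ (η⁺ 1.2, η⁻ 0.5, step
  bounds 1e-6..50). Iteration scanning stops early once validation MCC
  reaches 1 (the earliest-best selection cannot change after that) or
  once the training error plateaus.
* **Confidence shrinkage.** With desk-scale validation sets, an output
  bin may hold one or two cases; its raw TP fraction is then 0 or 1 on no
  evidence. Bins are therefore shrunk toward the validation base rate
  with a pseudo-count of 2 (configurable; 0 recovers the raw fraction).
  Empty bins are filled by linear interpolation between non-empty
  neighbours.
* **Degenerate inputs.** Attributes with no spread anywhere (an
  interacting type absent from the corpus) rescale as a 0/1 step; a
  one-class validation set yields threshold 0.5 with a warning; a seed
  set of size zero is a valid "no site predicted" outcome.
* **Local frames.** Built from an atom, its first bonded neighbour and a
  second reference (another neighbour, a neighbour's neighbour, or the
  nearest atom within bonding-plus-slack range), right-handed and
  equivariant under rigid motion; a fixed fallback axis is used only for
  a genuinely collinear environment.

## What the synthetic generator does and does not emulate

`generate_toy_complex()` builds a pseudo-protein of three concentric
residue shells (about 55 residues, 350–460 atoms) with a cylindrical
pocket carved along one axis and a six- (or five-) membered sugar ring
placed inside. Pocket-lining residues are drawn from aromatic
(Trp/Tyr), hydrogen-bond-donor (Asn/Ser/Lys) and aliphatic (Val/Ala/Leu)
classes at configurable fractions; the background surface uses a mixed
composition so every atom type occurs in both classes. Residues reuse
real residue and atom names, so the chemical typing, bond inference and
ring detection run unchanged, and the output parses from PDB text.
Protein atoms get independent Gaussian coordinate noise (0.15 Å); the
sugar is jittered as a rigid body so its ring topology survives
distance-based bond inference.

The generator reproduces the *geometric and compositional* signals the
method relies on — concave pockets, aromatic/donor lining, sugar contact
distances, aglycone decoys — at an easy-geometry setting: deep pockets,
strong lining contrast, low noise. It does **not** emulate real side-chain
rotamer statistics, crystallographic water networks, multi-site binding,
shallow or convex sites, or sequence-level redundancy between corpus
members. Passing the recovery checks therefore demonstrates that the
pipeline's machinery recovers planted signal under favourable conditions;
it does not certify real-data accuracy, where the published regime for
this class of method is residue-level MCC around 0.45–0.5.

The study conditions used by the acceptance checks are 30 deep-pocket
complexes under one fixed corpus seed, split 20 train / 5 validation /
5 test. At these sizes featurization of the corpus takes a few minutes
and training all three families a further one to two minutes on one CPU.
The single un-bagged network is the most seed-sensitive family — its
held-out MCC moves by roughly ±0.08 across training seeds — which is the
expected behaviour that bagging was introduced to damp.

## Known limitations

* The attribute set carries no evolutionary or secondary-structure
  information; backbone-atom predictors are accordingly the weakest.
* Sites that are deeply buried (no apo surface) or flat/convex are
  outside the patch model's reach.
* Covalently linked glycans are excluded from the ligand set only when a
  LINK record names the protein attachment; structures missing that
  record will treat a glycosylation site as a non-covalent ligand.
* The contact-filter matrix is a principled reconstruction, not fitted
  data; its entries are a configuration-level fidelity knob.
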