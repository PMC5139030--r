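---
title: "Single-model quality assessment with dbnQA: model, features and design"
author: "dbnQA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-model quality assessment with dbnQA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbnQA)
```

## The estimation problem

Given a single candidate structure (a *decoy*) for a protein target,
dbnQA predicts its GDT-TS score against the native structure — a
quality value in [0, 1] — without seeing the native and without
comparing against other decoys. The predictor is a deep belief network
(DBN) over a fixed vector of normalized features. This vignette is the
package's account of the model, its assumptions, the tunable
parameters, the numerical choices, and what the simulated validation
does and does not demonstrate.

## Feature model

A model of length $L$ is summarized by 16 features, each in $[0,1]$,
each oriented so that larger is better.

**Structural features (computed here).** Solvent accessible surface
area comes from a Shrake–Rupley sphere-point calculation (probe 1.4 Å;
van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80 Å; a 2.0 Å
pseudo-atom per residue for Cα-only models, flagged as approximate).
Relative accessibility divides a residue's area by a fixed theoretical
maximum-ASA reference, and residues at relative accessibility ≥ 0.25
count as *exposed* — a common convention; the threshold is a package
default, not a literature constant, and is exposed in code. From this:

* `SU` — area of exposed nonpolar residues (A,V,L,I,P,F,M,W,G,C) over
  total area. Well-folded models bury hydrophobics, so smaller raw
  exposure means better models; the feature is used as-is and the
  network learns the orientation.
* `EM` — mass fraction of exposed residues (average residue masses,
  Da).
* `ES` — total area over the summed per-residue reference maxima,
  clamped.
* `SA` — fraction of residues whose exposed/buried state matches a
  sequence-based two-state prediction (`e`/`b` string).
* `SS`, `SP` — agreement between the model's three-state secondary
  structure and a sequence-based prediction: `SS` is the Q3 fraction
  over all positions; `SP` restricts to positions predicted helix or
  strand (neutral 0.5 when there are none). The model-side assignment
  uses deterministic dihedral windows — helix for $\varphi \in
  (-100,-30)$, $\psi \in (-80,-5)$ in runs of ≥ 4; strand for $\varphi
  \in (-170,-50)$, $\psi \in (80,180] \cup (-180,-170)$ in runs of ≥ 2;
  else coil — rather than a hydrogen-bond (DSSP-style) assignment,
  keeping the package dependency-free. A precomputed DSSP string can be
  supplied instead and is reduced 8→3 as {H,G,I}→H, {E,B}→E, else C.
* `EC` — mean pairwise Cα distance divided by $3.8(L-1)$ Å, the span
  of a fully extended chain of virtual Cα–Cα bonds. Among several
  readings of "pairwise distance over the maximum distance (3.8)" we
  fixed the mean-pairwise / extended-span reading: it is bounded,
  dimensionless, and monotone in how extended the model is.

**External scores (consumed).** Nine established potentials and QA
scores enter as raw values from a TSV. Three have published
length-normalized linear maps:
$$\mathrm{DFIRE2}: \frac{-P}{1.971\,L},\qquad
  \mathrm{RWplus}: \frac{-P}{232.6\,L},\qquad
  \mathrm{RF}: \frac{700-P}{1000+0.4823\,L},$$
clamped to $[0,1]$ at both ends. Dope, GOAP and OPUS have no published
constants; they use the same $-P/(cL)$ form with calibration-knob
defaults $c_{\mathrm{dope}}=2$, $c_{\mathrm{goap}}=20$,
$c_{\mathrm{opus}}=2$, configurable per dataset. ProQ2, ModelEvaluator
and Qprob are themselves quality predictions on $[0,1]$ and pass
through clamped. Any absent feature — a failed tool, a missing column —
is imputed at the neutral value 0.5; missingness is never fatal, and
provenance (`computed` / `external` / `imputed`) is recorded per entry.

The full set is `full16`; `deepqa9` (SU, Dope, GOAP, OPUS, RWplus,
ModelEvaluator, SP, EC, Qprob) is the reduced selection that trades
little accuracy for model complexity.

## The network and its training

The regressor stacks two restricted Boltzmann machines —
input→$N_1$→$N_2$, defaults $N_1=20$, $N_2=10$ — with a logistic output
node, so the feed-forward pass applies the logistic function three
times and predictions always lie in $(0,1)$.

*Pretraining.* Each RBM is trained by one-step contrastive divergence
(CD-1). Visible units are real-valued scores in $[0,1]$; hidden
probabilities are logistic, hidden *states* are Bernoulli samples
during CD-1, and the second RBM trains on the first layer's hidden
*probabilities* (the lower-variance choice). The update is
$v \leftarrow \nu v + \varepsilon(\nabla - \omega W)$ with learning
rate $\varepsilon = 10^{-4}$, weight cost $\omega = 0.007$, and
momentum $\nu$ = 0.5 for the first 5 epochs then 0.9. Defaults: 100
epochs, minibatch 100, initial weights $N(0, 0.01^2)$, all seeded —
training is bit-reproducible.

*Fine-tuning.* All weights and biases are then optimized jointly by
BFGS on the full-batch mean squared error, with analytic
backpropagation gradients (verified against central finite differences
to relative error < 1e-5). The optimizer runs in bounded chunks so the
recorded objective trace is non-increasing; it stops at relative
improvement below `bfgsTol` (1e-9) or `bfgsMaxIter` (1000) iterations.
Cross-validation shuffles rows with the config seed into $k$ folds
whose sizes differ by at most one and reports per-fold and mean MAE.

## Structure comparison scores

True quality is measured by GDT-TS: for thresholds 1, 2, 4, 8 Å, the
largest fraction of Cα atoms superposable within the threshold, averaged.
Finding that largest subset is a search problem; dbnQA uses an
LGA-style iterative heuristic — seed superpositions from consecutive
windows and the full chain, re-select residues within the (relaxed)
cutoff to a fixed point, refine with k-closest re-superposition sweeps
and worst-residue trimming, and for chains of ≤ 12 residues also seed
from every residue triple. On random toy decoys (L ≤ 10) the heuristic
matches an exhaustive subset-superposition oracle exactly in our test
battery; for long chains a lighter seeding tier keeps per-pair cost
around tens of milliseconds. It is an approximation, not the LGA
program. TM-score uses the same search with
$d_0 = 1.24(L-15)^{1/3} - 1.8$, floored at 0.5 Å so toy chains stay
defined; RMSD is the plain Kabsch value. Evaluation statistics follow
the field's conventions: per-target Pearson r (undefined for
zero-variance pools, which are excluded from averages), per-target loss
(best-true minus true-of-top-ranked, prediction ties broken by model
id), best-of-top-k TM/RMSD, Z-score sums with the population standard
deviation (degenerate pools contribute 0), and a Wilcoxon signed-rank
test that drops zero differences, midranks ties, enumerates all $2^n$
sign assignments exactly for $n \le 12$ and otherwise uses the normal
approximation with tie and continuity corrections.

## The simulator: what it emulates, what it does not

`generateNative()` builds ideal-geometry N/Cα/C/O backbones from
template dihedrals (helix −57/−47, strand −120/120, coil sampled
outside both windows, or mixed thirds) by natural-extension-reference-
frame construction with standard bond lengths and angles.
`generateDecoys()` perturbs every atom with i.i.d. Gaussian noise at
σ ∈ {0.5, 1, 2, 4, 8} Å — a grid spanning GDT-TS ≈ 1 down to ≈ 0.2 —
then re-orients each decoy rigidly at random. `generateExternalScores()`
emits raw-scale synthetic score columns that normalize back to quality
plus Gaussian noise (default sd 0.05), emulating the accuracy of real
energy scores; the pool's "predicted" SS/SA strings are taken from the
native, emulating accurate sequence-based predictors.
`generateFeatureDataset()` draws features uniformly and sets the target
to a logistic ramp in two designated columns plus noise, clamped to
[0.01, 0.99] to keep the output sigmoid off its saturated tails.

These simulations validate the pipeline's mechanics — feature
computation, normalization, imputation, training, ranking — under known
ground truth. They do not reproduce real decoy physics: Gaussian
coordinate noise has no side chains, no compact misfolds, no
template-based error correlation, and the synthetic external scores are
honest by construction. Passing the simulated benchmarks (held-out
Pearson r ≈ 0.98 in cross-validation at n = 2000; pool ranking r ≈ 1.0,
loss ≈ 0.02 at L = 30 with 100 decoys) therefore demonstrates
correctness of the machinery, not CASP-level accuracy; accuracy on real
decoys depends on training data this package deliberately does not
ship. A related caveat: a network trained on the abstract uniform
feature dataset does not transfer to structure-derived feature
matrices — train on features of the same provenance you predict on.

## Numerical choices and degenerate inputs

* Sphere points are a deterministic Fibonacci lattice expressed in a
  body-fixed principal-axes frame (axis signs fixed by third moments,
  dominant axis at the lattice pole): SASA is bit-stable across runs,
  exactly invariant under rigid motions, and the lattice pole aligns
  with typical occlusion boundaries, reducing quantization error. 92
  points stay within ~1% of a 960-point reference on our fixtures.
* Kabsch superposition excludes reflections (det = +1 enforced via the
  SVD sign); superposing fewer than 3 points is an error.
* Chain termini have undefined φ or ψ and are assigned coil; models
  missing backbone atoms fall back to an all-coil string with a
  warning rather than failing.
* Residues without a Cα are rejected at parse time so feature vectors
  always have length $L$; models whose length disagrees with the
  target sequence are rejected rather than aligned (full-length decoy
  convention). Alternate locations resolve to the highest-occupancy
  conformer; only the first chain of the first MODEL block is read.
* Model files store weights with 17 significant digits so a saved and
  reloaded network predicts bit-identically.
* Every stochastic step — weight init, CD-1 sampling, fold shuffling,
  simulation — derives from an explicit integer seed.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on simulated
data at desk scale, chosen to exercise every code path while keeping a
full run in minutes: cross-validation on 2000 × 16 features; decoy
benchmarks on 30-residue chains with 120 training and 100 test decoys;
oracle comparisons on 7–10-residue toys where exhaustive enumeration is
feasible. Larger problems change runtime, not code paths: feature
extraction is O(atoms²) per model in the SASA step and the GDT search
is the dominant evaluation cost.

## Known limitations

Single-chain, single-domain models only; no insertion codes,
heteroatoms or mmCIF. Secondary structure is dihedral-window based, not
hydrogen-bond based. The GDT heuristic can in principle undershoot the
true optimum on long chains. The nine external scores are inputs, not
re-implementations — without a score table the network sees 0.5 for
all of them and must rank on structural features alone. No residue-level
quality prediction is offered beyond the published local-to-global
conversion formula.
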