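# dbnQA

Single-model protein quality assessment with a deep belief network.

## The problem

Protein structure prediction pipelines generate large pools of candidate
models ("decoys") for a target sequence, most of them poor. Picking the
best model without knowing the native structure is the model *quality
assessment* (QA) problem. Consensus methods rank a model by its
similarity to the rest of the pool and fail when good models are rare;
*single-model* methods instead predict a model's quality from that model
alone. dbnQA is a single-model method for structural biologists and
method developers: given one model, it predicts the model's GDT-TS
(Global Distance Test Total Score) against the unseen native, a number
in [0, 1].

## The method

Each model is described by 16 features, all normalized to [0, 1]:

* **7 structural / physio-chemical features** computed by the package:
  surface score SU (exposed-nonpolar area fraction), exposed mass EM,
  exposed surface ES, solvent-accessibility agreement SA, secondary
  structure similarity SS and penalty SP (agreement between the model's
  dihedral-derived secondary structure and a sequence-based prediction),
  and Euclidean compactness EC (mean pairwise Cα distance over the
  extended-chain span 3.8·(L−1) Å).
* **9 external scores** consumed from a score table: DFIRE2, RWplus and
  RF_CB_SRS_OD are length-normalized by

      Norm_DFIRE2 = −P / (1.971·L)
      Norm_RWplus = −P / (232.6·L)
      Norm_RF     = (700 − P) / (1000 + 0.4823·L)

  clamped to [0, 1]; Dope/GOAP/OPUS use configurable −P/(c·L) maps; and
  ProQ2, ModelEvaluator and Qprob are already on [0, 1]. Any feature
  that cannot be computed is imputed at the neutral value 0.5.

The regressor is a deep belief network: two stacked restricted
Boltzmann machines (default 20 and 10 hidden units) pretrained
layer-wise with one-step contrastive divergence (learning rate 1e-4,
weight cost 0.007, momentum 0.5 rising to 0.9), topped by a logistic
output node, and fine-tuned end-to-end by BFGS on the mean squared
error. A reduced 9-feature set (`deepqa9`) is available alongside the
full 16.

The package also implements the evaluation side of the QA literature:
GDT-TS, TM-score and Cα RMSD between structures (Kabsch superposition
with an LGA-style iterative large-subset search), per-target Pearson
correlation and loss, best-of-top-k selection, summed selection
Z-scores, exact/approximate Wilcoxon signed-rank tests, and the
local-to-global conversion `Global = (1/L) Σ 1/(1+(l_i/5)²)`. A
simulator builds ideal-geometry natives, noise-graded decoy pools and
feature datasets with known structure, so everything is testable with
no downloads.

## Worked example

Train on simulated decoy pools and rank an unseen pool:

```r
library(dbnQA)
bench <- runSimulatedBenchmark(seed = 1)
round(bench$pearson, 3)   # correlation of predicted vs true GDT-TS
round(bench$loss, 3)      # GDT-TS given up by trusting the top pick
```

This simulates three training targets (chains of 30 residues, 8 decoys
at each noise level 0.5/1/2/4/8 Å, 120 models in all), computes their
feature matrices and true GDT-TS, trains the network, then scores a
fresh 100-decoy pool. It prints:

```
held-out pool Pearson r: 0.998
per-target loss: 0.017
```

so predicted quality tracks true quality almost perfectly on this pool,
and the model ranked first is within 0.017 GDT-TS of the best decoy
available. The three top-ranked decoys come from the lowest-noise tier,
with predictions close to their true scores:

```
          predicted  true
d_s0.5_05     0.970 0.958
d_s0.5_12     0.968 0.967
d_s0.5_04     0.965 0.942
```

The same workflow is available over files — `cmdSimulate()`,
`cmdTrain()`, `cmdPredict()`, `cmdEvaluate()` in R, or from a shell via
the wrapper:

```sh
Rscript inst/cli/qa.R simulate --preset pool -o work/target1 --seed 1
Rscript inst/cli/qa.R predict --pool work/target1/pool \
    --fasta work/target1/target.fasta --scores work/target1/scores.tsv \
    --model work/model/model.json -o work/ranked.tsv
```

`predict` writes one row per model (id, the 16 features, predicted
GDT-TS), sorted best-first.

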