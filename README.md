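# erpred

Sequence-only prediction of endoplasmic reticulum resident proteins
(ERRPs).

Most proteins found in the ER at any moment are secretory cargo in
transit; the ER's own residents are retained or retrieved, classically by
short signals — the C-terminal KDEL class (consensus
`[KRHQSA]-[DENQ]-E-L`) and the dilysine motifs (`KKxx`, `KxKxx`, ...).
But roughly half of curated ERRPs carry no recognizable retention signal,
so `erpred` predicts residence from the full sequence instead: a protein
is encoded as a fixed-length composition vector and classified by a
cost-sensitive support vector machine. The package is aimed at anyone who
needs to triage candidate ER proteins from FASTA input — plus the
benchmarking machinery to evaluate such predictors honestly.

## What is inside

* **Six feature encodings** — amino acid composition
  (Acomp(i) = 100 · n_i/L, dim 20), dipeptide composition (dim 400),
  Chou's type-1 pseudo amino acid composition (dim 20 + λ), and three
  split compositions: N-terminal 25 | rest, C-terminal 25 | rest
  (dim 40), and the three-part split N-terminal 25 | C-terminal 25 |
  middle (dim 60), which resolves terminal sorting signals that
  whole-sequence composition dilutes.
* **Classifier** — RBF-kernel SVM with a class-imbalance cost ratio
  (`n_neg/n_pos` by default) and a user-selectable decision threshold.
* **Evaluation** — leave-one-out cross-validation with pooled confusion
  counts; sensitivity, specificity, accuracy (percent), Matthews
  correlation coefficient; ROC curve and trapezoidal AUC (equal to the
  pairwise rank statistic).
* **Motif tools** — a PROSITE-pattern scanner (classes, exclusions,
  wildcards, repetition, anchors) with a bundled ER-retention signal
  catalogue and per-dataset signal census.
* **Enrichment profiling** — per-residue compositional difference
  D = (d1 − d2)/d2 between a query and a background set, with bootstrap
  significance.
* **Synthetic data** — a seeded generator planting the compositional bias
  (F, Y, W, D, E, V, L up; R down) and the C-terminal retention signal
  that real ERRP sets exhibit, with exact ground truth for every record.
* **CLI** — `inst/cli/erpred.R` wires it all together for shell use
  (simulate / train / predict / evaluate / scan / profile), with no batch
  size cap.

## Worked example

```r
library(erpred)

## a labelled benchmark with planted structure: compositional bias in the
## positives and a C-terminal retention signal in about half of them
sim <- generate_dataset(synth_config(n_pos = 40, n_neg = 400,
    enrichment_bias = c(F = 2, Y = 1.5, W = 1.5, D = 1.5, E = 1.5,
                        V = 1.5, L = 1.5, R = 0.5), seed = 42))
pos <- sim[sim$label == "positive", ]

signal_census(pos)$count        # 17  (of 40 positives carry the signal)

loocv(sim, svm_config("SAAC3"))
#> <erpred_eval> pooled leave-one-out performance
#>   TP=26 TN=400 FP=0 FN=14
#>   sensitivity 65.00%  specificity 100.00%  accuracy 96.82%
#>   MCC 0.79  AUC 0.99

prof <- enrichment_test(pos, sim[sim$label == "negative", ],
                        iterations = 2000, seed = 1)
prof[prof$residue %in% c("F", "R"), c("residue", "d1", "d2", "D", "p_value")]
#>    residue     d1     d2      D p_value
#> 5        F 0.0876 0.0494  0.775   0.001
#> 15       R 0.0218 0.0485 -0.550   0.001
```

Reading the output: 17 of the 40 positives carry a planted
`[KRHQSA]-[DENQ]-E-L` tail — a signal census alone would miss the rest —
while the leave-one-out SVM on three-part split composition recovers 26
of them at perfect specificity (pooled accuracy 96.82%, MCC 0.79,
AUC 0.99). The enrichment profile recovers the planted directions:
phenylalanine enriched (D = +0.78), arginine depleted (D = −0.55), both
at the bootstrap resolution floor of p = 0.001.

The same run from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "erpred.R", package = "erpred"))')
Rscript $CLI simulate --out sim.fasta --truth truth.tsv --seed 42
# split sim.fasta into pos.fasta / neg.fasta using the labels in truth.tsv
Rscript $CLI train --pos pos.fasta --neg neg.fasta --model m.rds
Rscript $CLI predict --model m.rds --query sim.fasta --out pred.tsv
Rscript $CLI scan --query sim.fasta --out hits.tsv
```

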