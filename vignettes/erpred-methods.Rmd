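---
title: "Predicting ER-resident proteins from sequence composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ER-resident proteins from sequence composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The endoplasmic reticulum holds two populations of proteins at any moment:
its own residents (ERRPs) — chaperones, oxidoreductases, glycosylation
enzymes — and secretory cargo merely passing through. Classical retention
is explained by short retrieval signals: the C-terminal KDEL class
(consensus `[KRHQSA]-[DENQ]-E-L`) on luminal residents and the dilysine
motifs (KKxx and variants) on type-I membrane proteins. But roughly half
of curated ERRPs carry no recognizable retention signal, so a useful
predictor cannot be a motif grep: it has to read a weaker, distributed
compositional signature of residence from the whole sequence. `erpred`
implements such a predictor: composition-based feature encodings of a
protein sequence feeding a cost-sensitive support vector machine, with
leave-one-out evaluation, motif census tooling, enrichment profiling, and
a synthetic-data generator that makes every stage testable without any
database download.

## Feature encodings

All encodings order residues alphabetically by one-letter code
(`A, C, D, ..., Y`) and require validated sequences: the 20 standard amino
acids only, length strictly greater than 50 residues (shorter SwissProt
entries are mostly fragments). Non-standard residues (B, J, O, U, X, Z)
make composition percentages ill-defined; the validator rejects them by
default (`policy = "strict"`) or removes them (`policy = "strip"`).

* **AAC** (dim 20): per-residue percentage,
  $\mathrm{Acomp}(i) = 100\, n_i / L$.
* **Dipeptide** (dim 400): percentages of ordered residue pairs over
  sliding windows of width 2 and step 1; denominator $L - 1$.
* **Pseudo amino acid composition** (dim $20 + \lambda$): Chou's type-1
  construction. Sequence-order correlation factors
  $\tau_j = \frac{1}{L-j}\sum_i \Theta(R_i, R_{i+j})$ use
  $\Theta(a,b)$ = mean squared difference of standardized hydrophobicity,
  hydrophilicity (Hopp–Woods) and side-chain mass. Components are
  $p_u = f_u / (1 + w\sum_j \tau_j)$ and
  $p_{20+j} = w\,\tau_j / (1 + w\sum_j \tau_j)$, so the vector sums to 1.
  Defaults $\lambda = 1$, $w = 0.05$. The three property scales are
  standardized to zero mean and unit population standard deviation over
  the 20 residues before use; the scale values are the ones distributed
  with the standard PseAAC tooling and are printed in the source
  (`pseaac_properties()`).
* **Split compositions**: per-segment AAC of non-overlapping fragments.
  The two-part schemes take the 25 N-terminal (or C-terminal) residues
  versus the remainder (dim 40 each); the three-part scheme takes 25
  N-terminal, 25 C-terminal and the middle (dim 60). Blocks are
  concatenated N-terminal | C-terminal | middle; a different consistent
  order would be classifier-equivalent, but this one is frozen for file
  compatibility. The split size 25 is a parameter (`n`); three-part
  encoding needs $L \ge 2n + 1$, which the >50-residue rule guarantees at
  the default.

Splitting matters because sorting signals are positional: a 4-residue
C-terminal motif is invisible in the composition of a 600-residue
sequence (0.7% of residues) but prominent in a 25-residue terminal block
(16%).

## Classifier

`train_model()` wraps a support vector machine (libsvm via e1071) with:

* **RBF kernel**, width `gamma = 1/(dim × mean feature variance)`
  computed on the training matrix. Composition features are left on their
  natural scale (percentages; unit scale for PseAAC) and are deliberately
  not standardized, so the variance-blind `1/dim` convention would make
  the kernel matrix nearly the identity — every example a support vector
  and pure memorization. The variance-aware width is the scale-free
  analogue that behaves identically across all six encodings.
* **Cost** `C = 10` by default. `svm_config(tune = TRUE)` grid-searches
  `C` and `gamma` by internal 3-fold cross-validation on the training
  data only; it is off by default because nesting a grid search inside
  every leave-one-out fold costs hours for minutes of benefit at these
  data sizes. Whatever is used is recorded in the model object and its
  saved file.
* **Class-imbalance cost ratio**: errors on the positive class are
  weighted `n_neg/n_pos` (10 with the default 10:1 design), mirroring
  cost-factor handling of skewed training sets. Configurable.
* **Decision threshold** 0 on the margin score; a score exactly at the
  threshold is called positive. The threshold is exposed everywhere
  (`predict_model`, the CLI `--threshold`) to trade sensitivity against
  specificity; raw scores are always returned for ROC work.

## Evaluation

Leave-one-out cross-validation (`loocv()`) holds out each record once and
pools the held-out predictions into a single confusion table — with
test sets of size one, pooling is the only well-defined aggregate. From
the pooled counts:

$$\mathrm{Sn} = 100\,\frac{TP}{TP+FN},\quad
  \mathrm{Sp} = 100\,\frac{TN}{TN+FP},\quad
  \mathrm{Acc} = 100\,\frac{TP+TN}{N},$$
$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.$$

Percentages with a zero denominator are reported `NA`; an MCC whose
denominator vanishes is 0 by the usual convention. The ROC curve sweeps
all distinct score thresholds; AUC is the trapezoid area, which equals
the pairwise rank statistic (ties counted one half) — the test suite
asserts that identity against an independent brute-force oracle.

Two numerical choices make LOOCV affordable without changing its result.
Data-dependent hyperparameters (`gamma`, the cost ratio) are resolved
once on the full dataset and held fixed across folds, so all folds train
the same model family. Removing a non-support-vector from a training set
then leaves the SVM solution unchanged (its Karush–Kuhn–Tucker conditions
still hold), so only support-vector folds are retrained; `exact = FALSE`
disables the shortcut and the suite verifies both paths agree to
machine precision.

## Motif scanning

`compile_pattern()` implements the PROSITE pattern subset needed for
retention signals: classes `[..]`, exclusions `{..}`, wildcard `x`,
repetition `(n)`/`(n,m)`, anchors `<` and `>`. Matching is positional
with backtracking over variable repetitions; all matches are reported,
one per feasible start (overlaps included), with 1-based inclusive
coordinates. The bundled KDEL-class consensus is C-anchored by default —
that is how retention-signal censuses are conventionally computed — and
an unanchored variant is one flag away. The test oracle is an independent
PROSITE-to-regex translation.

## Enrichment profiling

`enrichment_test()` compares pooled residue fractions (all sequences of a
set merged; residue-weighted, not per-sequence averaged) between a query
and a background set. The effect size is the compositional difference
$D = (d_1 - d_2)/d_2$; $D$ is undefined (reported `NA`, flagged) for a
residue absent from the background rather than silently 0. Significance
comes from resampling sequences with replacement within each set (default
10,000 iterations, seedable), with a two-sided add-one-corrected p-value
for $d_1 - d_2$ against 0, so p-values lie in (0, 1] and are reproducible
under a fixed seed. Raw p-values are reported by default; a Bonferroni
option over the 20 residues exists but is off, matching the common
practice of reading per-residue profiles at a nominal level.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the predictor
exploits, with ground truth attached (`truth_table()`):

* positives enriched in F, Y, W, D, E, V, L and depleted in R via ±30%
  multiplicative reweighting of a uniform background — strong enough for
  reliable desk-scale recovery, and uniform because the tests must not
  depend on an external frequency table (a custom background can be
  supplied);
* a C-terminal `[KRHQSA]-[DENQ]-E-L` draw planted in a 66/124 fraction of
  positives (the fraction observed in curated training data); negatives
  optionally carry the signal too (`neg_signal_prob = 1` emulates an
  independent-style negative set selected *for* the signal);
* lengths uniform on [51, 600]; 10:1 negative:positive ratio;
  deterministic under a seed. Unplanted sequences are guaranteed
  signal-free (chance consensus tails are redrawn), so the planted flag is
  exact ground truth for the scanner.

What the generator does **not** emulate: residue frequencies of real
proteomes, homology and redundancy structure, domain architecture, length
distributions of real ERRPs, or signal peptides. Synthetic recovery
therefore demonstrates that the pipeline's machinery is correct and
sensitive to the structure it targets — it does not certify real-data
accuracy, which depends on curated training sequences.

Two properties of this design deserve emphasis because they shape what
the benchmark can show. First, the compositional bias is *global* — every
residue of a positive is drawn from the reweighted distribution — so
whole-sequence AAC is a sufficient statistic for it by construction, and
the split encodings buy nothing for that part of the signal. The
encoding-ordering experiment (split-3 at least as good as AAC) is
therefore run on terminal-signal-only data (`enrichment_bias` empty,
everything else at defaults): there the class difference lives in the
last four residues and the split encoding's advantage is the thing being
measured. Second, percentage compositions discard sequence length, while
the generator's planted bias is per-residue: a likelihood-ratio oracle
using raw counts reaches ~98% accuracy at the default 124 + 1,240 scale,
but classifiers restricted to the method's percentage features and 124
positive examples plateau around 92–94% accuracy (AUC ≈ 0.91). That gap
is a property of the feature class at this sample size, not a defect of
any particular classifier configuration.

## Problem sizes used by the checks

The packaged checks run at the design scale of the curated datasets:
124 positives and 1,240 negatives for leave-one-out evaluation and
enrichment profiling; 10 seeded replicates for the encoding-ordering and
enrichment-direction experiments; 1,000 random sequences (or confusion
tables / score sets) for each oracle-equivalence suite; a reduced
40 + 400 scale for the label-permutation null, where the permuted labels
make nearly every example a support vector and the statistic itself is
scale-free.

## Known limitations

* Real curated ERRP datasets are distributed as accession lists;
  reproducing published censuses and benchmark metrics requires fetching
  those sequences, which the package deliberately does not automate.
* The SVM hyperparameters of the original webserver are unpublished; the
  defaults here are this package's own, recorded in every model file, and
  trained weights will not match any historical deployment.
* PROSITE profile (matrix) entries, k-mers beyond dipeptides, and
  position-specific scoring are out of scope.
* `pseaac` property scales are fixed at the standard three; alternative
  scale sets change the pseudo components and are not currently pluggable.
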