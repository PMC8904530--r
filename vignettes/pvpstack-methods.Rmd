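---
title: "Stacked ensemble prediction of phage virion proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensemble prediction of phage virion proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Phage virion proteins (PVPs) are the structural proteins of the
bacteriophage particle. Given a protein sequence, the task is a binary
call: PVP or not. `pvpstack` approaches it by stacked generalization. The
first level is deliberately broad — thirteen feature descriptors crossed
with ten classifier families — because no single sequence representation is
uniformly informative for structural proteins. The second level is
deliberately narrow: the only thing a baseline contributes upward is its
probability that the sequence is a PVP, and a random-forest meta-model
(mRF) learns which baselines to trust.

The pipeline in order:

1. encode sequences (and optional PSI-BLAST profiles) into 13 fixed-length
   vectors;
2. tune one baseline per (descriptor, algorithm) pair by pooled out-of-fold
   MCC under stratified cross-validation — the full pool is
   10 algorithms × 13 descriptors = 130 members;
3. collect each member's out-of-fold probability into the probabilistic
   feature matrix PF (one column per member); thresholding strictly above
   0.5 gives the class features CF, and PCF is their concatenation;
4. rank meta-feature columns with a gradient-boosted tree classifier (gain
   importance), sweep the top-k subsets for k = 5, 10, ..., 100, and keep
   the subset whose tuned meta random forest maximises cross-validated MCC;
5. fit the meta random forest on the chosen columns; predictions above 0.5
   (strict) are labeled PVP.

The key statistical assumption of stacking is that the meta-features used
for training must be *out-of-fold*: a sample's PF entry must come from a
member refit without that sample, otherwise the meta-model learns each
baseline's training error rather than its generalization. `generate_pf()`
enforces this by refitting every member configuration per fold;
an `"in-sample"` mode exists only for protocol comparisons and is
documented as leaking.

## Descriptors: dimensions and conventions

| descriptor | dims | notes |
|---|---|---|
| AAC | 20 | residue frequencies, alphabetical order |
| AAI | 11 | mean of 11 min–max-normalised AAindex-style scales |
| APAAC | 20 + 2λ | amphiphilic pseudo composition, λ = 1 by default |
| CTDC / CTDT / CTDD | 39 / 39 / 195 | 13 properties × 3 groups |
| DDE | 400 | deviation of dipeptide counts from codon-usage expectation |
| DPC | 400 | dipeptide frequencies |
| EAAC | 20 | sliding-window AAC, averaged over windows |
| PAAC | 20 + λ | classic pseudo composition |
| PSSM_AAC / PSSM_DP / PSSM_COM | 20 / 400 / 400 | logistic-squashed profile statistics |

Conventions that were genuinely open and the choices made:

* **CTD property set.** A 39-dimensional composition block forces 13
  property partitions; we use the widely adopted iFeature grouping (seven
  hydrophobicity scales plus van der Waals volume, polarity, polarizability,
  charge, secondary structure, solvent accessibility). Transition counts
  pairs crossing each group boundary in either direction over L − 1
  adjacent pairs; distribution reports, per group, the position of the
  ⌈q·n⌉-th occurrence (q ∈ {first, 25%, 50%, 75%, 100%}) as 100·pos/L, with
  five zeros for an absent group. The transition block is the 39-D one and
  the distribution block the 195-D one, the standard semantics.
* **λ = 1, w = 0.05 for PAAC/APAAC.** The printed dimensions (21 and 22)
  force λ = 1 since PAAC is 20 + λ and APAAC 20 + 2λ; both remain
  configurable. Property scales are standardised to mean 0 / population
  sd 1 over the 20 residues before use, the classic convention.
* **EAAC aggregation.** The textbook sliding-window EAAC has
  length-dependent output; to keep a fixed 20-vector we average the window
  compositions (window 5 by default, configurable).
* **AAI scales.** Eleven broadly used scales (Kyte–Doolittle hydropathy,
  Hopp–Woods hydrophilicity, side-chain mass, Zamyatnin volume, Grantham
  polarity, isoelectric point, Bhaskaran–Ponnuswamy flexibility, Chothia
  accessible surface, Chou–Fasman helix/sheet/turn). Only the relative
  ordering matters after min–max normalisation; the set is user-overridable
  (`index_set` argument).
* **PSSM squashing.** Profile log-odds are mapped through the logistic
  function before averaging, the common normalisation for PSSM-composition
  descriptors; identity and global min–max transforms are available.
* **Ambiguous residues.** Default policy maps B→D, Z→E, U→C and drops
  other non-standard letters; a strict mode refuses them. This keeps
  real-world FASTA usable while letting tests be exact.

## Baseline families and tuning

All ten families sit behind one fit/probability interface
(`make_classifier()`). Two need probability adapters: the RBF SVM uses
libsvm's built-in Platt-style calibration, and PLS is run as a regression
on {0, 1} targets with predictions clipped to [0, 1]. ET, LR, MLP, RF, SVM
and XGB are tuned by pooled out-of-fold MCC over documented grids
(`default_grids()`); DT, KNN, NB and PLS run at their defaults. Grid
enumeration order is the tie-break order, making tuning deterministic; a
single global seed propagates to fold shuffling and to every stochastic
learner, so pool training is reproducible bit for bit. The shipped grids
are sensible stand-ins (the exact published search ranges are not
available); `reduced_grids = TRUE` collapses each grid to one point for
fast runs and is what the test-suite configurations use.

## Evaluation harness

ACC, Sn, Sp and MCC follow their standard confusion-matrix definitions,
with predicted-positive defined as probability strictly greater than the
threshold (0.5 everywhere). A zero factor in the MCC denominator yields
MCC = 0; an undefined Sn/Sp cannot occur when both classes are present and
is an error otherwise. AUC is the rank-based (Mann–Whitney) statistic with
midrank tie handling, which equals trapezoidal ROC integration — the test
suite asserts that equality against an independent integration oracle.
Cross-validation pools the out-of-fold predictions and computes one metric
set on the pool, rather than averaging per-fold metrics: pooled metrics
are threshold-consistent with an independent test and well defined even
when a fold happens to be single-class in prediction. Reported tables
round to three decimals.

## The synthetic generator

`generate_labeled_sequences()` emulates a two-class protein benchmark with
controllable separability: positives draw residues from a uniform
distribution with `delta` extra mass on each of the `bias_residues`
(renormalised), negatives are uniform, and lengths are uniform on the
configured range. Defaults are the study conditions this package is
validated under: 250/250 sequences, lengths 50–500, bias +0.15 on
{C, H, K}. A `dipeptide` bias mode plants first-order signal (transitions
into the biased set are favoured only after a biased residue) that only
order-aware descriptors can see. `generate_synthetic_pssm()` mimics
integer log-odds profiles: rounded Gaussian noise (sd 2) plus a
`concentration` shift on the true residue's column.

What this emulates — compositional and first-order class differences,
profile files in the PSI-BLAST ASCII dialect — is enough to exercise every
stage of the pipeline, including the no-signal (delta = 0) regime where an
honest pipeline must report chance-level MCC on an independent split.
What it does not emulate: homology structure between sequences, domain
architecture, length–class correlation, or realistic profile covariance.
Passing tests on this generator therefore demonstrate correctness of the
machinery and sane statistical behaviour, not field performance on real
phage proteomes.

## Problem sizes used by the tests and the acceptance script

The suite exercises the full 130-member pool on a 60-sequence set with
single-point grids and 3 folds (cardinality and meta-feature dimensions),
the stacking-vs-baseline property on 200 sequences at delta = 0.15 with a
5-descriptor × 10-algorithm pool and 10 folds, the null property on an
independent 100-sequence split at delta = 0, and the subset-sweep recovery
on 200 × 130 meta-feature matrices with 5 planted signal columns across
ten seeds. `scripts/acceptance.R` runs the benchmark-sized study
(250/250 train, 63/63 independent) with a 6-descriptor × 10-algorithm
pool. These sizes are the package's chosen demonstration conditions;
every one of them is generated in code at run time.

## Known limitations

* The PLS and SVM probability adapters are calibrated heuristics, not
  native probabilistic models; their PF columns are still bounded and
  monotone in the decision value, which is what stacking needs.
* `sweep_subsets()` retunes only the meta random forest per subset size;
  it does not revisit baseline hyperparameters, mirroring the two-step
  design it implements.
* The choice among PF, CF and PCF is configurable (`run_config(kind =)`);
  PF is the default final model, with CF/PCF retained for comparison
  experiments.
* Training refits every pool member once per fold during PF generation;
  with the full pool and large grids this is the dominant cost. Reduced
  grids and fewer descriptors scale it down linearly.
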