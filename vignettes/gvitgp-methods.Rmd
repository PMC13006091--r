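---
title: "Genomic prediction with a GRM-fused patch transformer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with a GRM-fused patch transformer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Genomic prediction estimates a quantitative phenotype (yield, milk
production, fertility, ...) from genome-wide SNP genotypes, so that
breeding candidates can be ranked from DNA alone. The statistical setting
is hostile: tens of thousands of markers, hundreds to a few thousand
individuals (`p >> n`), strong linkage disequilibrium (LD) between nearby
markers, and family structure that makes samples highly non-independent.
Classical linear methods (GBLUP and relatives) exploit exactly that
structure — the genomic relationship matrix (GRM) — but are additive by
construction. Attention-based sequence models can represent non-additive,
long-range interactions, but with weak inductive biases they overfit badly
at these sample sizes.

`gvitgp` implements a dual-pathway architecture that combines the two: a
vision-transformer-style encoder over patch-embedded SNP sequences, with
the VanRaden GRM injected as an inductive bias through cross-attention.
Everything around the model — quality control, leakage-free relationship
features, locus selection, the nested evaluation protocol, ablation
harnesses, and a population simulator — is part of the package, so the
whole pipeline is testable end-to-end without any external data.

## Marker quality control

Markers are biallelic dosages coded 0/1/2 (count of the second allele),
`NA` for missing. `apply_qc()` retains markers with

* call rate strictly above 0.95,
* minor allele frequency strictly above 0.01, where the second-allele
  frequency at marker *j* is `p_j = sum_i M_ij / (2 n_j)` over the `n_j`
  non-missing genotypes,
* exact Hardy–Weinberg equilibrium p-value strictly above 1e-6.

The HWE test is the exact conditional test on the heterozygote count given
the allele counts (the test PLINK uses), implemented in log-space and
checked in the test suite against an independent factorial enumeration for
every genotype configuration up to n = 50. A monomorphic marker is assigned
p = 1 by convention. QC is idempotent; a panel in which no marker survives
is a hard error because nothing downstream is defined.

## The genomic relationship matrix, fold-aware

`compute_grm()` implements the VanRaden GRM

    G = M* M*' / (2 * sum_j p_j (1 - p_j)),   M* = M - 2p,

with `p` estimated on a *declared reference cohort*. Two conventions
matter:

* missing dosages are filled with `2 p_j` before centering, so they
  contribute exactly zero (the standard neutral treatment; the choice is
  ours, as the centering of missing values is underdetermined by the
  formula);
* markers monomorphic in the reference cohort (`p` of 0 or 1) are zeroed
  out of the numerator — they already contribute nothing to the
  denominator, and this keeps held-out individuals carrying the rare
  allele from injecting mass through an undefined marker.

`fold_grm_features()` is the leakage-safe entry point: frequencies and the
reference GRM come exclusively from the training cohort, and evaluation
individuals are represented only by their relationship vectors
`G_eval×train`. Overlapping cohorts raise an error rather than a warning,
because a silent overlap is precisely the leakage the protocol is designed
to exclude. The GRM is computed on the full post-QC panel, not the
selected subset: the relationship prior should summarize the whole genome,
while selection only shapes the sequence pathway.

## Locus selection

Three interchangeable selectors feed the tokenizer, all restricted to
training-fold rows (ids outside the declared fold raise a leakage error):

* **Gradient-boosted trees (default).** A boosted regression forest on raw
  mean-filled dosages; every marker with strictly positive total
  split-gain importance is retained, so the retained count `k` is
  data-driven rather than a tuned threshold. We use 500 trees of up to 31
  leaves, learning rate 0.05, feature and row subsampling 0.8, and a fixed
  seed; these are ordinary gradient-boosting defaults for this problem
  size and are exposed as arguments. At the package's desk scales (a few
  thousand markers) the positive-gain rule retains most of the panel; on
  dense chips it is strongly sparsifying.
* **Linear-kernel SVR.** Epsilon-SVR on standardized dosages; markers are
  ranked by the absolute primal weight `|w| = |t(coefs) %*% SV|` and the
  top-`k` kept, ties broken toward the smaller marker index.
* **GWAS + LD pruning.** Greedy LD pruning first (200 kb window, step 1,
  `r^2 > 0.5` removes the lower-MAF member; position ties remove the later
  marker), then the `k` smallest single-marker regression p-values among
  survivors. The per-marker test is the two-sided t-test on the slope of
  `y ~ dosage`, computed in closed form and verified against `lm()`;
  constant markers get p = 1. No structure correction is applied — the
  univariate baseline is deliberately plain, and with family structure in
  the simulator its p-values are anti-conservative, which is part of why
  it is the weakest selector.

In ablations the baselines run at the *gbdt-matched* `k` (the fixed-`k`
discipline), so comparisons isolate the ranking, not the dimensionality.
Selected markers are always returned in genomic (chromosome, position)
order because the tokenizer patches the *sequence* of selected SNPs and
the interpretability export maps patches back to coordinates.

## Tokenization

`make_patch_plan(L, N_p)` uses a fixed patch *count*: `P = ceiling(L /
N_p)` markers per patch, zero-padding the final patch (`pad = N_p * P -
L`). The default `N_p = 400`; the package's tests run smaller `N_p` purely
for problem-size reasons. When `L < N_p` the trailing patches are
all-padding and are retained so the token-sequence shape is constant
across folds.

Three embeddings implement the tokenization ablation:

* **SPE** — patch the selected sequence, flatten each patch, map it
  `P -> D` with one shared affine layer;
* **FPE** — the same over the entire unfiltered post-QC panel;
* **SIE** — one token per selected marker through a shared `1 -> D` map
  (no local context).

A learned `[CLS]` vector (`N(0, 0.02^2)`) is prepended; its final state is
the regression readout. Before embedding, dosages are mean-filled with the
training-fold `2 p_j` and standardized by training-fold mean/sd (constant
markers get sd 1); held-out rows are transformed with the training
statistics.

## The model

The encoder stacks Pre-LN transformer blocks:

    x'  = x  + MHSA(LN(x))
    x'' = x' + FFN(LN(x'))

with `FFN = affine(D -> ffn_mult*D) -> GELU -> affine(-> D)` and the tanh
GELU approximation `0.5 x (1 + tanh(sqrt(2/pi) (x + 0.044715 x^3)))`.
Self-attention adds a learnable relative positional bias: per head, entry
(j, k) of the score matrix receives `table[k - j]` from a
`(2 S_max - 1)`-row lookup table (zero-initialized, `S_max = N_p + 1` with
`[CLS]` at position 1 of the same indexing). A zero table makes the model
exactly permutation-equivariant over patch tokens; the test suite asserts
both that identity and its converse.

The GRM pathway maps each individual's relationship vector (length
`n_ref`, the training-cohort size) through
`affine -> GELU -> affine -> reshape to m_g tokens -> per-token LayerNorm`.
The default is a single GRM token (`m_g = 1`), the most literal reading of
a per-individual kinship embedding. With one token, cross-attention
degenerates: the softmax over a single key is identically 1 and the fusion
injects one shared (value-projected) vector into every SNP token — a
uniform, dynamically gated shift rather than a position-specific mixture.
We keep this default and document the degeneracy instead of hiding it
(`m_g > 1` is available); empirically the injection is exactly what lifts
the fused model over the SNP-only baseline on kinship-structured data.

Midway through the stack (after `L_pre` of `L_pre + L_post` blocks) the
fusion module computes

    Q = LN(H_snp) W_Q,  K = H_grm W_K,  V = H_grm W_V
    H' = H_snp + MultiHead(Q, K, V);  out = H' + FFN(LN(H'))

with no positional term on the cross-attention (its keys are not a
sequence). Only the query side is layer-normalized; the GRM tokens arrive
already normalized by their pathway.

Variants for the fusion ablation: `gvit_base` (encoder only),
`grm_mlp` (GRM pathway + head only), `gvit_concat` (encoder `[CLS]`
concatenated with the flattened GRM tokens — static fusion), and
`gvit_gp` (cross-attention fusion). Zeroing the fusion output projections
turns `gvit_gp` into `gvit_base` exactly; this weight-surgery equivalence
is asserted in the tests.

The regression head is `affine(D -> D/2) -> GELU -> dropout -> affine(->
1)`; dropout (default 0.1) is the only stochastic element at training time
and is disabled in eval mode.

Defaults where the architecture leaves room: `D = 128`, 8 heads,
`L_pre = L_post = 2`, `ffn_mult = 4`, `grm_hidden = 512`, dropout 0.1.
The package's tests run `D = 64` and `grm_hidden = 256` as their standard
problem size.

### Implementation notes

The network is implemented directly in the package (forward passes and
hand-derived backward passes); the encoder runs as a single fused
compiled routine (RcppArmadillo) with all intermediates held outside the
R heap, because per-layer round-trips through R dominated runtime at
realistic batch sizes. Inside the training kernels, `exp` (softmax) and
`tanh` (GELU) use a range-reduced polynomial with ~1e-7 relative accuracy;
softmax rows are renormalized exactly, so attention rows sum to 1 to
machine precision. Correctness of the whole gradient is enforced by a
finite-difference check over every parameter leaf of every variant in the
test suite. Training is AdamW (decoupled decay on weight matrices only;
never on biases, LayerNorm parameters, the `[CLS]` vector or the bias
table) with cosine annealing from the peak rate to 0 over `t_max` epochs
and early stopping on validation MSE (`patience + 1` consecutive
non-improvements; best weights restored). All randomness (shuffling,
dropout, initialization) is seeded; a repeated run is bit-identical on the
same machine.

## The evaluation protocol

`make_split()` draws a seeded 80/20 split and partitions the 80% into 5
folds exactly. `run_protocol()` then enforces the nesting discipline:

1. per fold — locus selection on the fold-training rows only, fold-aware
   GRM features, dosage and phenotype standardization by fold-training
   statistics, training with early stopping on the fold-validation rows;
2. refit — the selector and model are refit on the full 80% and trained
   for the *median of the folds' best epochs* with no early stopping, so
   the test set influences nothing (no validation set exists at refit
   time; fixing the epoch budget from the inner folds is our resolution
   of that gap);
3. one evaluation on the untouched 20%.

Phenotypes are standardized to training z-scores and all metrics (Pearson
r, `R2 = 1 - SS_res/SS_tot`, MSE) are reported on that scale; with
unit-variance targets MSE and `1 - R2` track each other. Constant
predictions get r = 0 by convention, flagged, so ablation tables stay
total. `gblup_ridge_baseline()` provides the linear reference: kernel
ridge on the training GRM with the penalty chosen by inner CV, predicting
held-out individuals through their relationship vectors.

`run_ablation()` compares arms — embeddings (SPE/SIE/FPE), fusion variants,
or selectors at matched `k` — under an identical split, selection and seed
per repetition. Arms train on folds 2..5 with fold 1 as the early-stopping
validation set and are evaluated once on the common test set: a single
consistent fold per repetition rather than a full 5-fold pass per arm,
because ablations compare arms under identical conditions and the full
protocol's per-fold averaging adds cost but no contrast. The harness
accepts an `arms` subset to run a targeted pair.

## The population simulator

`sim_config()` defaults define the reference study population used across
the tests: 40 families (2 founders + 18 offspring each, n = 800), 2,000
markers split over 10 chromosomes, founder haplotypes drawn per marker
from `Bernoulli(p_j)` with `p_j ~ U(0.05, 0.5)` and a first-order copying
process (probability 0.6) between adjacent markers of a chromosome;
offspring inherit one recombination-free chromosome copy per parent.
Phenotypes combine 20 additive causal loci and 5 centered pairwise
epistatic interactions, with effects `N(0,1)` rescaled so the genetic
fraction of variance is h2 = 0.7, then standardized; 1% of genotypes are
set missing. These values are a deliberately favorable but realistic
small-breeding-program regime: strong kinship for the GRM pathway, local
LD for patches to exploit, a non-additive component linear selectors miss.

What the simulator does *not* emulate: realistic recombination maps and
crossover interference, mutation/selection/drift history, allele-frequency
spectra from real chips, genotype-calling error structure, dominance, or
gene–environment interaction. Passing tests therefore demonstrate that the
machinery is correct and that the architecture behaves as designed under
its intended conditions — not that it attains any particular accuracy on
real breeding data.

## Numerical choices and conventions

* Marker/sample indices are 1-based throughout (R convention); bp
  positions are 1-based physical coordinates.
* Missing-genotype encodings: `NA`, `-9`, `.` in TSV; a `0` allele in
  `.ped` pairs. Unparseable tokens become missing and are counted, not
  fatal. In `.ped` input the counted ("second") allele is the
  lexicographically later of the two alleles observed at that marker.
* LayerNorm epsilon 1e-5; weights `N(0, 0.02^2)`; LN gains 1; bias table
  and all biases 0 at initialization.
* Selector tie-breaks: smaller marker index (SVR ranks, GWAS p-values);
  LD pruning removes the lower-MAF member, the later-position marker on a
  tie.
* The exact-test p-value accumulates all heterozygote counts whose
  conditional probability is at most that of the observed count, with a
  1e-12 relative tie guard.
* Attention interpretability (`attention_manhattan()`): `[CLS]` row of
  the chosen self-attention layer (default: last), averaged over heads
  and evaluation samples; the `[CLS]`-to-`[CLS]` entry is dropped without
  renormalizing, so patch scores plus that weight sum to 1. Patches are
  placed at the majority chromosome and median bp of their member
  markers; the significance line is mean + 3 sd of patch scores. Which
  layer best reflects locus importance is genuinely open; the layer and
  aggregation are exposed as arguments.

## Problem sizes used by the tests

The test suite exercises the full pipeline at the reference population
scale (n = 800, 2,000 markers, `N_p = 50`, `D = 64`, 2+2 encoder blocks,
4-epoch budgets with batch 128) and verifies: GBDT recall of the planted
causal loci (mean over 5 seeds at least 0.8), a hold-out test correlation
significant under a 200-shuffle permutation null (p < 0.01), and the
fusion ordering mean r(`gvit_gp`) at least mean r(`gvit_base`) over 5
seeds. These sizes are the package's standard desk-scale regime; the
architecture itself scales to dense chips by raising `N_p`, `D` and the
epoch budget.

## Known limitations

* The two-stage design inherits the selector's biases: a tree ensemble
  favors loci with marginal effects, so interaction-only loci can be
  filtered out before the transformer ever sees them.
* With `m_g = 1` the fusion is a gated global injection, not patch-specific
  kinship routing; `m_g > 1` enables the latter but is less literal.
* Single-marker GWAS selection is uncorrected for structure and is
  expected to underperform on stratified cohorts.
* Training is CPU-bound single-threaded deterministic; the package targets
  method-scale experiments, not production-scale chips, on this backend.
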