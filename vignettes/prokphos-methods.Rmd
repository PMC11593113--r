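---
title: "prokphos: models, parameters and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{prokphos: models, parameters and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`prokphos` predicts prokaryotic phosphorylation sites from sequence alone.
This vignette documents the modelling choices: what each component assumes,
which parameters matter and why their defaults were chosen, what the
synthetic benchmark does and does not demonstrate, and the numerical
conventions needed to reproduce results bit for bit.

## Peptide windows and datasets

A candidate site is represented as a `PSP(n, n)` window: the central
phosphorylatable residue with `n` residues on each side, `*`-padded past
protein termini.  The default `n = 10` (21-mer windows) balances context
against data sparsity and is configurable everywhere.  Site positions are
1-based; motif offsets are counted -n..+n from the centre, matching the
field's "(-3, +1)" notation.

Positives are windows at listed phosphosites; negatives are windows at every
other occurrence of the same residue types within the same proteins.  This
"same protein" negative convention assumes the listed sites are complete for
those proteins; unreported true sites will contaminate the negatives, which
depresses apparent specificity but does not bias the ranking.

Nonstandard residues (B, J, O, U, X, Z) are rejected by default; a `pad`
option maps them to `*` (treated as "no residue" by every encoder) for users
with selenoproteins or ambiguity codes.

Redundancy reduction is a deterministic greedy single-linkage filter on
fractional peptide identity (matching non-`*` positions over compared
positions).  Windows are scanned earliest-timestamp first, then by protein
and position, so the oldest record of a redundant group is retained; exact
duplicate peptides of a label always collapse.  The published thresholds
(0.40 routine, 0.25 stringent) refer to this identity.  A precomputed
two-column cluster file can substitute for the built-in reducer when an
external clustering (e.g. CD-HIT) is preferred.

Train/test splitting is by timestamp — all windows of a protein inherit its
date, so no protein straddles the cutoff, avoiding within-protein leakage.

## Feature channels

Eight sequence descriptors use their conventional definitions; none of their
hyperparameters is dictated by the method itself, so the defaults are the
descriptor-family conventions, recorded in model metadata:

| parameter | default | meaning |
|---|---|---|
| `eaac_window` | 5 | EAAC sliding sub-window (positions) |
| `cksaap_kmax` | 3 | largest CKSAAP pair spacing |
| `apaac_lambda`, `paac_lambda` | 4 | sequence-order correlation depth |
| `apaac_weight`, `paac_weight` | 0.05 | weight of the correlation terms |
| `distpair_max_distance` | 2 | largest DistancePair distance |
| `gps_matrix` | BLOSUM62 | GPS substitution matrix |

`*` never counts as a residue: frequency denominators use valid symbols or
pairs only, and correlation terms are computed on the compressed non-`*`
subsequence.  APAAC/PAAC use Chou's hydrophobicity, hydrophilicity and
side-chain-mass tables, z-scored over the 20 amino acids; CTDC uses the 13
standard three-class physicochemical partitions.  DDE's expected dipeptide
means come from standard-genetic-code codon multiplicities (61 sense
codons).

The GPS channel scores a window as its mean substitution-matrix similarity
to the known positive windows, each per-peptide similarity floored at zero
(a negative similarity carries no more evidence than no similarity).  When
training positives are themselves encoded, the window's own entry is removed
(leave-one-out) to avoid leaking the label.  The original GPS
matrix-mutation training is not performed; the matrix is fixed.

## Contextual channels

The transformer encoder embeds each position as the sum of a learned token
and a learned position embedding, then applies 3 post-norm residual blocks
of 4-head self-attention (`softmax(QK'/sqrt(d_k)) V` per head, heads
concatenated through `Wo`) and a two-layer ReLU feed-forward network.  Only
the head and block counts are fixed by the architecture (yielding 12
attention matrices per window); width defaults (`d_model = 64`,
`d_ffn = 128`) are sized for desk-scale training and exposed in
`transformer_config()`.  Learned (not sinusoidal) position embeddings were
chosen because windows are short and fixed-length.  The sigmoid classifier
head reads the flattened last-block hidden states; those same states are the
contextual feature channel.  Training minimises class-weighted binary
cross-entropy with Adam (lr 1e-3) and, beyond a cap (default 2,000 windows),
a balanced subsample — the encoder is a feature extractor, and its
downstream scorer still sees every window.

The PLM channel is a provider interface.  The shipped stub projects the
one-hot window through a fixed seeded Gaussian matrix: deterministic,
dependency-free, and honest about being a random feature map — it gives the
integration network a tenth channel with the right interface, not
evolutionary knowledge.  Users with a local ESM-2-style checkpoint can
register a provider that returns real embeddings (centre-residue pooling by
default).

## Scoring model and transfer learning

Each channel trains a 7-layer network (input + 5 hidden + output, ReLU,
sigmoid).  Scorer hidden widths default to (256, 128, 64, 32, 16); the
integration network over `V = (D1, ..., D10)` uses (32, 16, 16, 8, 8) — its
input is only 10-dimensional.  Training uses Adam, inverse-class-frequency
sample weights (all negatives retained; a `negative_ratio` option subsamples
instead), a stratified 15% validation split and early stopping (patience 3).
Scores are deterministic functions of the window, and training is bitwise
reproducible from the seed.

Fine-tuning copies the parent and re-trains only the first and last weight
matrices (with biases) of every scorer and of the integration network —
the most literal reading of "input and output layers updated, hidden layers
frozen" — starting from the parent's weights (no re-initialisation), so
zero-epoch fine-tuning returns the parent's behaviour exactly.  The
transformer and the feature scalings are inherited; the GPS channel, being
group-based, scores similarity against the fine-tuning subset's own
positives by default (falling back to the parent's group when the subset
has fewer than 4 positives) — a species-specific predictor's "group" is
that species' substrates, and keeping the parent's mixed group was observed
to wash out species specificity.  Species-scoped fine-tuning requires at
least 4 positive samples.  The
integration-network reading (rather than a fixed score combination) is used
for the final score at prediction time.

Thresholds High/Medium/Low are the 95/90/85% empirical quantiles of
negative scores — computed on a held-out calibration split (default 15% of
the data, stratified), not on the scorers' own training negatives, so the
achieved specificity generalises.  Quantiles use linear interpolation
between order statistics (`stats::quantile` type 7), making cutoffs
reproducible bit for bit.  MCC is defined as 0 when any margin is empty.
Cross-validation is stratified by label; `pretrain_general(cv_folds = 4)`
runs the published 4-fold protocol but is off by default because it
multiplies training cost by the fold count.

## Motif statistics

Motif patterns are dash-separated tokens with `/` alternation, `X`
wildcards, and a `p` prefix marking the acceptor token; unmarked patterns
locate the acceptor by convention (first S/T/Y token, then H, then R/K).
The enrichment test compares motif prevalence among positives with
prevalence among all windows (`E-ratio`) and computes the exact upper-tail
hypergeometric probability with log-binomial coefficients; the printed
summation bound `m..n` is implemented as `m..min(n, M)` since terms with
`m' > M` vanish.  Raw p-values are thresholded at 0.01 to mirror the usual
reporting; a Benjamini–Hochberg column is provided but not used for the
flag.  Attention motif matrices are min–max normalised per matrix (the
normalisation scope is not fixed by the method; per-matrix was chosen so
every matrix uses the full [0, 1] range).  Whether the 12 block/head
matrices should be averaged or kept separate downstream is equally open;
both the per-head matrices and their grand mean are returned.

## The synthetic benchmark

The generator emulates the structure of a prokaryotic phosphoproteome
dataset: proteins sampled i.i.d. from a background composition (uniform by
default, so motif-coverage expectations are exact in closed form; a
realistic composition can be supplied), planted kinase-like context motifs,
and protein-level timestamps placing 90% of proteins before the cutoff.
The default conditions are 2,000 proteins, motif-conditional positive rate
0.8, background positive rate 0.05, and five planted motifs (basophilic
-3/-2, proline-directed +1, acidophilic +3, hydrophobic +2) around S/T
(acidophilic also around Y).  Protein lengths are drawn from a rounded
normal (mean 40, sd 10, minimum 21): short proteins keep the benchmark at
desk scale (about 12,000 candidate windows) while every window still has
full flanking context.  With these rates the Bayes-optimal AUC of the
matched/unmatched structure is about 0.90, so the observed held-out AUC of
roughly 0.89 means the model nearly saturates the planted signal.

What passing the benchmark shows: the encoders expose the planted anchors,
the scorers and integration network learn them, leave-one-out GPS encoding
and the held-out calibration split prevent the leakage that would otherwise
inflate AUC and specificity, and the attention machinery localises the
anchors.  What it does not show: performance on real phosphoproteomes —
real motifs are weaker and correlated, real negatives are incomplete, and
real proteins are long with non-uniform composition.  The benchmark is a
correctness and plumbing instrument, not a biological validation.

The transfer benchmark plants disjoint motifs in two equally sized species
(basophilic in A, proline-directed in B), pretrains a general model on the
union and fine-tunes one model per species; each fine-tuned model should
assign a higher median score to its own species' held-out positives.

## Degenerate inputs and numerical conventions

Empty positive sets, single-class training data, missing timestamps,
out-of-range positions and unknown symbols raise immediate errors.
Constant feature matrices train with a warning (the scorer can only learn
the base rate).  Attention softmax subtracts row maxima; BCE probabilities
are clipped to [1e-12, 1 - 1e-12]; layer norm uses eps = 1e-5.  All
stochastic steps (simulation, subsampling, initialisation, batching, fold
assignment) derive from explicit integer seeds.

## Known limitations

* The stub PLM channel carries no evolutionary information; with it, the
  channel measures plumbing, not biology.
* The transformer is intentionally small; on large corpora its capacity,
  not the data, may bind.
* Negatives are assumed unlabelled-negative; prediction scores are
  calibrated against that convention.
* The greedy identity reducer is order-dependent by design (deterministic),
  which can retain a different representative than clustering tools would.
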