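---
title: "Conditional SMILES generation with stochastic context learning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional SMILES generation with stochastic context learning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`smilesgen` implements a decoder-only, Llama-2-style transformer language
model over SMILES strings, conditioned on molecular properties.  A molecule
is a token sequence $S$; the model is trained autoregressively to predict
each next token.  Conditions are *prepended* to the sequence as extra
embedding rows, the context $C$, so the full input is
$X = \mathrm{Concat}(C, S) \in \mathbb{R}^{L \times d_{emb}}$.

The context holds up to $n = 3$ numeric conditions — Crippen logP, the
synthetic-accessibility score (SAScore, 1 = easy to 10 = hard), and the
molecular weight divided by 100 so all three live on comparable scales —
plus an optional *token-sequence condition*: a tokenized core-structure
SMILES the generated molecule should contain.

Each decoder block applies, in pre-normalization style,

$$x \leftarrow x + \mathrm{Drop}(\mathrm{MMHA}(\mathrm{RMSNorm}(x))), \qquad
  x \leftarrow x + \mathrm{Drop}(\mathrm{FFN}(\mathrm{RMSNorm}(x))),$$

with masked multi-head attention
$\mathrm{softmax}(QK^\top/\sqrt{d_k} + M)V$ (causal mask $M$ has $-\infty$
strictly above the diagonal), rotary positional embeddings applied to $Q$
and $K$ of every row — context rows included, positions $0..L-1$ over the
concatenated sequence — and a SwiGLU feed-forward layer
$(\mathrm{silu}(XW_1) \odot XW_3)\,W_2$.  A final RMSNorm and an untied
output projection produce next-token logits.  The full-scale configuration
(8 blocks, 8 heads, $d_{emb}=384$, $d_{ffn}=1024$, $d_k = d_v = 48$,
vocabulary 591) counts about 15 M parameters.

### Context ingestion

Each numeric condition value $v$ of type $t$ becomes one embedding row
$v\,w_t + b_t + e_t$, where $w_t, b_t$ are a per-type linear map from the
scalar into $\mathbb{R}^{d_{emb}}$ and $e_t$ is a learned type encoding, so
the model sees the value *and* its label.  The phrase "a separate linear
layer" admits a per-type or a shared reading; we chose per-type as the
stricter one — with three conditions the difference is $2 \times 2 d_{emb}$
parameters.  The token-sequence condition reuses the shared token-embedding
table, adds a second table of the same shape specific to the
token-sequence role, and a single learned label vector is added to every
row.  Two additive tables is again the stricter reading of "combined with
an embedding specific to the token sequence … additionally a learned label
embedding"; one table would merely remove a redundant parameterization.

Applying rotary positions to the numeric rows carries no information but
keeps the implementation uniform; it does not hurt because the type
encodings disambiguate the rows.

## Stochastic context learning

A single model must serve unconditional, single- and multi-conditional
generation.  During training, for every batch one Bernoulli($p_{del}$) draw
is made per numeric-condition *type* and one for the token sequence, with
$p_{del} = 0.15$; a deleted condition's row is removed from **every**
sequence of the batch, so the surviving layout is batch-uniform (this is
the batched algorithm; the per-row description is its $B=1$ special case).
A token-sequence condition is sampled for every batch — a contiguous slice
of each molecule's own tokens (random start, random end at or after it,
capped at 50 tokens) — and then possibly deleted as a whole.  Over many
batches each condition survives with frequency $1 - p_{del}$, and a fully
unconditional batch occurs with probability $p_{del}^{4} \approx 5\times
10^{-4}$.

The loss is the cross-entropy of Eq. — mean negative log-probability over
the *SMILES-region* target positions only: context rows and pads are
excluded by a loss mask, so a framed SMILES of $m$ tokens contributes
$m-1$ targets.  Optimization is AdamW ($\beta_1 = 0.9$, $\beta_2 = 0.95$,
constant learning rate $10^{-4}$, decoupled weight decay 0.01 on
matrix-shaped weights only) with batch 256 and 4-step gradient
accumulation at full scale.

The forward *and* backward passes are written directly in R as matrix
algebra; the backward pass is verified in the tests against brute-force
oracles and, during development, against central finite differences on
every parameter group (relative error $\sim 10^{-5}$).  Sequences of a
collated batch are processed in a loop; because pads are part of each
padded sequence exactly as in a tensorized batch, the loop computes the
same loss and gradients a batched implementation would.

## Tokenizer

Splitting is character-level except that square-bracket atoms
(`[nH]`, `[O-]`, …) are single tokens — and, deviating deliberately from a
literal reading of "character level", so are the two-character elements
`Cl`/`Br` and `%nn` ring closures, since splitting `Cl` into `C`, `l`
would corrupt the chemistry.  The vocabulary is corpus-derived
(specials `[PAD]`=0, `[CLS]`=1, `[SEP]`=2, then tokens in C-locale
lexicographic order) rather than a fixed 591-token pretrained list: the
architecture only needs a consistent bijection, and this removes an
external dependency; $d_{voc}$ is reported at build time.  Unknown tokens
at inference are a hard error, never silently substituted.

## Corpus preparation

Pipeline order: RDKit canonicalization (stereochemistry kept) → filters →
string deduplication (first occurrence kept) → annotation.  Filters reject
unparseable strings, molecules over 256 tokens (measured with the package
tokenizer on the canonical string, frame tokens excluded), and "salts",
operationalized as any SMILES containing the `.` fragment separator;
single-fragment charged molecules are kept.  Annotation computes Crippen
logP, SAScore (the RDKit SA_Score contribution, bounded [1, 10]) and
molecular weight / 100.  Records failing descriptor computation would be
dropped with a warning rather than aborting a long run.  The 90/10
train/test split is a seeded permutation.

Since no RDKit binding exists for R, these primitives run in the system
Python RDKit through a batched command-line bridge
(`inst/python/chem_bridge.py`): one process per batch of molecules, TSV
over stdin/stdout.  All chemistry — canonicalization, parsing, the three
descriptors, substructure matching — goes through this single backend, so
train-time conditions and evaluation-time measurements are definitionally
identical.

## Sampling

Generation starts from the context plus `[CLS]` and proceeds token by
token: logits are divided by the temperature $t$ (default 0.8), softmaxed,
and sampled; generation ends at `[SEP]` or after `maxNewTokens`.  The pad
token's logit is masked to $-\infty$ — `[PAD]` is never a legal
continuation.  As $t \to 0^+$ sampling approaches greedy argmax; $t = 1$
leaves the model's distribution untouched.  No top-k or nucleus filtering
is applied.  User-facing units: molecular weight is accepted in Daltons
and divided by 100; a core SMILES is canonicalized before tokenization.

## Metrics

* **Validity** — fraction of generated strings RDKit parses.
* **Uniqueness** — distinct strings among the first $k$ of a batch.
* **Novelty** — distinct generated strings absent from the reference set.
* **MAD** — $\frac1n \sum_i |x_i - y_i|$ between requested values and the
  properties recomputed on the generated molecules; molecular weight on
  the /100 scale.
* **Substructure match (SM)** — fraction containing the core under a
  *bond-order-relaxed* SMARTS: atoms match by element (atomic-number
  queries, aromaticity-agnostic), bonds by `~` (any).  A benzene core
  therefore matches cyclohexane — the intended consequence of retaining
  topology while tolerating electronic detail.

Uniqueness and novelty are string comparisons of canonical SMILES over the
*valid* generations; synonymous SMILES of one molecule count as distinct.
Both choices (valid-only denominator; string level) follow the common
convention of this model family where the sources are silent.

## The toy chemical space

A deterministic stochastic grammar emulates a small organic space so the
whole pipeline is testable with no download: branched alkyl chains of 1–7
carbons with optional mid-chain ether oxygen, functional tails (alcohol,
amine, ether, thioether, halide, aldehyde, nitrile, ketone, ester, acid),
and the rings benzene, thiophene, pyrrole, cyclopentane, cyclohexane and
tetrahydrofuran with up to two substituents — at most 12 heavy atoms per
molecule.  Molecules are drawn from the grammar, deduplicated, and pushed
through the *same* preparation pipeline as real data.  The space spans
roughly $-1.3$ to $4.5$ logP units and $0.16$ to $2.2$ in scaled molecular
weight, ample for conditioning; pyrrole contributes the bracket token
`[nH]` and the halogens exercise two-character tokens.

What the toy space does **not** emulate: stereochemistry, charged or
multi-fragment species, macrocycles, fused rings, and the long-tail token
diversity of a 12.5 M-molecule corpus.  Passing tests therefore establish
the correctness of the machinery (tokenization, conditioning, SCL,
optimization, metrics) at desk scale, not the chemical reach of a
full-scale training run.

## Desk-scale study configuration

The conditional-control experiment run by the tests and by
`scripts/acceptance.R` uses the package's desk-scale configuration,
chosen once for a single-CPU budget of a few minutes:

* corpus: 3000 toy molecules, 90/10 split;
* model: 2 blocks, $d_{emb} = 64$, 4 heads, $d_{ffn} = 128$, dropout 0;
* training: 1200 AdamW steps at batch 32, no gradient accumulation,
  learning rate $10^{-3}$ (the full-scale $10^{-4}$ is needlessly slow for
  a model this small), scaled-molecular-weight condition only, no
  token-sequence condition so the whole capacity serves the one condition
  being measured;
* evaluation: 200 molecules at each of the in-distribution targets
  mw/100 $\in \{1.2, 1.7\}$ (the corpus inter-quartile range is roughly
  1.3–1.7) against a 200-molecule unconditional baseline scored on the
  same targets.

A typical run reaches training loss $\approx 0.5$ nats/token, validity
well above 90 %, and conditional MAD several-fold below the unconditional
baseline — i.e. the condition demonstrably steers generation.  Exact
numbers are computed, not quoted: run the tests or the acceptance script.

## Numerical choices and degenerate inputs

* Softmax rows use max-subtraction; the $-\infty$ mask entries are exact
  and become zero weights.
* RMSNorm uses $\varepsilon = 10^{-5}$ inside the root, so all-zero rows
  are defined.
* Rotary base 10000 (the customary value; unstated in the sources).
* Greedy ties (exactly equal scaled logits) resolve to the lowest token
  id via `which.max` in the greedy reference path; sampled paths draw
  proportionally.
* A batch with zero target positions (nothing to score) is an error, as
  is a non-finite training loss (divergence aborts with the step number).
* Checkpoints store weights, configuration, vocabulary and a vocabulary
  hash; loading verifies shapes and the hash.

## Known limitations

* Per-sequence looping trades speed for clarity; a tensorized batch or
  compiled backend would be needed well before full scale.
* No KV cache: generation recomputes the full forward pass per token,
  acceptable at toy lengths.
* Missing-property padding (for corpora where some molecules lack some
  conditions) is reserved in the collate contract but not exercised: the
  toy corpus always has all three properties.
* The relaxed substructure pattern intentionally ignores bond orders;
  saturated analogues of aromatic cores count as matches.
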