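# smilesgen

Conditional de novo molecular design with a decoder-only transformer and
**stochastic context learning** (SCL), in R.

Generative language models over SMILES strings can propose new molecules,
but practical design work needs *conditional* generation — "a molecule
around 120 Da", "logP near 0", "containing a thiophene core" — and real
datasets rarely carry every property for every molecule. `smilesgen`
implements a single model that serves unconditional, single- and
multi-conditional generation at once: a Llama-2-style decoder (causal
multi-head attention with rotary positional embeddings, RMSNorm
pre-normalization, SwiGLU feed-forward blocks) whose input sequence is the
concatenation X = Concat(C, S) of a *context* C — up to three numeric
property embeddings (Crippen logP, SAScore, molecular weight / 100), each
tagged with a learned type encoding, plus an optional tokenized
core-structure SMILES — and the molecule S itself.

During training, SCL deletes each condition from the whole batch with
probability p_del = 0.15, so the model learns every subset of conditions
in one go; the cross-entropy loss

CE(y, ŷ) = −(1/N) Σₙ log( exp(ŷ[n, yₙ]) / Σᵢ exp(ŷ[n, i]) )

is computed over SMILES-region positions only.  Sampling is pure
temperature sampling (logits / t, default t = 0.8).  Evaluation covers
validity, uniqueness, novelty, the mean absolute deviation
MAD = (1/n) Σ |xᵢ − yᵢ| between requested and recomputed property values,
and the bond-order-relaxed substructure-match rate.

The transformer forward *and* backward passes are hand-written R matrix
algebra (verified against finite differences and brute-force oracles in
the test suite), with AdamW optimization.  Standard cheminformatics
(canonicalization, descriptors, SMARTS matching) is delegated to the
system Python RDKit through a batched command-line bridge, so no external
corpus or download is needed: a deterministic toy chemical-space generator
provides annotated corpora for testing and desk-scale experiments.

## Worked example

```r
library(smilesgen)

rec <- generateToyCorpus(1000, seed = 7)
head(rec, 3)
#>         smiles    logp  sascore mw_scaled
#> 1 CSc1ccc[nH]1 1.73660 3.364150   1.13185
#> 2    FCc1cccs1 2.21760 2.620757   1.16160
#> 3    CCCCCCC#N 2.48038 1.951114   1.11188

vocab <- buildVocab(rec$smiles)
vocab
#> Vocabulary of 17 tokens (specials: [PAD]=0, [CLS]=1, [SEP]=2)
#>   chemistry tokens: # ( ) 1 = C Cl F N O S [nH] ...

splitSmiles("CC(=O)c1cc[nH]c1")   # bracket atoms are single tokens
#>  [1] "C" "C" "(" "=" "O" ")" "c" "1" "c" "c" "[nH]" "c" "1"

split <- splitCorpus(rec, seed = 1)          # 900 train / 100 test
cfg <- modelConfig(dVoc = vocabSize(vocab), nBlocks = 2L, dEmb = 64L,
                   nHeads = 4L, dFfn = 128L, dropoutP = 0)
tc <- trainingConfig(batchSize = 32L, steps = 400L, seed = 1L, lr = 1e-3,
                     gradAccumSteps = 1L, conditionTypes = 2L,  # mw only
                     useTsCondition = FALSE)
model <- trainModel(split, vocab, cfg, tc)   # ~2 min on one CPU
model
#> SmilesLM with 86,144 parameters over a 17 token vocabulary
#>   trained for 400 optimizer steps; final loss 0.6192

gen <- generateSmiles(model, contextBundle(mw = 1.2),   # target 120 Da
                      generationSettings(nSamples = 50L, seed = 9L))
head(gen, 5)
#> [1] "CCCCCCCOC"  "CCOCCCCCl"  "COCCCCS"  "CN(C)Cc1ccc[nH]1"  "CCCCC(O)C=O"

evaluateRun(gen, reference = trainRecords(split),
            conditions = list(mw_scaled = 1.2))
#> MetricsReport over 50 generated / 49 valid molecules
#>   validity    98.00 %
#>   uniqueness  91.84 % (at 50)
#>   novelty     53.33 %
#>   MAD(mw_scaled) = 0.08994
```

Reading: 98 % of the samples parse; the recomputed molecular weights sit
on average 9 Da from the requested 120 Da — even this 86 k-parameter model
trained for two minutes steers its output toward the requested weight
(the unconditional baseline MAD against the same target is several-fold
larger).

A command-line wrapper covers the same pipeline
(`toydata | prepare | train | generate | evaluate`):

```sh
Rscript inst/scripts/smilesgen toydata --n 5000 --seed 7 --out corpus.csv
Rscript inst/scripts/smilesgen generate --checkpoint model.rds --n 1000 \
    --temperature 0.8 --mw-da 120 --seed 1 --out out.smi
```

Every run writes a `.manifest.json` (options, seeds, input hashes) beside
its output.

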