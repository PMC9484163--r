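# MolRank

Dual-branch molecular property modelling and candidate ranking for
small-molecule screening against estrogen receptor alpha (ERα), the
principal drug target in hormone-receptor-positive breast cancer. Given a
compound table with SMILES strings, precomputed molecular descriptors, a
pIC50 activity label and five binary ADMET endpoints (Caco-2, CYP3A4, hERG,
HOB, MN), the package:

1. **Topological branch** — parses each SMILES into a heavy-atom graph with
   a 39-dimensional atom featurization (atom type, degree, formal charge,
   chirality, hydrogen count, hybridization, aromaticity, normalized mass)
   and a bond-order adjacency matrix (aromatic = 1.5); propagates node
   states with a gated graph neural network,
   h^t = h̃^t ⊙ z^t + h^{t−1} ⊙ (1 − z^t) with GRU gates over
   bond-order-weighted neighbour aggregation o^t = (A h^{t−1}) W_o + b_o;
   reads out a molecule vector by a gated mean (divisor n+1) plus max-pool;
   extracts frequent substructures by SMILES pair encoding, embeds their
   induced subgraphs with the same network, and fuses everything with
   softmax attention.
2. **Descriptor branch** — ranks the descriptor columns with a
   gradient-boosted tree ensemble (second-order objective; leaf weight
   −G/(H+λ), structure score −½ Σ G²/(H+λ) + γT), keeps the top 50,
   standardizes them, and compresses them through per-position attention
   and an affine projection to the same 39 dimensions.
3. **Prediction** — fuses the branches as λ·h + (1−λ)·h_m (λ = 0.6),
   and trains a linear regression head (pIC50, MSE loss) or a softmax
   classification head (each ADMET endpoint, cross-entropy) end to end with
   Adam (lr 0.01), dropout 0.5 and stratified 8:1:1 splits. All gradients
   are hand-written reverse mode, verified against finite differences in
   the test suite.
4. **Ranking** — converts predictions into a single candidate score via
   chi-merge binning, weight-of-evidence encoding and a logistic scorecard
   (score = Σ ((woe_i·β_i + a/n)·factor + offset/n)), and emits a ranked
   compound list.

The reference dataset behind the method (1,974 compounds × 729 descriptors)
is not publicly deposited, so the package ships a synthetic generator with
planted ground truth — informative descriptor columns and an
activity-raising substructure — giving every pipeline stage a recovery test
that runs on a desk machine. See `vignettes/molrank-methods.Rmd` for the
model, its assumptions, and every numerical choice.

## Worked example

```r
library(MolRank)

spec <- syntheticSpec(nCompounds = 120, seed = 42)
ds <- generateCompounds(spec)
dim(ds$table)
#> [1] 120 737
ds$truth$informative
#>  [1] "D048" "D162" "D171" "D283" "D346" "D364" "D451" "D544" "D565" "D723"

g <- molFromSmiles(ds$table$SMILES[1])
g
#> MolecularGraph: CC(C)(C)CC
#>   6 heavy atoms, 5 bonds

vocab <- learnVocab(ds$table$SMILES, maxVocab = 300, minFrequency = 5)
vocab
#> SpeVocabulary: 74 merges (maxVocab 300, minFrequency 5)
#>   top tokens: CC C1CCNCC1 1CCNCC1 C1CCNCC1CC OC

descNames <- grep("^D\\d+$", names(ds$table), value = TRUE)
rk <- rankDescriptors(as.matrix(ds$table[, descNames]), ds$table$pIC50, k = 50)
head(selectedDescriptors(rk))
#> [1] "D544" "D283" "D171" "D162" "D163" "D590"

cfg <- pipelineConfig(seed = 7, epochs = 20, nMaxSubstructures = 4L)
res <- runPipeline(ds$table, "hERG", cfg)
round(res$metrics, 3)
#> precision    recall        F1       AUC      AUPR
#>     0.500     1.000     0.667     0.667     0.779

preds <- data.frame(compound_id = ds$table$compound_id,
                    pIC50 = ds$table$pIC50,
                    ds$table[, c("Caco2", "CYP3A4", "hERG", "HOB", "MN")])
out <- scorecardPipeline(preds)
head(out$ranking, 5)
#>   compound_id    score rank
#> 1     CPD0028 662.7538    1
#> 2     CPD0022 648.5399    2
#> 3     CPD0027 648.5399    3
#> 4     CPD0047 648.5399    4
#> 5     CPD0059 648.5399    5
```

Reading the output: the learned vocabulary's most frequent multi-atom token
after `CC` is the planted piperidine substructure `C1CCNCC1`; the top-ranked
descriptors are drawn from the planted informative set; held-out metrics on
a 120-compound toy run are modest by design (a 12-compound test split); the
scorecard assigns each compound an additive point total (factor 20/ln 2,
offset 600, so ~663 means roughly 8-to-1 odds of being a "good candidate"
relative to the 600-point baseline), and compounds with identical predicted
profiles tie exactly, ordered by id.

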