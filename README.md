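# odorlex

Predicting the odor character of a chemical from its electron-ionization
mass spectrum, for researchers in machine olfaction and flavor/fragrance
informatics.

Binary sensory catalogs (chemicals × verbal descriptors, 0/1) are almost
entirely zeros, and catalogers use semantically similar descriptors
*mutually exclusively* — a chemical annotated "rose" rarely also gets
"violet" — so the Pearson correlation between kindred descriptor columns
vanishes and correlation-based structure discovery fails. odorlex instead
groups descriptors by **word-embedding cosine distance**
(d(i,j) = 1 − cos(vᵢ, vⱼ)), clusters them with **UPGMA**
(unweighted average linkage,
d(A∪B, C) = (|A|·d(A,C) + |B|·d(B,C)) / (|A|+|B|)), cuts the dendrogram at
K clusters, and collapses the catalog onto cluster labels with an OR rule.
A sigmoid feed-forward **autoencoder** ([212, 85, 30, 85, 212] at reference
scale) compresses the spectrum (m/z window 51..262, globally max-normalized)
into a 30-dimensional feature vector; a mapping network ([30, 50, 20, K])
predicts the cluster labels; the assembled six-layer predictor is fine-tuned
end-to-end. Training is per-sample momentum SGD,

    Δw(τ+1) = −η_τ ∂E/∂w + α_τ Δw(τ),   η_τ = η₀·decay^τ,

on mean-squared error with an L2 weight penalty λ·Σw², and the continuous
outputs are binarized by a step-function threshold fitted on the training
set. Generalization is measured by five-fold cross-validated pooled
true-positive / true-negative rates (each truth column of the confusion
table sums to 100%).

A seeded synthetic-data module generates catalogs, spectra and embeddings
with planted odor groups — including the exclusive-annotation regime that
kills correlations — so the entire pipeline is testable offline.

## Worked example

The package ships a hand-checkable miniature: 6 descriptors in 2 semantic
families, 8 chemicals, 8-bin spectra.

```r
library(odorlex)
fix <- generateWorkedFixture()
dm  <- cosineDissimilarity(descriptorNames(fix$catalog), fix$embeddings)
dend <- upgma(dm)
dend
#> OdorDendrogram: 6 leaves, 5 merges, heights 0.0400..0.7822
clusterMembers(cutToK(dend, 2))
#>   rose   lily violet   milk cheese butter
#>      1      1      1      2      2      2
asMatrix(buildClusterLabels(fix$catalog, cutToK(dend, 2)))["mix1", ]
#> cluster1 cluster2
#>        1        1
```

The merge heights 0.04, 0.04, 0.30, 0.30, 0.7822 can be verified by hand
from the fixture's 3-d embeddings; chemical `mix1` is annotated "rose" and
"milk", so the OR rule lights both cluster bits.

A full synthetic run (240 chemicals, 6 planted groups, five-fold CV of the
autoencoder + mapper predictor at K = 6):

```r
w   <- generateWorld(syntheticConfig(seed = 11))
sm  <- buildSpectrumMatrix(w$spectra, w$mzWindow[1], w$mzWindow[2])
asg <- cutToK(upgma(cosineDissimilarity(descriptorNames(w$catalog),
                                        w$embeddings)), 6)
cv  <- crossvalidate(w$catalog, sm, asg,
                     pipelineConfigs(ncol(asMatrix(sm)), 6, seed = 11),
                     makeFolds(240, 5, seed = 11))
cv$pooled
#> ConfusionRates: TP 75.5%, TN 93.1% (FP 6.9%, FN 24.5%)
```

Both rates sit far above the prevalence-matched chance baseline
(TP ≈ 32%, TN ≈ 68% here); substituting the correlation-based clustering
for the embedding-based one drops performance sharply, which is the
phenomenon the method exists to demonstrate. `runPipeline()` wraps the
whole sequence (read → filter → normalize → cluster → CV) with YAML
configs and result files; `inst/cli/odorlex.R` is a thin shell front end.

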