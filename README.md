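# hetdti

Drug–target interaction (DTI) prediction from heterogeneous biological
networks in R.

Known DTI matrices are extremely sparse: most drugs and targets have few or
no annotated partners, which starves graph-based models of signal. `hetdti`
implements a pipeline that attacks that sparsity from three directions
before a classifier ever sees a drug–target pair:

1. **Meta-path densification.** From the six typed relations over drugs (D),
   targets (T), diseases (I) and side-effects (S), nine meta-path count
   matrices are built by chained adjacency products (`DT`, `DDT`, `DIT`,
   `DTT`, `DIDT`, `DITT`, `DSDT`, `DDIT`, `DTDT`); entry *(d, t)* of each
   counts the typed path instances from *d* to *t*. The eight indirect
   matrices are fused by learned semantic attention
   (`A_fusion = Σ_i softmax(w)_i · A_i`), thresholded at τ, and merged with
   the known interactions: `Y_DTI = max(A_DT, [A_fusion ≥ τ])`.
2. **Entropy-weighted similarity fusion.** Four drug views (Tanimoto
   chemical, and Jaccard over the D–D, D–I, D–S neighborhoods) and three
   target views (normalized Smith–Waterman sequence, Jaccard over T–T and
   T–I) are combined with weights inversely proportional to each view's
   mean row entropy, so less-random views count more:
   `ω_m = (1/E_m) / Σ_n (1/E_n)`.
3. **Regularized graph-convolutional autoencoder.** With block matrices
   `Ã = [[A_DD, Y_DTI], [Y_DTIᵀ, A_TT]]` and
   `S̃ = [[S_D, Y_DTI], [Y_DTIᵀ, S_T]]`, a two-layer GCN
   `Z = tanh(L̂ · sigmoid(L̂ S̃ W₁) · W₂)` (with
   `L̂ = D^{-1/2}(Ã + I)D^{-1/2}`) is trained under
   `Loss = ‖Ã − sigmoid(ZZᵀ)‖² + Loss_STC + Loss_MI`, where the spatial
   topological consistency (STC) term pulls mutual p-nearest similarity
   neighbors together in embedding space and the mutual-information (MI)
   term maximizes Deep-InfoMax-style global and local dependence between
   each node's input row and its embedding while adversarially matching the
   latent distribution to a Gaussian prior.

An XGBoost classifier on concatenated pair embeddings `[z_d, z_t]` scores
drug–target pairs, evaluated by leakage-aware five-fold cross-validation
(test-fold positives are masked *before* meta-path fusion and embedding
training, since `Y_DTI` would otherwise leak test labels into the inputs).

The package is aimed at method developers and computational pharmacologists
who want a fully inspectable, dependency-light reference implementation of
this family of models, exercisable end to end on synthetic heterogeneous
networks with planted group structure — no external database downloads.

## Worked example

```r
library(hetdti)

# A synthetic heterogeneous network: 60 drugs, 60 targets, 30 diseases,
# 30 side-effects, 2 planted groups shared by all relations.
ds  <- generate_synthetic_dataset(synthetic_config())
cfg <- train_config(tau = 3, epochs = 300, seed = 1)

model <- hetdti_fit(ds$network, ds$fingerprints, ds$sequences, cfg)
model
#> Drug-target interaction model (meta-path fused GCN autoencoder)
#>   network: 60 drugs, 60 targets, 30 diseases, 30 side-effects
#>   DTI densification (tau = 3): 591 known -> 753 fused positives
#>   embeddings: k = 256, 300 epochs, final total loss 3191.2695
#>   classifier: xgb on concat pair features

round(coef(model)$attention, 4)   # softmax weights over the indirect meta-paths
#>  DDT  DIT  DTT DIDT DITT DSDT DDIT DTDT
#>    0    1    0    0    0    0    0    0
round(coef(model)$drug_views, 4)  # entropy-derived similarity view weights
#> interaction     disease       sider    chemical
#>      0.2471      0.2726      0.2690      0.2113

rank_predictions(model, "D001", "drug", top_n = 3)
#>   partner_id     score
#> 1       T013 0.2499240
#> 2       T041 0.2346815
#> 3       T039 0.2095892
```

The printed densification line says the fused meta-path network promoted
162 unobserved pairs (whose indirect path support cleared τ = 3) into the
interaction network alongside the 591 known DTIs. On this fixture the
attention head concentrates on the disease-mediated `DIT` path — the
indirect relation whose counts track the known interactions best — and the
ranked list contains the query drug's strongest unannotated candidate
targets with their classifier scores.

Leakage-guarded evaluation:

```r
hetdti_cv(ds$network, ds$fingerprints, ds$sequences, cfg)
#> Cross-validation metrics (per fold):
#>     AUC   AUPR Recall     F1    ACC fold
#>  0.7722 0.3597 0.1092 0.1722 0.8266    1
#>  ...
#> Mean:
#>    AUC   AUPR Recall     F1    ACC
#> 0.7498 0.3259 0.1185 0.1774 0.8203
```

On this fixture the mean AUC of 0.75 is essentially the information
ceiling: scoring pairs by the *true* planted group labels attains AUC 0.758,
because interactions are sampled independently given the groups. The methods
vignette (`vignettes/hetdti-methods.Rmd`) discusses what the synthetic
conditions can and cannot demonstrate.

A thin command-line interface over the same functions lives at
`inst/cli/hetdti.R` (`simulate`, `build`, `train`, `evaluate`, `predict`
subcommands).

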