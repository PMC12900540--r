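# stransfer

Transfer learning for spatial transcriptomics domain annotation: given one
tissue slice whose spatial domains (cortical layers, tumor regions, ...)
have been annotated by hand, **stransfer** annotates an adjacent unlabeled
slice — with the same region names — instead of re-clustering it from
scratch. It is aimed at analysts working with multi-slice datasets (serial
sections, replicates, cross-platform profiles of the same tissue) where
manual annotation of every slice is the bottleneck.

## The model

Each slice is a pair (X, S): expression X ∈ R^(N×G) over N spots, planar
coordinates S ∈ R^(N×2). Three components:

1. **Dual spatial graphs.** A k-nearest-neighbour adjacency A (local
   contiguity, a_ij = 1 iff spot j is among spot i's k nearest neighbours)
   and a positive pointwise mutual information graph P built from truncated
   random walks over A, p_ij = max(0, log P(i,j)/(P(i)P(j))) — long-range
   co-occurrence structure beyond direct adjacency.
2. **Dual-graph variational GCN encoder.** A linear embedding of X feeds two
   three-layer graph-convolution branches, σ(Ĝ H W) with
   Ĝ = D̃^(-1/2)(G+I)D̃^(-1/2), one per graph. Each branch emits a
   deterministic feature f_G and variational parameters (μ_G, log σ_G²)
   sampled as z_G = μ_G + σ_G ⊙ ε. Per-spot attention weights
   (softmax over learned scores) fuse the branches; the embedding is
   h = [f, z].
3. **Classifier + adversarial adaptation.** A residual-block softmax
   classifier is trained on the labeled source slice with cross-entropy.
   A target encoder (initialized from the source encoder) is then trained
   adversarially against a domain discriminator D — D minimizes
   L_D = −E[log D(h_s)] − E[log(1 − D(h_t))], the target encoder minimizes
   L_G = −E[log D(h_t)] — until D's balanced accuracy settles near 0.5,
   i.e. the two slices' embeddings are no longer distinguishable and the
   source classifier transfers.

The methods vignette (`vignettes/stransfer-methods.Rmd`) documents every
modelling choice, default and limitation.

## Worked example

The package ships a synthetic-data generator that draws paired slices with
4 layered domains, domain-specific marker genes and a gene-wise
multiplicative batch effect on the target (the reference conditions:
400 spots/slice, 60 genes, effect size 2, noise sd 0.6, batch shift 1.0 on
half the genes):

```r
library(stransfer)

pair <- generate_slice_pair(synthetic_config())
fit <- stransfer(pair$source, pair$target)  # ~30 s on one core
fit
#> Slice-to-slice transfer model (stransfer)
#>   source: synthetic_source - 400 spots; target: synthetic_target - 400 spots; 60 genes
#>   graph_mode: both | classifier: residual | adaptation: on 
#>   source phase: 200 epochs, final loss 0.0010, accuracy 1.000
#>   adaptation: 600 iterations, final domain accuracy 0.532
#>   target metrics: ARI 0.935, CA 0.975

domain_accuracy(fit)
#> [1] 0.52075
```

Reading the output: the source phase fits the encoder and classifier to the
labeled slice (training accuracy 1.000 — the domains are well separated at
these settings). Adaptation then aligns the target's embeddings; the final
domain-classification accuracy ≈ 0.53 means the discriminator can no longer
tell the slices apart, and the held-out target labels (kept only for
evaluation) score ARI 0.935 / accuracy 0.975. Turning adaptation off
(`adapt = FALSE`) on the same pair drops the target ARI by roughly 0.1 —
the batch effect is real and adaptation closes it.

`predict(fit)` returns the per-spot labels and class probabilities,
`plot(fit)` draws the training curves, `write_result(fit, dir)` writes
predictions, embeddings and metrics to disk. Real data comes in as a CSV
pair per slice via `read_slice()`; a command-line wrapper with
`simulate` / `run` / `eval` subcommands lives at
`inst/scripts/stransfer-cli.R`.

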