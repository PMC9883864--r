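# metalncloc

Graph meta-learning for **lncRNA subcellular localization**: predict the
cellular compartment (Cytoplasm, Nucleus, Cytosol, Ribosome, Exosome) of
a long non-coding RNA from its sequence alone.

Compartment benchmarks for lncRNAs are small (hundreds of transcripts)
and badly imbalanced, which defeats conventionally trained deep
classifiers. This package implements a pipeline designed for that
few-shot regime:

1. **Features** — k-mer frequency vectors `f ∈ Δ^(4^k)` (counts over the
   `L − k + 1` sliding windows, normalized), with
   reverse-complement-collapsed k-mers and pseudo dinucleotide
   composition (PseDNC, dimension `16 + λ`) as alternatives, and
   optional PCA.
2. **Balancing** — SMOTE: every minority compartment is filled to the
   majority count with synthetic points `x_c + u·(x_n − x_c)`,
   `u ~ U(0,1)`, between a class member and a same-class nearest
   neighbor.
3. **Similarity graph** — nodes are transcripts; an edge joins `i, j`
   iff the cosine similarity `S_ij = ⟨l_i, l_j⟩ / (‖l_i‖‖l_j‖) ≥ τ`
   (ties included). Each node's sample is its local (ego) graph.
4. **Model** — a graph convolutional network per local graph,
   `H_{l+1} = σ(D'^{-1/2} (A + I) D'^{-1/2} H_l W_l)`, read out at the
   center node, trained episodically under **MAML**: inner-loop
   adaptation on each task's support set, outer-loop update of the
   shared parameters from the summed post-adaptation query losses
   (exact second-order meta-gradients via Hessian-vector products, with
   a first-order switch), then meta-test fine-tuning on a small support
   set.
5. **Evaluation** — accuracy, macro F1/recall, per-class sensitivity,
   specificity and MCC; stratified splits and 10-fold cross-validation;
   an optional real-samples-only test mode.

A synthetic sequence generator reproduces the class shapes and imbalance
of the published benchmarks (e.g. 292/149/91/43/25, total 600), so the
whole pipeline runs and is tested without any download.

## Worked example

```r
library(metalncloc)

# simulate a five-compartment benchmark-shaped dataset
records <- generate_imbalanced_benchmark("dataset1-like",
                                         separation = 5, seed = 1)
class_distribution(records$label)
#> Cytoplasm   Nucleus   Cytosol  Ribosome   Exosome
#>       292       149        91        43        25

# featurize, balance, build the similarity graph
x <- featurize_dataset(records, feature_config("kmer", k = 5))
dim(x)
#> [1]  600 1024
bal <- smote_balance(x, records$label, smote_config(seed = 2))
length(bal$labels)
#> [1] 1460
g <- build_similarity_graph(bal$features, bal$labels, tau = 0.7,
                            provenance = bal$provenance)
g
#> similarity_graph: 1460 nodes, 331114 edges (tau = 0.7), 0 isolated

# full pipeline (same stages, one call): filter -> featurize -> SMOTE ->
# graph -> local graphs -> MAML meta-training -> meta-test evaluation
cfg <- default_config(seed = 1)
cfg$synthetic$separation <- 5
res <- run_pipeline(cfg)
round(res$accuracy, 3)
#> [1] 0.992
round(res$metrics$per_class, 3)
#>   precision recall sensitivity specificity    f1   mcc
#> 1      1.00  1.000       1.000        1.00 1.000 1.000
#> 2      0.96  1.000       1.000        0.99 0.980 0.975
#> 3      1.00  1.000       1.000        1.00 1.000 1.000
#> 4      1.00  1.000       1.000        1.00 1.000 1.000
#> 5      1.00  0.958       0.958        1.00 0.979 0.974
```

The numbers mean: the 600 simulated transcripts become 1460 balanced
samples (each compartment filled to 292); at τ = 0.7 the similarity
graph keeps every node connected; and after episodic meta-training the
fine-tuned classifier labels 99.2% of the held-out query samples
correctly (chance is 20% for five compartments), with near-perfect
per-compartment sensitivity and specificity on this strongly separated
synthetic benchmark. Rows of `per_class` follow the alphabetical class
order (Cytoplasm, Cytosol, Exosome, Nucleus, Ribosome).

A command-line front end covers the same stages
(`simulate`, `featurize`, `balance`, `build-graph`, `validate`, `run`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","metalncloc.R",package="metalncloc"))')" \
    simulate --preset dataset1-like --separation 5 --seed 1 --out data/
```

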