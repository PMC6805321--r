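# rhnmf

Robust hypergraph-regularized non-negative matrix factorization for sample
clustering and gene selection in expression data.

## What problem this solves

Given a non-negative expression matrix **X** (m genes × n samples), NMF
finds non-negative factors **X ≈ UV** whose coefficient matrix **V** embeds
samples for clustering and whose basis matrix **U** ranks genes. Two things
routinely break this on real cohorts: corrupted samples (a squared loss
chases their squared error) and the manifold structure of the samples
(which plain NMF ignores). `rhnmf` fits

```
min_{U,V ≥ 0}  Σ_j ‖x_j − U v_j‖₂  +  α · Tr(V L Vᵀ)
```

where the first term is the L2,1 norm of the residual over sample columns —
each sample contributes its error *norm*, not its square, so outliers are
automatically downweighted via the per-sample weights
D_jj = 1/√(‖x_j − Uv_j‖² + γ) — and **L** is the unnormalized Laplacian
L = Dv − H W De⁻¹ Hᵀ of a k-nearest-neighbor **hypergraph** over samples,
whose hyperedges (one per sample: centroid + g neighbors, heat-kernel
weights) capture high-order neighborhood relations that pairwise graph
edges cannot. Multiplicative updates keep U, V non-negative and decrease
the objective every sweep.

Flags reduce the solver to the whole ablation family — classical NMF,
L2,1-NMF, GNMF, HNMF, RGNMF — by choosing `norm ∈ {l21, frobenius}` and
`manifold ∈ {none, simple_graph, hypergraph}`.

The package is for computational biologists who want a self-contained,
fully tested factorization/clustering/gene-selection pipeline: hypergraph
construction, the solver family, clustering accuracy (Hungarian label
matching) and NMI, basis-matrix gene ranking, a block-structured synthetic
generator with planted outliers, TSV/CSV I/O and a CLI.

## Worked example

```r
library(rhnmf)

sim <- generate_dataset(synth_params(n = 150, outlier_fraction = 0.1, seed = 42))
sim
#> Synthetic dataset: 300 genes x 150 samples, 3 classes (rank 3)
#>   noise sd 0.1, 15 outlier columns

fit <- rhnmf_fit(sim$X, fit_config(k = 3, alpha = 10, norm = "l21",
                                   manifold = "hypergraph", g = 5,
                                   max_iter = 150, seed = 42))
fit
#> Non-negative factorization (L2,1 loss, hypergraph penalty (alpha = 10))
#>   U: 300 x 3, V: 3 x 150
#>   150 iterations, converged: FALSE, final objective: 946.755

pred <- cluster_coefficients(fit$V, 3, seed = 42)
cat(sprintf("AC  = %.3f\nNMI = %.3f\n",
            accuracy(pred, sim$true_labels), nmi(pred, sim$true_labels)))
#> AC  = 0.947
#> NMI = 0.799

w <- fit$final_residual_weights
mean(w[sim$outlier_mask]); mean(w[!sim$outlier_mask])
#> [1] 0.02126837
#> [1] 0.6458748

rownames(fit$U) <- rownames(sim$X)
head(select_top(score_genes(fit$U), 10))
#> [1] "gene_9"   "gene_5"   "gene_3"   "gene_55"  "gene_1"   "gene_181"
```

Reading the output: clustering accuracy (AC) is the fraction of samples
matched after optimally permuting predicted to true labels; NMI is the
mutual information between the partitions normalized by the larger entropy.
The 15 corrupted columns end with ~30× smaller residual weights than clean
columns — that is the robustness mechanism at work. The generator plants
its marker genes in rows 1–30 (10 per class); planted markers (here gene_9,
gene_5, gene_3, gene_1) lead the basis-matrix ranking, interleaved with
high-background genes — 16 of the 30 planted markers land in the top 40 of
this run. (Ranking recovery is sharper for the Frobenius fit, which has no
factor-scale reweighting; the planted-marker test in the suite recovers
20/20 there.)

## Command line

```sh
inst/cli/rhnmf simulate --m 300 --n 150 --classes 3 --noise 0.1 --outliers 0.1 --seed 0 --out-dir run/
inst/cli/rhnmf run --input run/X.tsv --labels run/labels.txt \
    --k 3 --alpha 10 --norm l21 --manifold hypergraph --g 5 --seed 0 --out-dir run/
inst/cli/rhnmf evaluate --pred run/labels_pred.txt --truth run/labels.txt
inst/cli/rhnmf select-genes --basis run/U.tsv --n 100 --out run/top100.txt
inst/cli/rhnmf select-alpha --input run/X.tsv --labels run/labels.txt --folds 5
```

Subcommands exit 0 on success, 1 on user error, 2 on internal error.

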