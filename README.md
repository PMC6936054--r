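# glspca

Graph-regularized sparse PCA for gene-expression matrices.

## What problem this solves

Expression studies (bulk tumour cohorts, single-cell experiments) need two
things from a dimension reduction: sample clusters that respect the local
geometry of the data, and components sparse enough that a short list of
driver genes can be read off them. Classical PCA gives neither — it is
blind to manifold structure and its loadings are dense. `glspca` fits a
single factorisation that adds both ingredients to PCA:

$$
\min_{U,H}\;\|X - UH^\top\|_F^2 \;+\; \alpha\,\mathrm{Tr}(H^\top L H)
\;+\; \gamma\,\|H\|_{2,1} \qquad \text{s.t. } H^\top H = I,
$$

where $X$ is the genes × samples matrix, $H$ (n × k) is the sample
embedding, $U = XH$ (m × k) holds the gene loadings, $L$ is the
unnormalised Laplacian of a k-nearest-neighbour graph over samples, and
$\|H\|_{2,1}$ is the row-sparsity norm. The graph term pulls neighbouring
samples together in the embedding (better clustering); the L2,1 penalty
zeroes rows of $H$ (interpretable, sparse components). The solver is an
iteratively reweighted trace minimisation: each iteration reduces to the
k smallest eigenvectors of a dense symmetric n × n matrix, and the
objective decreases monotonically. The graph weight is tuned through
$\beta \in [0,1]$ (with $\beta=0,\gamma=0$ exactly classical PCA and
$\beta=1,\gamma=0$ exactly Laplacian embedding).

Downstream, the package ranks genes by aggregating rows of $U$, evaluates
selections against a reference gene table (identification accuracy IA,
total relevance score TRS), clusters samples with K-means and scores them
by best-mapping clustering accuracy (ACC, exact assignment optimum), and
simulates seeded expression matrices with planted clusters and informative
genes so every claim is testable offline.

## Worked example

```r
library(glspca)

se  <- simulateExpression(seed = 1)              # 200 genes x 60 samples, 3 clusters
fit <- fitGLSPCA(se, kDims = 2, beta = 0.5, gamma = 1)
fit
#> GLSPCAFit: 200 genes x 60 samples, 2 components
#>   beta = 0.5, gamma = 1, alpha = 2.74501e+63
#>   2 iteration(s), converged (tol = 1e-06)
#>   objective: 13407.6 -> 13407.6
#>   ||H||_{2,1} = 9.39226

pred <- clusterSamples(fit, nClusters = 3, seed = 0)
clusteringAccuracy(pred, trueLabels(se))
#> ClusterEvaluation over 60 samples
#>   ACC = 100.00%
#>   mapping: 1->2, 2->3, 3->1

ranking <- rankGenes(fit, topN = 20)
ranking
#> GeneRanking over 200 genes; top 20 selected
#>   leading genes: gene_106 (25.99), gene_182 (25.97), gene_187 (25.6), gene_110 (24.53), gene_7 (24.16)
```

Reading the output: the fit converged in two reweighted iterations with a
non-increasing objective; K-means on the embedding recovers the three
planted sample clusters perfectly up to label permutation (ACC 100%, the
mapping line shows the label bijection used); and the top of the gene
ranking is dominated by planted informative genes (14 of the top 20 here).
The very large `alpha` is the heat-kernel graph at work on raw
high-dimensional distances — the Laplacian's eigenvalues are tiny and the
β-parameterisation rescales accordingly; see the methods vignette for when
to prefer the binary kernel.

A command-line interface with `simulate`, `fit`, `grid`, `rank-genes` and
`cluster` subcommands wraps the same functions:

```sh
Rscript inst/cli/glspca.R simulate --out sim --seed 1
Rscript inst/cli/glspca.R fit --matrix sim/matrix.tsv --out fit --beta 0.5 --gamma 1
Rscript inst/cli/glspca.R cluster --fit fit --truth sim/labels.tsv --out fit
```

## Documentation

The methods vignette (`vignettes/glspca-methods.Rmd`) describes the model,
the majorise–minimise solver and its descent guarantee, the numerical
conventions (tie-breaking, sign fixing, zero-row guard), what the
simulator does and does not emulate, and known limitations.
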