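# jgrnmf

Spatial domain identification for spatial transcriptomics by **joint
graph-regularized non-negative matrix factorization (JGR-NMF)**.

Spatial transcriptomics platforms such as 10x Visium measure gene expression
at thousands of capture spots with known 2D positions. A central analysis
task is to partition those spots into *spatial domains* — contiguous tissue
regions sharing an expression program. Clustering expression alone ignores
spatial coherence; clustering positions alone ignores biology. JGR-NMF
couples both sources in one factorization.

## Model

Given the preprocessed expression matrix `X` (HVG-selected, scaled to
[0, 1]; genes x spots), JGR-NMF solves

```
min_{W>=0, H>=0}  || X - W H ||_F^2  +  a1 * Tr(H L1 H')  +  a2 * Tr(H L2 H')
```

where

* `L1 = D1 - A1` is the Laplacian of an **adaptive expression-neighbor
  graph**: each spot's connection probabilities to its `k1max` nearest
  expression neighbors are the closed-form solution of a constrained
  optimization, `E_l = max(0, 1 - sqrt(d_l)/sqrt(zeta))` with
  `sqrt(zeta) = sum_l sqrt(d_l) / (k1max - 1 - sigma)`, so each spot selects
  its own neighborhood size (weak, far connections are clipped to zero);
  edges are kept only when mutual and symmetrized;
* `L2 = D2 - A2` is the Laplacian of a binary **mutual k-nearest-neighbor
  graph** on the spot coordinates (`k2 = 6`, the Visium hexagonal
  neighborhood);
* `W` (genes x f) is a basis of expression programs and `H` (f x spots) is
  the low-dimensional spot embedding.

The problem is solved by alternating multiplicative updates that preserve
non-negativity and monotonically decrease the objective; spatial domains are
obtained by K-means on the columns of `H`, and agreement with reference
labels is scored with ARI, NMI and purity. A one-vs-rest Wilcoxon rank-sum
screen ranks marker genes per domain.

## Worked example

```r
library(jgrnmf)

## synthetic tissue: 20x20 spot grid, 4 stripe domains, 300 genes,
## 5x marker elevation, 30% dropout
sce <- simulateSpatialDataset(rows = 20, cols = 20, k = 4,
                              layout = "stripes", nGenes = 300,
                              effectSize = 5, dropoutRate = 0.3, seed = 7)

res <- runPipeline(sce, nDomains = 4, truth = TRUE, seed = 7)
res$fit
#> JGRNMFFit: 300 genes x 4 factors x 400 spots
#>   alpha1 = 0.8, alpha2 = 0.1
#>   500 iterations, converged = FALSE, final objective = 4424.33
res$assignment
#> DomainAssignment: 400 spots in 4 domains (sizes: 99, 100, 100, 101)
str(res$scores)
#> List of 3
#>  $ ari: num 0.987
#>  $ nmi: num 0.98
#>  $ pur: num 0.995
```

The fit recovers the four stripes almost exactly (ARI 0.987: roughly one
boundary spot in a hundred is misassigned; purity 0.995 means predicted
domains are 99.5% homogeneous). Markers are recovered by the Wilcoxon
screen — the top domain-1 genes are the planted domain-1 markers:

```r
head(rankMarkerGenes(res$preprocessed$xFiltered, res$assignment), 4)
#>   domain      gene   log2fc       pvalue rank
#> 1      1 gene_0003 2.568716 3.457234e-24    1
#> 2      1 gene_0009 2.480963 6.770479e-20    2
#> 3      1 gene_0004 2.459184 8.835670e-27    3
#> 4      1 gene_0001 2.455324 6.769275e-18    4
```

Real data enter through `readVisium()` (Matrix-Market counts +
`tissue_positions` table) or `readCsvMatrix()`; `writeResults()` emits
labels, embedding, objective trace, run metadata and metrics. A thin CLI
over the same functions lives at `inst/cli/jgrnmf.R`
(`run` / `simulate` / `score` subcommands).

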