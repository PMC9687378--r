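# abcdeg

Bayesian posterior normalization and computed ABC analysis for
differential CD-gene expression in acute myeloid leukemia (AML).

## The problem

Flow-cytometric diagnosis of AML rests on surface molecules encoded by
cluster-of-differentiation (CD) genes, but expression screens return
hundreds of candidates on incomparable scales. This package implements a
two-step analysis for finding *the important few* discriminating CD genes:

1. **Unsupervised structure.** The pooled distribution of log expression
   values is bimodal — genes are essentially unexpressed or expressed. A
   Gaussian mixture model
   `f(x) = Σᵢ wᵢ N(x | mᵢ, sᵢ)` is fitted by expectation–maximization with
   the component count chosen by AIC (`2k − 2·logL`, `k = 3M − 1`). Every
   measurement is replaced by the Bayes posterior
   `p(c_high | x) = w_high·N(x | m_high, s_high) / f(x)`, normalizing the
   data to [0, 1]; the *decision border* is the log-expression value with
   posterior 0.5. Ward clustering (Euclidean distance, minimum-variance
   linkage) of the posterior matrix, cut at the largest change in fusion
   level, discovers the sample subgroups — in AML: the promyelocytic entity
   (APL) plus two further subgroups.
2. **Supervised selection.** For every subgroup dichotomy `(G_k, G_j)` and
   gene `a`, the posterior difference
   `pdeg(a) = p̄_{G_k}(a) − p̄_{G_j}(a) ∈ [−1, 1]` and Cohen's D (pooled-SD
   form) quantify differential expression. Recursive computed ABC analysis
   — three rounds of the Lorenz-curve split into sets A/B/C — applied to
   the pooled `|pdeg|` values yields the selection threshold; genes at or
   above it are reported, with sub-threshold Cohen's D values printed as 0
   as in the published table convention.

A synthetic-data generator (`simulate_expression()`) emulates the bimodal
pooled distribution, planted subgroups and planted one-vs-rest marker
genes, with full ground truth, so every stage is testable end to end. See
the methods vignette (`vignettes/bayes-abc-workflow.Rmd`) for the model,
parameter meanings, and design choices.

## Worked example

```r
library(abcdeg)

run <- run_pipeline(pipeline_config(m_candidates = 1:3, n_restarts = 5))
print(run)
#> AML surface-marker pipeline run
#>   mixture: M = 2 by AIC (n = 20000 pooled values)
#>   decision border: log 2.888 -> raw 772
#>   GOF: chi2 = 47.1 (dof 44), p = 0.348
#>   clustering: K = 3 on 150 samples
#>   ABC threshold (|pdeg|, keep AB): 0.487
#>   G1_vs_G2: 35 gene(s) selected
#>   G1_vs_G3: 36 gene(s) selected
#>   G2_vs_G3: 23 gene(s) selected
#>   G1_vs_normal: 21 gene(s) selected
#>   G2_vs_normal: 13 gene(s) selected
#>   G3_vs_normal: 11 gene(s) selected

run$contingency
#>        label
#> cluster AML1 AML2 APL
#>      G1    0    0  15
#>      G2  106    1   0
#>      G3    0   28   0
```

Reading the output: AIC confirms the two-mode (unexpressed/expressed)
structure; the decision border at log₁₀ ≈ 2.89 means raw expression ≈ 772
separates the modes. The dendrogram cut finds K = 3 subgroups of the 150
leukemia-like samples, and the contingency table shows the APL-like
cluster (G1) is pure — exactly the planted structure. Recursive ABC puts
the selection threshold at |pdeg| ≈ 0.49; the per-dichotomy tables list
each selected gene with its `pdeg` and Cohen's D:

```r
tab <- run$selected$G1_vs_G2
head(tab[tab$selected, c("gene", "pdeg", "cohen_d")], 3)
#>    gene       pdeg   cohen_d
#> 1 CD001  0.6634107  1.976043
#> 2 CD002 -0.5215532 -1.549546
#> 3 CD003  0.6961424  2.386484
```

Positive `pdeg` means higher expression in the first group of the
dichotomy. `run_pipeline(cfg, out_dir = "results/run1")` additionally
writes every intermediate (`model.json`, `posteriors.tsv`, `merges.tsv`,
`partition.tsv`, `contingency.tsv`, `deg/*.tsv`, `selected/*.tsv`) and a
JSON run report.

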