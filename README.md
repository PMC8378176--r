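# ntmep

Essential proteins — those whose deletion is lethal — are expensive to map
experimentally, so they are routinely prioritized computationally from
protein–protein interaction (PPI) networks. Pure topology scores (degree,
betweenness, ...) suffer from the heavy false-positive/false-negative load of
interaction screens, while naive multi-omics fusion imports its own noise.
`ntmep` implements a three-stage ranking pipeline for yeast-style PPI
networks that addresses both problems:

1. **Co-neighbor (CoN) weighting.** Every protein pair (i, j) whose
   neighborhoods N(i), N(j) both have at least two members is scored

   P_CoN(i, j) = |N(i) ∩ N(j)|² / ((|N(i)| − 1)(|N(j)| − 1)),

   and 0 otherwise — a topology-only association weight that also creates
   edges between non-adjacent proteins sharing neighbors (values are capped
   at 1, the statistic's nominal range).

2. **NMTF denoising/completion.** The weighted matrix is factorized as
   P_CoN ≈ F S Gᵀ (F: n×k, S: k×k, G: n×k, all non-negative) by KKT-derived
   multiplicative updates minimizing ‖P_CoN − F S Gᵀ‖²_F. The dense
   reconstruction Y = F S Gᵀ surfaces latent associations and suppresses
   spurious ones, and is turned into a propagation operator
   P\*(i, j) = max(Y_ij, Y_ji) / Σ_k Y_ik (row-renormalized by default).

3. **Seeded score propagation.** Each protein gets an initial score
   S_I = S_H · S_L from ortholog conservation (S_H, counts over reference
   species, max-normalized) and subcellular localization (S_L, frequency of
   its most common compartment). The final score solves
   S_F = α P\* S_F + (1 − α) S_I by damped Jacobi iteration (default
   α = 0.2) — a personalized-PageRank analogue seeded by biology rather
   than uniform teleport.

The package also provides degree/betweenness/closeness/subgraph centrality
baselines, precision–recall and jackknife evaluation, an overlap/difference
comparison of two rankings, and a synthetic scale-free benchmark generator
with planted essentials (hub-biased, ortholog-rich, compartment-enriched)
so the whole pipeline is testable without any database download.

## Worked example

```r
library(ntmep)

d <- generateSynthetic(syntheticSpec(n = 300, seed = 11))
d$network
#> WeightedNetwork (stage 'adjacency'): 300 proteins, 1788 nonzero entries
#>   894 undirected edges

con <- conMatrix(d$network)
fac <- nmtf(con, k = 40, seed = 11, maxIter = 300, relTol = 1e-5)
#> nmtf: stopped after 300 sweeps (maxIter), objective 40.438
Pst <- transitionMatrix(reconstruct(fac))

si <- initialScores(homologyScores(d$annotations),
                    localizationScores(d$annotations))
sf <- rankProteins(Pst, si)
sf
#> ScoreVector (stage 'SF'): 300 proteins, range [0.146, 0.8701]
head(topProteins(sf), 5)
#> [1] "P089" "P025" "P136" "P127" "P093"

evaluateRanking(topProteins(sf), d$gold, cutoffs = c(50L, 100L))
#> EvaluationReport: 300 ranked proteins, 60 gold essentials
#>   PR AUC 0.9774, jackknife AUC 0.9004
#>   top-k hits: 50:50 100:60
```

All 60 planted essentials are recovered in the top 100 (50 of the top 50
are true essentials); the degree-centrality baseline on the same data finds
33/50 and 46/100. For file-based inputs use `runPipeline()` (or the CLI
wrapper in `inst/scripts/ntmep.R`), which writes the ranked score table,
evaluation curves and a JSON run manifest.

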