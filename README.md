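# multiwalk

Candidate disease-gene prioritization by random walk with restart on
**multigraphs** and on a **heterogeneous gene–phenotype network**, for
computational biologists who need to rank the genes inside a linkage
interval by their network proximity to the genes already known for a
disease, integrating several genomic data sources at the network level.

## The model

Each data source (protein interactions, annotation-derived functional
similarity, ...) is one weighted undirected layer. A layer's transition
matrix degree-normalizes its adjacency, `M[i,j] = A[i,j]/d(i)`, and the
layers are merged into a multigraph by taking the **expectation over the
layers a node belongs to**:

    M[i,j] = Σ_k q⁽ᵏ⁾ M⁽ᵏ⁾[i,j],   q⁽ᵏ⁾ = 1/Nᵢ

where `Nᵢ` is the number of layers in which gene *i* has an edge. The
random walk with restart

    p(s+1) = (1 − γ) Mᵀ p(s) + γ p₀

is seeded uniformly on the known disease genes; candidates are ranked by
the stationary probability. The heterogeneous (CHN) extension couples the
gene multigraph to a phenotype similarity network through the bipartite
association matrix *B*: rows of *bridging* nodes (those with an
association) keep `1 − λ` of their mass at home and spread `λ` uniformly
over their associations, and the initial vector splits restart mass
`[(1 − η)u₀; ηv₀]` between gene and phenotype seeds. Defaults:
`γ = 0.7`, `λ = 0.5`, `η = 0.5`.

Also included: KNN similarity-graph construction, annotation-overlap gene
functional similarity, leave-one-out cross-validation with artificial
99-neighbour linkage intervals (rank-based ROC/AUC and strict rank-1
success counting, plus a phenotype-KNN `K` sweep), a seeded synthetic
planted-module benchmark generator, TSV I/O and a CLI.

## Worked example

```r
library(multiwalk)

mg <- toy_multigraph()              # three layers over g1..g4
M <- merge_transition(mg)
M["g1", "g2"]                       # 0.75  = 1/2 * 1/2 + 1/2 * 1
M["g2", "g3"]                       # 0.4444444 = 1/3 * (1/2 + 1/3 + 1/2)

# five-gene worked matrix, walker restarting at g4 with gamma = 0.7
p <- rwr(toy_merged_matrix(), initial_distribution(paste0("g", 1:5), "g4"))$p
round(p, 2)
#>   g1   g2   g3   g4   g5
#> 0.01 0.04 0.13 0.71 0.12
# g3 is the top-ranked non-seed: the predicted disease gene

# heterogeneous network: bridging row scaled by (1 - lambda)
Mc <- chn_transition(toy_chn(lambda = 0.5))
Mc["g2", "g3"]                      # 0.2222222 (= 4/9 * 0.5, prints as 0.22)
Mc["g1", "g2"]                      # 0.75, internal row unchanged

# synthetic planted-module benchmark, 200 LOOCV trials
bench <- generate_benchmark(synthetic_spec(rng_seed = 20260919))
res <- loocv_rwrm(bench$disease_sets, bench$multigraph, bench$positions)
res
#> <loocv_result> 200 trials (rwrm), 200 ranked first
rank_auc(res)$overall_auc
#> [1] 1
```

The stationary probabilities measure proximity to the seed set; in the
easy-regime benchmark every held-out module gene outranks its ~99
interval neighbours because its module mates are the seeds.

The command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "multiwalk.R", package = "multiwalk"))')
Rscript $CLI simulate --seed 7 --out-dir bench
Rscript $CLI merge-rank --layers bench/layer1.tsv,bench/layer2.tsv,bench/layer3.tsv \
    --seeds seeds.txt --candidates candidates.txt --gamma 0.7 --out ranks.tsv
Rscript $CLI loocv --layers ... --phenotype-similarity bench/phenotype_similarity.tsv \
    --knn-k 10 --associations bench/associations.tsv --positions bench/positions.tsv
```

Exit codes: 0 success, 2 validation error, 3 non-convergence.

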