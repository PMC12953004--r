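# crustnet

Community assembly and co-occurrence network stability for biocrust
microbiomes.

Biological soil crusts (biocrusts) develop through a succession of stages —
bare sand, algal crust, lichen crust, moss crust — and cyanobacteria are
widely thought to organise the surrounding bacterial and fungal communities
along the way. Testing that idea from amplicon count tables requires a
chain of specialised analyses, each with its own pitfalls: null-model
phylogenetic β-diversity to separate deterministic from stochastic
assembly, compositionally robust correlation inference to build
co-occurrence networks from relative-abundance data, module-based keystone
detection, and node-removal experiments to quantify what a taxon group
contributes to network stability. `crustnet` implements that chain as a
tested, reusable R pipeline for microbial ecologists, together with a
synthetic-data generator that plants known assembly regimes, known
correlations and known keystone topology, so every stage can be validated
without any sequencing data.

## Methods at the core

* **Assembly (βMNTD / βNTI).** For communities *A*, *B* with relative
  abundances *f* and cophenetic distances *d*,

  βMNTD = ½ [ Σᵢ fᵢᴬ min_{j∈B} d(i,j) + Σⱼ fⱼᴮ min_{i∈A} d(i,j) ],

  and βNTI = (βMNTD_obs − mean βMNTD_null) / sd βMNTD_null, the null
  obtained by shuffling tip labels across the full taxon pool (999
  permutations by default; the hot loop is in C++). Pairs with βNTI < −2
  are classified as homogeneous selection, βNTI > 2 as variable selection,
  |βNTI| < 2 as stochastic; per-stage fractions summarise all within-stage
  replicate pairs.
* **SparCC.** Log-ratio variances t_ij = Var log(x_i/x_j) are computed on
  scale-invariant pseudocounted proportions; basis variances ω² solve the
  sparsity-assumption linear system Σ_{j≠i} t_ij ≈ (D−1)ωᵢ² + Σ_{j≠i} ωⱼ²,
  with iterative exclusion of the strongest correlated pair; correlations
  ρ_ij = (ωᵢ² + ωⱼ² − t_ij) / (2 ωᵢ ωⱼ). Pseudo p-values come from
  permuting each taxon across samples (add-one estimator).
* **Networks and keystones.** Edges require |ρ| ≥ 0.65 and p ≤ 0.05 after
  filtering taxa to relative abundance > 0.1% present in ≥ 7 of 9
  replicates per stage. Modules come from deterministic greedy modularity
  maximisation; within-module connectivity Zi and among-module
  participation Pi classify nodes into peripherals, connectors (Zi ≤ 2.5,
  Pi > 0.62), module hubs (Zi > 2.5, Pi ≤ 0.62) and network hubs (both
  exceeded); non-peripheral nodes are keystone candidates.
* **Stability.** Robustness is the fraction of taxa surviving node removal
  (random 50%, 100 permutations, or a targeted ordered set) plus the
  secondary-extinction cascade that removes newly isolated nodes.
  Vulnerability is the largest relative drop in global efficiency
  (mean inverse shortest-path length) caused by deleting one node. The
  Ctr/Cyr contrast compares the network with and without its
  cyanobacterial nodes (Welch t-test over robustness replicates).

## Worked example

```r
library(crustnet)

tree <- simulate_tree(300, 101L)           # pure-birth reference phylogeny
cfg  <- simulation_config(n_taxa = 300, selection_regime = "homogeneous",
                          rng_seed = 42)
tab  <- simulate_communities(tree, cfg)    # 4 stages x 9 replicates
asm  <- stage_fractions(tab, tree, n_null = 999, rng_seed = 42)
print(asm)
#> <assembly_result> 144 sample pairs, n_null = 999
#>       stage homogeneous_selection variable_selection stochastic n_pairs
#> 1     algal             0.8888889                  0  0.1111111      36
#> 2 bare_sand             0.8888889                  0  0.1111111      36
#> 3    lichen             0.7222222                  0  0.2777778      36
#> 4      moss             0.6388889                  0  0.3611111      36
```

The planted regime is homogeneous selection and the modal classification in
every stage is indeed `homogeneous_selection` — replicate communities are
phylogenetically more similar than the tip-shuffling null expects, as
βNTI < −2 demands. A per-stage network then follows the filter → SparCC →
threshold chain:

```r
ft  <- filter_taxa(tab, stage = "bare_sand")  # >0.1% and >=7/9 replicates
res <- sparcc(ft$counts, n_boot = 100, rng_seed = 42)
net <- build_network(res, ft)                 # |rho| >= 0.65, p <= 0.05
cmp <- compare_with_without_group(net, rng_seed = 42)
print(cmp)
#> <stability_comparison>
#>   mean robustness  ctr: 0.1978  cyr: 0.0960 (welch p = 4.73e-06)
#>   vulnerability    ctr: 0.2987  cyr: 0.5238
```

Removing the two cyanobacterial nodes halves mean robustness (0.20 to
0.10) and nearly doubles vulnerability — this early-stage network depends
on its cyanobacteria.

A thin command-line wrapper with subcommands (`simulate`, `diversity`,
`assembly`, `correlate`, `network`, `stability`, `subnetwork`, `run-all`)
is installed at `system.file("cli/crustnet.R", package = "crustnet")`.

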