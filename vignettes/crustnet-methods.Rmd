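---
title: "Models and design choices behind crustnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind crustnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crustnet` chains four analyses that microbial ecologists apply to
stage-structured amplicon data: null-model phylogenetic community assembly
(βMNTD/βNTI), SparCC co-occurrence inference, Zi–Pi keystone detection,
and node-removal stability experiments. This vignette records the models,
their assumptions, the tunable parameters, and the design decisions taken
where the methodology is genuinely open.

## Community assembly: βMNTD, βNTI and the null model

For two communities with within-community relative abundances $f$ and
cophenetic distances $d$ from a rooted, branch-length-bearing tree,

$$\beta\mathrm{MNTD} = \tfrac12\Big[\sum_{i\in A} f^A_i \min_{j\in B} d_{ij}
 + \sum_{j\in B} f^B_j \min_{i\in A} d_{ij}\Big].$$

βNTI standardises the observed value against a null in which tip labels
are shuffled across the *full* taxon pool of the table being analysed:
richness and abundances are preserved, phylogenetic relationships are
randomised. This is the standard null of the Stegen framework; one shuffle
ensemble is shared by all sample pairs of a table (the matrix-shuffle
null), which is both conventional and what makes 999 permutations
affordable — the βMNTD kernel is implemented in C++ and evaluates all
pairs for all permutations in seconds at the package's default problem
sizes (200–300 taxa, 36 samples).

Decisions worth knowing:

* **Abundance weighting** is on by default (`weighted = TRUE`);
  presence/absence is available.
* **Classification** uses strict inequalities: βNTI < −2 homogeneous
  selection, > 2 variable selection, everything else (including exactly
  ±2) stochastic. Non-finite values are reported as `unclassified` and
  excluded from stage fractions.
* **Degenerate pairs.** If two samples contain exactly the same taxon set,
  every nearest-taxon distance is zero under *any* relabelling, the null
  distribution collapses, and βNTI is undefined; the package returns `NaN`
  with a warning rather than forcing a sign onto 0/0.
* **Scope of pairs.** Fractions are computed over within-stage replicate
  pairs (36 per stage for 9 replicates); `all_pairs = TRUE` adds
  between-stage pairs to the pair table, which is where the variable
  regime's phylogenetic turnover appears when each stage has its own
  anchor clade.
* βNTI is invariant to uniform rescaling of branch lengths (observed and
  null scale together); a property test asserts this.

## SparCC: compositional correlation

Sequencing yields compositions, so ordinary correlations of relative
abundances are distorted. SparCC works from log-ratio variances
$t_{ij} = \mathrm{Var}\,\log(x_i/x_j)$, which are invariant to per-sample
totals, and solves the sparsity-assumption system
$\sum_{j\neq i} t_{ij} \approx (D-1)\,\omega_i^2 + \sum_{j\neq i}\omega_j^2$
for basis variances, giving
$\rho_{ij} = (\omega_i^2+\omega_j^2-t_{ij})/(2\,\omega_i\,\omega_j)$,
clipped to $[-1, 1]$.

* **Zero handling.** Counts are converted to proportions first, then the
  pseudocount is applied at a fixed reference depth
  ($p_i = (q_i T + c)/(T + Dc)$, $T = 10^4$, $c = 1$). This reproduces
  the familiar "+1 pseudocount" at depth $T$ while keeping the whole chain
  *exactly* invariant to per-sample rescaling of the counts — the defining
  compositional property, asserted to $10^{-9}$ in the tests. A stochastic
  Dirichlet-resampling variant was deliberately not used: a single
  deterministic transform is testable and reproducible.
* **Exclusion heuristic.** Up to 10 rounds, the strongest-|ρ| pair above
  0.1 is removed from the basis system and the variances re-solved,
  mirroring the original SparCC heuristic; exclusion stops early rather
  than leave any taxon with fewer than two partners or an unsolvable
  system. The minimum taxon count is 3 (the exactly determined
  three-equation system); identifiability from the sparsity assumption is
  weak below 4 taxa, and small systems (< ~15 taxa) visibly saturate —
  networks should be built from adequately sized taxon sets.
* **p-values.** Each of `n_boot` (default 100) permutations shuffles every
  taxon independently across samples, destroying association while
  preserving marginals; the two-sided add-one estimator
  $p = (1+\#\{|\rho_b| \ge |\rho_{obs}|\})/(n_{boot}+1)$ never returns 0.
  No multiple-testing correction is applied by default because the
  customary edge filter is a raw $p \le 0.05$; BH correction can be
  applied downstream if desired.
* **Recovery.** At 100 samples and depth 50 000, planted basis
  correlations of magnitude 0.6–0.9 are recovered within 0.15 and the
  background stays below 0.1 mean |ρ| (asserted in the acceptance tests).

## Networks, modules and keystones

Taxa enter a stage's network if their overall relative abundance exceeds
0.1% (strict) and they occur in at least 7 of the stage's replicates;
edges require $|\rho| \ge 0.65$ and $p \le 0.05$ (inclusive, magnitudes so
negative co-occurrences pass), with the sign kept as an attribute.
Isolated nodes are dropped. Module detection uses greedy modularity
maximisation (Clauset–Newman–Moore, via igraph), chosen because it is
deterministic — reruns give identical partitions without managing solver
seeds. Zi and Pi follow the usual definitions (within-module degree
z-score; one minus the Herfindahl concentration of a node's edges across
modules), with Zi = 0 for zero-spread modules and Zi = Pi = 0 for isolated
nodes. Role thresholds are Zi 2.5 and Pi 0.62.

## Stability: robustness and vulnerability

Robustness = surviving fraction of the original nodes after (i) removing a
specified node set and (ii) the secondary-extinction cascade that deletes
nodes whose degree has dropped to zero. The cascade is unweighted — the
abundance-weighted variant of the species-loss framework is out of scope —
and is idempotent (removing isolated nodes cannot isolate others), which a
property test asserts. Random schemes remove ⌈fraction·N⌉ nodes
(default 50%, 100 permutations), optionally restricted to a node class
such as the cyanobacteria; targeted schemes take an ordered set and report
the stepwise curve. Vulnerability is
$\max_i (E - E_{-i})/E$ with $E$ the mean inverse shortest-path length
over unordered pairs (disconnected pairs contribute 0).

The Ctr/Cyr contrast builds the without-group network by deleting flagged
nodes, their incident edges, and any newly isolated nodes — identical to
rebuilding from the same correlation matrix without those taxa — and
compares robustness replicate distributions with a two-sided Welch t-test
(Mann–Whitney by flag; the choice matters little at 100 replicates).

## The synthetic-data generator

The generator exists so that every downstream stage has inputs with known
ground truth. It emulates the study design — 4 successional stages × 9
replicates, a tagged cyanobacterial subset (default 20% of taxa),
heavy-tailed abundances (log-normal, mean-log uniform on
$[\log 10, \log 1000]$, sd-log 1), exact multinomial depth per sample — on
a pure-birth (Yule) phylogeny with unit rate.

**Selection regimes.** Inclusion probability follows a logistic gate on a
taxon's cophenetic-distance *rank* from an anchor: ceiling 0.85, floor
0.01, midpoint at the nearest 15% of the tree, decay rate
`selection_strength` (default 20). The anchor is chosen
deterministically as the tip with the most compact 15%-neighbourhood —
selection acts on a coherent clade, and an anchor astride deep splits
would dilute the planted signal. The `homogeneous` regime shares one
anchor across stages; `variable` picks per-stage anchors that are far
apart relative to their diffuseness; `neutral` includes every taxon at a
flat 0.4. Selection also suppresses the *abundance* of disfavoured taxa
(fitness ∝ inclusion probability): without this, rare phylogenetically
distant "tourists" dominate the non-shared taxon set and bias βNTI
upward. The ceiling of 0.85 is a deliberate compromise: high enough that
favoured taxa recur in ≥ 7 of 9 replicates (feeding the network-stage
prevalence filter), low enough that replicate taxon sets keep turning
over, which is what the βNTI null reads. Under these defaults the
homogeneous regime yields mean within-stage βNTI ≈ −2 to −2.5 and
homogeneous selection as the modal class at 200–300 taxa; recovery
degrades below `selection_strength` ≈ 10 as the gate flattens toward the
neutral rate.

**Replicate covariation.** A latent environmental gradient (one normal
factor per sample, sd 0.6) with discrete per-taxon loadings (±0.8 or 0)
induces blocks of strongly co-varying taxa — the signal co-occurrence
networks are built from. Continuous loadings were tried and rejected:
they spread correlation strength thinly so that almost no pair cleared
the 0.65 edge threshold from 9 replicates.

**Planted correlations.** `simulate_correlated_counts` uses a Gaussian
copula: the requested correlation matrix (repaired to the nearest
positive-semidefinite correlation matrix by eigenvalue clipping at
$10^{-10}$) correlates the log-scale basis abundances, which is exactly
the quantity SparCC estimates — so the planted matrix is the ground truth
without approximation. Compositional closure and multinomial sampling then
distort the observable counts in precisely the way SparCC must undo.

**Planted keystones.** `plant_keystone_network` overlays deterministic
wiring on a modular Bernoulli graph (within 0.6, between 0.01 by
default): one hub per module wired to its whole module (high Zi), and
connectors wired to a fixed fraction of every module (high Pi). For the
with/without-group stability fixture, sparser modules (within 0.2) and
four connectors at 50% coverage are used instead, because in dense
modules almost no node is isolated by 50% random removal and group
removal would have nothing to degrade.

**What the generator does not emulate.** Real amplicon data have taxon
numbers in the thousands, overdispersion beyond multinomial, chimeras and
primer artifacts, patchy taxonomy, and phylogenetic signal in abundances
themselves. Passing tests therefore demonstrate that the *methods
recover planted structure under the stated model*, not that any
biological conclusion transfers to a particular real dataset.

## Numerical and interface choices

* One global integer seed is split hierarchically per sub-generator
  (multiplicative hash of a string key), so adding draws to one component
  never perturbs another; every function is a pure function of
  (inputs, seed).
* Rarefaction subsamples without replacement and *drops* samples below
  the target depth (with a warning) — the common practice; the default
  pipeline depth of 1648 reads matches the customary cyanobacterial-table
  depth, and rarefaction is optional (`rarefaction_depth = NULL`).
* Shannon uses natural logarithms; the ACE rare/abundant cutoff is 10;
  when every rare taxon is a singleton ACE is undefined and Chao1 is
  returned with a warning.
* Negative basis-variance solutions are floored at $10^{-8}$ with a
  warning; SparCC correlations are clipped to $[-1, 1]$.
* Problem sizes used by the test-suite and acceptance runs — 200–300
  taxa, 36 samples, 999 null permutations, 100 bootstraps, 100 removal
  permutations — were chosen as the smallest sizes at which all planted
  structure is comfortably recoverable; the βMNTD C++ kernel makes the
  null model the only stage that would otherwise be slow in R.
* Outputs are plain TSV/GraphML/JSON only; the run manifest records
  parameters, seed, package version and input checksums, making every
  result bundle reproducible from the manifest alone.

## Known limitations

* SparCC p-values from 9 replicates are coarse (minimum 1/101 at 100
  bootstraps) and small taxon sets saturate the estimator; per-stage
  networks from few replicates should be read qualitatively.
* The βNTI magnitude depends on tree geometry; on very unbalanced random
  trees the compactness-based anchor mitigates but does not remove this.
* The stochastic class is not partitioned further (no Raup–Crick /
  dispersal-limitation split), and RCbray is intentionally absent.
* Module detection maximises modularity greedily; resolution-limit
  caveats of modularity apply.
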