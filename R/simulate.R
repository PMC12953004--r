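#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators.  Defaults emulate
#' the sampling design of a four-stage biocrust chronosequence (bare sand,
#' algal, lichen and moss crust) with nine field replicates per stage.
#'
#' @param n_taxa number of taxa (>= 10).
#' @param n_stages number of successional stages.
#' @param n_replicates replicates per stage (>= 3).
#' @param seq_depth sequencing reads per sample (multinomial total).
#' @param cyano_fraction proportion of taxa tagged as cyanobacteria.
#' @param selection_regime one of `"homogeneous"`, `"variable"`, `"neutral"`:
#'   the community-assembly regime planted into the communities.
#' @param selection_strength non-negative decay rate of taxon-inclusion
#'   probability with phylogenetic distance from the regime's anchor taxon;
#'   ignored under the neutral regime.
#' @param basis_correlations `NULL`, or a data.frame/matrix with columns
#'   (`taxon_i`, `taxon_j`, `rho`) of planted latent (basis) correlations,
#'   `|rho| <= 1`; taxa given as integer indices or taxon IDs.
#' @param rng_seed integer seed; all generators are pure functions of
#'   (config, seed).
#'
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_taxa = 200, n_stages = 4, n_replicates = 9,
                              seq_depth = 20000, cyano_fraction = 0.2,
                              selection_regime = c("neutral", "homogeneous",
                                                   "variable"),
                              selection_strength = 20,
                              basis_correlations = NULL, rng_seed = NULL) {
  selection_regime <- match.arg(selection_regime)
  if (n_taxa < 10) abort_arg("n_taxa must be >= 10")
  if (n_replicates < 3) abort_arg("n_replicates must be >= 3")
  if (seq_depth <= 0) abort_arg("seq_depth must be positive")
  if (cyano_fraction < 0 || cyano_fraction > 1)
    abort_arg("cyano_fraction must be in [0, 1]")
  if (selection_strength < 0) abort_arg("selection_strength must be >= 0")
  if (!is.null(basis_correlations)) {
    bc <- as.data.frame(basis_correlations)
    names(bc) <- c("taxon_i", "taxon_j", "rho")
    if (any(abs(bc$rho) > 1)) abort_arg("planted |rho| must be <= 1")
    basis_correlations <- bc
  }
  structure(list(n_taxa = as.integer(n_taxa), n_stages = as.integer(n_stages),
                 n_replicates = as.integer(n_replicates),
                 seq_depth = as.integer(seq_depth),
                 cyano_fraction = cyano_fraction,
                 selection_regime = selection_regime,
                 selection_strength = selection_strength,
                 basis_correlations = basis_correlations,
                 rng_seed = rng_seed),
            class = "simulation_config")
}

#' Simulate a rooted phylogeny
#'
#' Pure-birth (Yule) tree with unit speciation rate: rooted, bifurcating,
#' strictly positive branch lengths.  Tips are labelled `otu_0001` ...
#'
#' @param n_taxa number of tips (>= 2).
#' @param rng_seed integer seed (deterministic output for a fixed seed).
#' @return an [ape::phylo] tree.
#' @export
simulate_tree <- function(n_taxa, rng_seed = NULL) {
  if (n_taxa < 2) abort_arg("n_taxa must be >= 2")
  with_seed(rng_seed, {
    tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  })
  # guard against zero-length branches from ties in event times
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  tree$tip.label <- sprintf("otu_%04d", seq_len(n_taxa))
  tree
}

stage_names <- function(n_stages) {
  std <- c("bare_sand", "algal", "lichen", "moss")
  if (n_stages <= length(std)) std[seq_len(n_stages)]
  else c(std, sprintf("stage_%d", seq(length(std) + 1, n_stages)))
}

cyano_families <- c("Chroococcidiopsidaceae", "Microcoleaceae", "Nostocaceae",
                    "Coleofasciculaceae", "Symphyonemataceae", "Wilmottiaceae")

# taxon metadata shared by the community generators: a cyanobacterial subset
# plus bacterial and fungal taxa with synthetic family labels
make_taxon_meta <- function(taxa, cyano_fraction, seed) {
  n <- length(taxa)
  n_cy <- round(cyano_fraction * n)
  with_seed(split_seed(seed, "taxonomy"), {
    cy <- sort(sample.int(n, n_cy))
    is_cy <- seq_len(n) %in% cy
    kingdom <- ifelse(is_cy, "Bacteria",
                      ifelse(stats::runif(n) < 0.7, "Bacteria", "Fungi"))
    phylum <- ifelse(is_cy, "Cyanobacteria",
                     paste0("Phylum_", sample.int(8, n, replace = TRUE)))
    family <- character(n)
    family[is_cy] <- sample(cyano_families, n_cy, replace = TRUE)
    family[!is_cy] <- paste0("Family_", sample.int(25, n - n_cy,
                                                   replace = TRUE))
    # a sprinkling of unclassified lineages, as in real amplicon tables
    ncy_idx <- which(!is_cy)
    family[ncy_idx[stats::runif(length(ncy_idx)) < 0.05]] <- NA_character_
  })
  data.frame(taxon_id = taxa, kingdom = kingdom, phylum = phylum,
             family = family, is_cyanobacterium = is_cy,
             stringsAsFactors = FALSE)
}

#' Simulate stage-structured communities under a known assembly regime
#'
#' Generates a count table of `n_stages * n_replicates` samples.  Taxon pools
#' are drawn from inclusion probabilities that decay with cophenetic distance
#' from an anchor taxon (rate = `selection_strength`): the `homogeneous`
#' regime shares one anchor across all stages (communities phylogenetically
#' clustered and mutually similar -> homogeneous selection downstream); the
#' `variable` regime uses a different, phylogenetically distant anchor per
#' stage (strong between-stage turnover); the `neutral` regime includes taxa
#' uniformly at random per sample.  Included taxa get heavy-tailed log-normal
#' abundances with stage- and replicate-level multiplicative noise, and each
#' sample is a multinomial draw of exactly `seq_depth` reads.
#'
#' @param tree a phylogeny whose tips cover the configured taxa.
#' @param config a [simulation_config].
#' @return an [abundance_table]; the attribute `"anchors"` records the anchor
#'   taxon used per stage (ground truth for regime recovery).
#' @export
simulate_communities <- function(tree, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$seq_depth <= 0) abort_arg("seq_depth must be positive")
  if (length(tree$tip.label) < config$n_taxa)
    abort_arg("tree must have at least n_taxa tips")
  taxa <- tree$tip.label[seq_len(config$n_taxa)]
  n <- config$n_taxa
  seed <- config$rng_seed

  d <- ape::cophenetic.phylo(tree)[taxa, taxa]
  dn <- d / mean(d[upper.tri(d)])

  # Anchors are chosen deterministically from the tree: selection acts on a
  # coherent clade, so the anchor is the tip whose 15%-neighbourhood is the
  # most phylogenetically compact.  The variable regime additionally wants
  # stage anchors far apart, so subsequent anchors maximise (distance to
  # anchors already chosen) / (neighbourhood diffuseness).
  k_nb <- max(2L, ceiling(0.15 * n))
  compact <- apply(dn, 2, function(col) mean(sort(col)[2:k_nb]))
  a1 <- which.min(compact)
  anchors <- if (config$selection_regime == "variable" &&
                 config$n_stages > 1) {
    anc <- a1
    for (k in seq_len(config$n_stages - 1)) {
      dmin <- apply(dn[, anc, drop = FALSE], 1, min)
      anc <- c(anc, which.max(dmin / compact))
    }
    anc
  } else rep(a1, config$n_stages)

  incl_target <- 0.4  # mean per-sample richness fraction (neutral regime)
  # logistic gate on the distance *rank* from the anchor: high strength
  # approaches a sharp cutoff admitting roughly the nearest 15% of the tree
  # (a tight clade neighbourhood) at inclusion probability ~0.85 — high
  # enough that favoured taxa recur across most replicates, low enough that
  # replicate taxon sets keep turning over inside the clade; a small floor
  # lets occasional distant taxa through
  incl_prob <- function(anchor) {
    if (config$selection_regime == "neutral")
      return(rep(incl_target, n))
    r <- rank(dn[, anchor], ties.method = "first") / n
    0.01 + 0.84 / (1 + exp(config$selection_strength * (r - 0.15)))
  }

  with_seed(split_seed(seed, "base-abundance"), {
    meanlog <- stats::runif(n, log(10), log(1000))
    stage_eff <- matrix(stats::rnorm(n * config$n_stages, 0, 0.5), n,
                        config$n_stages)
    # a latent environmental gradient with per-taxon loadings induces
    # correlated abundance fluctuations across replicates — the kind of
    # co-variation co-occurrence networks are built from
    # discrete loadings: responsive guilds (positive or negative) and
    # indifferent taxa, giving blocks of strongly co-varying taxa
    env_loading <- sample(c(-0.8, 0, 0.8), n, replace = TRUE,
                          prob = c(0.3, 0.4, 0.3))
  })

  stages <- stage_names(config$n_stages)
  counts <- matrix(0L, n, config$n_stages * config$n_replicates)
  rownames(counts) <- taxa
  ids <- character(ncol(counts))
  smeta <- vector("list", ncol(counts))
  col <- 0L
  for (s in seq_len(config$n_stages)) {
    p_incl <- incl_prob(anchors[s])
    fitness <- p_incl / max(p_incl)  # selection suppresses abundance too
    for (r in seq_len(config$n_replicates)) {
      col <- col + 1L
      with_seed(split_seed(seed, sprintf("sample-%d-%d", s, r)), {
        pool <- stats::runif(n) < p_incl
        if (!any(pool)) pool[anchors[s]] <- TRUE
        env <- stats::rnorm(1, 0, 0.6)
        w <- exp(meanlog + stage_eff[, s] + env_loading * env +
                   stats::rnorm(n, 0, 0.2)) * fitness
        w[!pool] <- 0
        counts[, col] <- as.integer(
          stats::rmultinom(1, config$seq_depth, w))
      })
      ids[col] <- sprintf("%s_%02d", stages[s], r)
      smeta[[col]] <- data.frame(sample_id = ids[col], stage = stages[s],
                                 replicate = r, stringsAsFactors = FALSE)
    }
  }
  colnames(counts) <- ids
  tab <- abundance_table(counts, do.call(rbind, smeta),
                         make_taxon_meta(taxa, config$cyano_fraction, seed))
  attr(tab, "anchors") <- taxa[anchors]
  tab
}

# nearest positive-semidefinite repair by eigenvalue clipping, then rescale
# back to a correlation matrix
nearest_psd_corr <- function(R, eps = 1e-10) {
  e <- eigen(R, symmetric = TRUE)
  if (all(e$values >= eps)) return(R)
  v <- pmax(e$values, eps)
  R2 <- e$vectors %*% (v * t(e$vectors))
  R2 <- stats::cov2cor(R2)
  (R2 + t(R2)) / 2
}

#' Simulate compositional counts with planted basis correlations
#'
#' Latent (basis) abundances are log-normal with the planted correlation
#' matrix on the log scale (Gaussian copula): per-taxon `meanlog` uniform in
#' `[log 10, log 1000]`, `sdlog = 1`.  Each sample's basis abundances are
#' normalised to proportions and multinomially sampled at `seq_depth` reads —
#' the compositional distortion SparCC is designed to undo.  The requested
#' correlation matrix is repaired to the nearest positive-semidefinite
#' correlation matrix by eigenvalue clipping before sampling.
#'
#' @param config a [simulation_config]; `basis_correlations` holds the
#'   planted pairs; samples = `n_stages * n_replicates`.
#' @return list with `table` (an [abundance_table]) and `rho_true` (the
#'   ground-truth basis correlation matrix actually used, after repair).
#' @export
simulate_correlated_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_taxa
  n_samples <- config$n_stages * config$n_replicates
  taxa <- sprintf("otu_%04d", seq_len(n))

  R <- diag(n)
  if (!is.null(config$basis_correlations)) {
    bc <- config$basis_correlations
    ii <- if (is.numeric(bc$taxon_i)) as.integer(bc$taxon_i)
          else match(bc$taxon_i, taxa)
    jj <- if (is.numeric(bc$taxon_j)) as.integer(bc$taxon_j)
          else match(bc$taxon_j, taxa)
    if (anyNA(ii) || anyNA(jj) || any(ii == jj))
      abort_arg("invalid planted correlation pairs")
    R[cbind(ii, jj)] <- bc$rho
    R[cbind(jj, ii)] <- bc$rho
    R <- nearest_psd_corr(R)
    if (any(!is.finite(R))) abort_arg("planted covariance not repairable")
  }
  U <- tryCatch(chol(R + diag(1e-9, n)),
                error = function(e) abort_arg("planted covariance not ",
                                              "repairable: ", e$message))
  seed <- config$rng_seed
  with_seed(split_seed(seed, "copula"), {
    meanlog <- stats::runif(n, log(10), log(1000))
    Z <- matrix(stats::rnorm(n_samples * n), n_samples, n) %*% U
    basis <- exp(sweep(Z, 2, meanlog, "+"))  # samples x taxa
    counts <- apply(basis, 1, function(b)
      as.integer(stats::rmultinom(1, config$seq_depth, b / sum(b))))
  })
  rownames(counts) <- taxa
  stages <- stage_names(config$n_stages)
  sm <- data.frame(
    sample_id = sprintf("s_%03d", seq_len(n_samples)),
    stage = rep(stages, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), config$n_stages),
    stringsAsFactors = FALSE)
  colnames(counts) <- sm$sample_id
  dimnames(R) <- list(taxa, taxa)
  list(table = abundance_table(counts, sm,
                               make_taxon_meta(taxa, config$cyano_fraction,
                                               seed)),
       rho_true = R)
}

#' Plant a modular network with known keystone nodes
#'
#' Random modular graph: dense Bernoulli edges within modules, sparse between.
#' One designated module hub per module is rewired to a large fraction of its
#' own module (high within-module degree Zi); designated connectors are
#' rewired to a fixed fraction of members of *every* module (high
#' participation Pi).  Ground-truth roles are stored as the vertex attribute
#' `truth_role`, and connectors can optionally be flagged as the focal
#' cyanobacterial group for with/without-group contrasts.
#'
#' @param n_nodes total nodes (>= `n_modules`).
#' @param n_modules number of planted modules (>= 2).
#' @param rng_seed integer seed.
#' @param within_p,between_p within-/between-module edge probabilities.
#' @param n_connectors number of planted connectors.
#' @param hub_within_frac fraction of its module a planted hub connects to.
#' @param connector_frac fraction of every module a connector connects to.
#' @param flag_connectors if `TRUE`, connectors carry
#'   `is_cyanobacterium = TRUE`.
#' @return an [igraph::igraph] with vertex attributes `name`, `module_truth`,
#'   `truth_role`, `kingdom`, `is_cyanobacterium` and edge attributes `rho`,
#'   `sign`, `p`.
#' @export
plant_keystone_network <- function(n_nodes, n_modules, rng_seed = NULL,
                                   within_p = 0.6, between_p = 0.01,
                                   n_connectors = 1, hub_within_frac = 1,
                                   connector_frac = 0.25,
                                   flag_connectors = FALSE) {
  if (n_modules < 2 || n_nodes < n_modules)
    abort_arg("need n_nodes >= n_modules >= 2")
  module <- sort(rep_len(seq_len(n_modules), n_nodes))
  nm <- sprintf("n_%03d", seq_len(n_nodes))

  with_seed(split_seed(rng_seed %||% 0L, "keystone-net"), {
    hubs <- vapply(seq_len(n_modules), function(m)
      which(module == m)[1], integer(1))
    pool <- setdiff(seq_len(n_nodes), hubs)
    connectors <- sort(sample(pool, n_connectors))
    special <- c(hubs, connectors)

    adj <- matrix(FALSE, n_nodes, n_nodes)
    same <- outer(module, module, "==")
    pmat <- ifelse(same, within_p, between_p)
    r <- matrix(stats::runif(n_nodes^2), n_nodes)
    adj[upper.tri(adj)] <- (r < pmat)[upper.tri(adj)]
    adj <- adj | t(adj)
    # designated nodes get fully deterministic wiring
    adj[special, ] <- FALSE
    adj[, special] <- FALSE
    for (h in hubs) {
      own <- setdiff(which(module == module[h]), special)
      k <- max(2L, ceiling(hub_within_frac * length(own)))
      tgt <- sample(own, min(k, length(own)))
      adj[h, tgt] <- TRUE
      adj[tgt, h] <- TRUE
    }
    for (cn in connectors) {
      for (m in seq_len(n_modules)) {
        own <- setdiff(which(module == m), special)
        k <- max(1L, ceiling(connector_frac * length(own)))
        tgt <- sample(own, min(k, length(own)))
        adj[cn, tgt] <- TRUE
        adj[tgt, cn] <- TRUE
      }
    }
    diag(adj) <- FALSE
  })

  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- nm
  igraph::V(g)$module_truth <- module
  role <- rep("peripheral", n_nodes)
  role[hubs] <- "module_hub"
  role[connectors] <- "connector"
  igraph::V(g)$truth_role <- role
  igraph::V(g)$kingdom <- "Bacteria"
  igraph::V(g)$is_cyanobacterium <- flag_connectors &
    (role == "connector")
  igraph::V(g)$mean_rel_abund <- 1 / n_nodes
  igraph::E(g)$rho <- 0.8
  igraph::E(g)$sign <- "+"
  igraph::E(g)$p <- 0.001
  g
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the TSV/newick/JSON bundle every downstream stage consumes: count
#' table, taxonomy, sample metadata, tree, and a ground-truth JSON recording
#' the planted regime and correlations.
#'
#' @param dir output directory (created if needed).
#' @param config a [simulation_config].
#' @return invisibly, a named list of file paths.
#' @export
write_synthetic_fixture <- function(dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(config$n_taxa, split_seed(config$rng_seed, "tree"))
  tab <- simulate_communities(tree, config)
  paths <- list(counts = file.path(dir, "counts.tsv"),
                taxonomy = file.path(dir, "taxonomy.tsv"),
                metadata = file.path(dir, "metadata.tsv"),
                tree = file.path(dir, "tree.nwk"),
                truth = file.path(dir, "truth.json"))
  write_abundance_table(tab, paths$counts, paths$taxonomy, paths$metadata)
  ape::write.tree(tree, paths$tree)
  truth <- list(selection_regime = config$selection_regime,
                selection_strength = config$selection_strength,
                anchors = attr(tab, "anchors"),
                planted_correlations = config$basis_correlations,
                rng_seed = config$rng_seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(paths)
}
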