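#' Filter taxa for network construction
#'
#' Keeps taxa whose overall relative abundance is strictly greater than
#' `min_rel_abund` and that are present (nonzero) in at least
#' `min_prevalence` replicates of the focal stage.  Defaults mirror the
#' customary "> 0.1% and present in >= 7 of 9 replicates" inclusion rule.
#'
#' @param table an [abundance_table].
#' @param stage focal stage; `NULL` applies the rule over all samples.
#' @param min_rel_abund relative-abundance threshold (strict `>`).
#' @param min_prevalence minimum number of replicates with nonzero counts.
#' @return filtered [abundance_table].
#' @export
filter_taxa <- function(table, stage = NULL, min_rel_abund = 0.001,
                        min_prevalence = 7) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.null(stage)) table <- subset_table(table, stage = stage)
  counts <- table$counts
  rel <- rowSums(counts) / sum(counts)
  prev <- rowSums(counts > 0)
  keep <- rel > min_rel_abund & prev >= min_prevalence
  if (!any(keep)) abort_arg("no taxa pass the abundance/prevalence filter")
  out <- subset_table(table, taxa = rownames(counts)[keep])
  empty <- colSums(out$counts) == 0
  if (any(empty)) {
    warning(sum(empty), " sample(s) without reads on the retained taxa ",
            "dropped")
    out <- subset_table(out, samples = colnames(out$counts)[!empty])
  }
  out
}

#' Build a co-occurrence network from SparCC results
#'
#' An undirected edge links taxa i and j iff `|rho_ij| >= r_min` and
#' `p_ij <= p_max` (inclusive thresholds); nodes left without any edge are
#' dropped.  Edge sign records the direction of the association; node
#' attributes carry kingdom, family, the cyanobacterial flag and mean
#' relative abundance.
#'
#' @param corr a `sparcc_result` with `rho` and `pval`.
#' @param table the [abundance_table] the correlations were computed from
#'   (source of node attributes).
#' @param r_min correlation-magnitude threshold.
#' @param p_max p-value threshold.
#' @return an [igraph::igraph].
#' @export
build_network <- function(corr, table, r_min = 0.65, p_max = 0.05) {
  rho <- corr$rho
  pval <- corr$pval
  if (is.null(pval)) abort_arg("correlation result has no p-values")
  if (!isTRUE(all.equal(rho, t(rho)))) abort_arg("rho must be symmetric")
  adj <- abs(rho) >= r_min & pval <= p_max
  diag(adj) <- FALSE
  if (!any(adj)) abort_arg("no edges pass the thresholds")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  el <- igraph::as_edgelist(g, names = TRUE)
  igraph::E(g)$rho <- rho[el]
  igraph::E(g)$sign <- ifelse(rho[el] >= 0, "+", "-")
  igraph::E(g)$p <- pval[el]
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)

  tm <- table$taxon_meta
  ix <- match(igraph::V(g)$name, tm$taxon_id)
  igraph::V(g)$kingdom <- tm$kingdom[ix] %||% NA_character_
  if ("family" %in% names(tm)) igraph::V(g)$family <- tm$family[ix]
  igraph::V(g)$is_cyanobacterium <-
    (tm$is_cyanobacterium %||% logical(nrow(tm)))[ix]
  rel <- rowMeans(relative_abundance(table))
  igraph::V(g)$mean_rel_abund <- rel[igraph::V(g)$name]
  g
}

#' Detect network modules
#'
#' Greedy agglomerative modularity maximisation (Clauset-Newman-Moore),
#' which is deterministic — identical input graphs give identical
#' partitions; the seed argument exists only for interface symmetry with
#' the stochastic stages.
#'
#' @param net an [igraph::igraph] with >= 1 edge.
#' @param rng_seed ignored (the algorithm is deterministic).
#' @return named integer vector: module id per node.
#' @export
detect_modules <- function(net, rng_seed = NULL) {
  if (igraph::ecount(net) == 0) abort_arg("network has no edges")
  cl <- igraph::cluster_fast_greedy(net, weights = NULL)
  m <- igraph::membership(cl)
  stats::setNames(as.integer(m), igraph::V(net)$name)
}

#' Topological summary of a network
#'
#' @param net an [igraph::igraph].
#' @param membership optional module partition (detected if missing).
#' @return one-row data.frame: `nodes`, `edges`, `mean_degree`, `density`,
#'   `clustering`, `modularity`, `positive_edge_fraction`.
#' @export
topology_summary <- function(net, membership = NULL) {
  if (igraph::ecount(net) == 0) abort_arg("network has no edges")
  if (is.null(membership)) membership <- detect_modules(net)
  data.frame(
    nodes = igraph::vcount(net),
    edges = igraph::ecount(net),
    mean_degree = mean(igraph::degree(net)),
    density = igraph::edge_density(net),
    clustering = igraph::transitivity(net, type = "global"),
    modularity = igraph::modularity(net, membership[igraph::V(net)$name]),
    positive_edge_fraction =
      if (!is.null(igraph::E(net)$sign))
        mean(igraph::E(net)$sign == "+") else NA_real_)
}

#' Within-module (Zi) and among-module (Pi) connectivity
#'
#' `Zi = (k_i,m - mean_m) / sd_m`, the z-score of node i's within-module
#' degree against the nodes of its own module (0 when the module's spread is
#' zero); `Pi = 1 - sum_s (k_is / k_i)^2`, the participation of i's edges
#' across modules.  Isolated nodes get `Zi = Pi = 0`.
#'
#' @param net an [igraph::igraph].
#' @param membership module partition covering all nodes (from
#'   [detect_modules()]).
#' @return data.frame with `taxon`, `module`, `degree`, `zi`, `pi`.
#' @export
zipi <- function(net, membership) {
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% names(membership)))
    abort_arg("membership must cover all nodes")
  mem <- membership[nodes]
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE) > 0
  deg <- rowSums(adj)
  mods <- sort(unique(mem))
  # k_is: edges from node i into module s
  k_mod <- vapply(mods, function(s)
    rowSums(adj[, mem == s, drop = FALSE]), numeric(length(nodes)))
  k_within <- k_mod[cbind(seq_along(nodes), match(mem, mods))]
  zi <- numeric(length(nodes))
  for (s in mods) {
    in_s <- mem == s
    mu <- mean(k_within[in_s])
    sd_s <- stats::sd(k_within[in_s])
    zi[in_s] <- if (is.na(sd_s) || sd_s == 0) 0
                else (k_within[in_s] - mu) / sd_s
  }
  pi <- ifelse(deg == 0, 0, 1 - rowSums((k_mod / pmax(deg, 1))^2))
  data.frame(taxon = nodes, module = as.integer(mem), degree = deg,
             zi = zi, pi = pi, row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify node topological roles from Zi and Pi
#'
#' Connectors: `zi <= 2.5, pi > 0.62`; module hubs: `zi > 2.5, pi <= 0.62`;
#' network hubs: `zi > 2.5, pi > 0.62`; everything else peripheral.
#' Non-peripheral nodes are the keystone candidates.
#'
#' @param zipi_df data.frame from [zipi()] (columns `zi`, `pi`), or a
#'   numeric vector `zi` together with `pi`.
#' @param pi numeric vector when `zipi_df` is a vector.
#' @param zi_threshold,pi_threshold role thresholds.
#' @return the input data.frame with columns `role` and `keystone` added
#'   (or a character vector for vector input).
#' @export
classify_roles <- function(zipi_df, pi = NULL, zi_threshold = 2.5,
                           pi_threshold = 0.62) {
  if (is.data.frame(zipi_df)) {
    zv <- zipi_df$zi; pv <- zipi_df$pi
  } else {
    zv <- zipi_df; pv <- pi
  }
  if (any(!is.finite(zv)) || any(!is.finite(pv)))
    abort_arg("zi and pi must be finite")
  role <- ifelse(zv > zi_threshold,
                 ifelse(pv > pi_threshold, "network_hub", "module_hub"),
                 ifelse(pv > pi_threshold, "connector", "peripheral"))
  if (is.data.frame(zipi_df)) {
    zipi_df$role <- role
    zipi_df$keystone <- role != "peripheral"
    zipi_df
  } else role
}

#' Export a network for Gephi and other tools
#'
#' Writes GraphML plus Gephi-style node and edge CSV tables.
#'
#' @param net an [igraph::igraph].
#' @param graphml_path,nodes_path,edges_path output paths.
#' @return invisibly, the paths.
#' @export
write_network <- function(net, graphml_path, nodes_path, edges_path) {
  igraph::write_graph(net, graphml_path, format = "graphml")
  va <- igraph::vertex_attr(net)
  nodes <- data.frame(Id = va$name, Label = va$name,
                      va[setdiff(names(va), "name")],
                      stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(nodes, nodes_path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  el <- igraph::as_edgelist(net)
  edges <- data.frame(Source = el[, 1], Target = el[, 2],
                      Type = "Undirected", igraph::edge_attr(net),
                      stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(edges, edges_path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(c(graphml_path, nodes_path, edges_path))
}
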