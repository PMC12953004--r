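# remove isolated survivors until none remain (secondary-extinction cascade);
# deleting a degree-0 node never changes another node's degree, so the loop
# terminates after the first effective pass — kept as a loop for clarity and
# the idempotence property
cascade <- function(g) {
  repeat {
    iso <- igraph::degree(g) == 0
    if (!any(iso)) return(g)
    g <- igraph::delete_vertices(g, which(iso))
  }
}

#' Network robustness under node removal
#'
#' For each permutation the specified nodes are removed, isolated survivors
#' are then removed by the secondary-extinction cascade, and robustness is
#' the proportion of the original nodes remaining.  `scheme = "random"`
#' removes a uniform sample of `ceiling(fraction * N)` nodes (optionally
#' restricted to a node class, e.g. the cyanobacterial nodes) and returns
#' `n_perm` replicate values; `scheme = "targeted"` removes a given ordered
#' node set one at a time and returns the stepwise robustness curve.
#'
#' @param net an [igraph::igraph].
#' @param scheme `"random"` or `"targeted"`.
#' @param fraction fraction of (eligible) nodes to remove (random scheme).
#' @param nodes ordered character vector of node names (targeted scheme),
#'   or the pool to sample from when `restrict_to` is unused.
#' @param restrict_to optional character vector: random removals are drawn
#'   from these nodes only.
#' @param n_perm number of permutations (random scheme).
#' @param rng_seed integer seed.
#' @return for `"random"`, a numeric vector of `n_perm` robustness values;
#'   for `"targeted"`, a data.frame with `step`, `removed`, `robustness`
#'   (non-increasing).
#' @export
robustness <- function(net, scheme = c("random", "targeted"),
                       fraction = 0.5, nodes = NULL, restrict_to = NULL,
                       n_perm = 100, rng_seed = NULL) {
  scheme <- match.arg(scheme)
  if (igraph::vcount(net) == 0) abort_arg("empty network")
  all_nodes <- igraph::V(net)$name
  n0 <- length(all_nodes)
  if (scheme == "targeted") {
    if (is.null(nodes)) abort_arg("targeted scheme needs an ordered node set")
    if (!all(nodes %in% all_nodes))
      abort_arg("removal set contains unknown nodes")
    g <- net
    out <- data.frame(step = seq_along(nodes), removed = nodes,
                      robustness = NA_real_, stringsAsFactors = FALSE)
    for (k in seq_along(nodes)) {
      if (nodes[k] %in% igraph::V(g)$name)
        g <- igraph::delete_vertices(g, nodes[k])
      g <- cascade(g)
      out$robustness[k] <- igraph::vcount(g) / n0
    }
    return(out)
  }
  pool <- restrict_to %||% all_nodes
  if (!all(pool %in% all_nodes))
    abort_arg("removal set contains unknown nodes")
  k <- min(ceiling(fraction * length(pool)), length(pool))
  with_seed(rng_seed, {
    vals <- vapply(seq_len(n_perm), function(i) {
      rm_nodes <- pool[sample.int(length(pool), k)]
      g <- cascade(igraph::delete_vertices(net, rm_nodes))
      igraph::vcount(g) / n0
    }, numeric(1))
  })
  vals
}

#' Network vulnerability
#'
#' Global efficiency `E` is the mean over unordered node pairs of the
#' inverse shortest-path length (0 for disconnected pairs).  Each node's
#' vulnerability is the relative efficiency drop caused by deleting it,
#' `V_i = (E - E_{-i}) / E`, and the network's vulnerability is the maximum
#' over nodes.
#'
#' @param net an [igraph::igraph] with >= 3 nodes.
#' @param per_node if `TRUE`, return the full per-node vector.
#' @return the network vulnerability (or a named per-node vector).
#' @export
vulnerability <- function(net, per_node = FALSE) {
  if (igraph::vcount(net) < 3) abort_arg("need >= 3 nodes")
  eff <- function(g) {
    n <- igraph::vcount(g)
    if (n < 2) return(0)
    d <- igraph::distances(g)
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    mean(inv)
  }
  E0 <- eff(net)
  if (E0 == 0) abort_arg("zero global efficiency: vulnerability undefined")
  v <- vapply(seq_len(igraph::vcount(net)), function(i)
    (E0 - eff(igraph::delete_vertices(net, i))) / E0, numeric(1))
  names(v) <- igraph::V(net)$name
  if (per_node) v else max(v)
}

#' Compare network stability with and without a focal taxon group
#'
#' The with-group network (Ctr) is the input; the without-group network
#' (Cyr) deletes the flagged nodes and their incident edges (then any newly
#' isolated nodes), exactly as if the group's taxa had been withheld from
#' the same correlation result.  Both networks get random-removal robustness
#' distributions (default 50% removal, 100 permutations) and vulnerability;
#' the robustness distributions are compared with a two-sided Welch t-test
#' (or Mann-Whitney).
#'
#' @param net the full network; vertex attribute `group_flag` marks the
#'   focal group.
#' @param group_flag name of a logical vertex attribute (default
#'   `is_cyanobacterium`).
#' @param fraction,n_perm random-removal parameters.
#' @param rng_seed integer seed.
#' @param test `"welch"` or `"wilcoxon"`.
#' @return a `stability_comparison` list: `robustness` (data.frame with
#'   columns `network`, `replicate`, `robustness`), `vulnerability` (named
#'   vector), `p_value`, `test`, `networks` (list with `ctr`, `cyr`).
#' @export
compare_with_without_group <- function(net, group_flag = "is_cyanobacterium",
                                       fraction = 0.5, n_perm = 100,
                                       rng_seed = NULL,
                                       test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  flag <- igraph::vertex_attr(net, group_flag)
  if (is.null(flag)) abort_arg("no vertex attribute '", group_flag, "'")
  flag <- as.logical(flag)
  if (!any(flag)) abort_arg("focal group is empty")
  cyr <- igraph::delete_vertices(net, which(flag))
  cyr <- cascade(cyr)
  if (igraph::vcount(cyr) == 0)
    abort_arg("removing the group empties the network")
  r_ctr <- robustness(net, "random", fraction = fraction, n_perm = n_perm,
                      rng_seed = split_seed(rng_seed %||% 0L, "ctr"))
  r_cyr <- robustness(cyr, "random", fraction = fraction, n_perm = n_perm,
                      rng_seed = split_seed(rng_seed %||% 0L, "cyr"))
  pv <- if (stats::sd(r_ctr) == 0 && stats::sd(r_cyr) == 0) {
    if (isTRUE(all.equal(mean(r_ctr), mean(r_cyr)))) 1 else 0
  } else if (test == "welch") {
    stats::t.test(r_ctr, r_cyr)$p.value
  } else {
    stats::wilcox.test(r_ctr, r_cyr, exact = FALSE)$p.value
  }
  structure(list(
    robustness = data.frame(
      network = rep(c("ctr", "cyr"), each = n_perm),
      replicate = rep(seq_len(n_perm), 2),
      robustness = c(r_ctr, r_cyr), stringsAsFactors = FALSE),
    vulnerability = c(ctr = vulnerability(net), cyr = vulnerability(cyr)),
    p_value = pv, test = test,
    networks = list(ctr = net, cyr = cyr)),
    class = "stability_comparison")
}

#' @export
print.stability_comparison <- function(x, ...) {
  rb <- tapply(x$robustness$robustness, x$robustness$network, mean)
  cat("<stability_comparison>\n")
  cat(sprintf("  mean robustness  ctr: %.4f  cyr: %.4f (%s p = %.3g)\n",
              rb["ctr"], rb["cyr"], x$test, x$p_value))
  cat(sprintf("  vulnerability    ctr: %.4f  cyr: %.4f\n",
              x$vulnerability["ctr"], x$vulnerability["cyr"]))
  invisible(x)
}

#' Extract the focal-group subnetwork
#'
#' Induced subgraph on the flagged nodes and their first neighbours, with a
#' summary of how the group is embedded: its share of prokaryotic
#' (bacterial, cyanobacteria included) nodes, the fraction of network nodes
#' connected to the group, and the positive/negative split of group-incident
#' edges by partner kingdom.
#'
#' @param net an [igraph::igraph].
#' @param group_flag logical vertex attribute marking the group.
#' @return list with `subnetwork` (igraph) and `summary` (one-row
#'   data.frame).
#' @export
extract_focal_subnetwork <- function(net, group_flag = "is_cyanobacterium") {
  flag <- as.logical(igraph::vertex_attr(net, group_flag))
  if (is.null(flag) || !any(flag)) abort_arg("focal group absent from network")
  gidx <- which(flag)
  nb <- unique(unlist(igraph::adjacent_vertices(net, gidx)))
  keep <- union(gidx, nb)
  sub <- igraph::induced_subgraph(net, keep)

  kingdom <- igraph::V(net)$kingdom
  prok <- sum(kingdom == "Bacteria", na.rm = TRUE)
  el <- igraph::as_edgelist(net)
  sgn <- igraph::E(net)$sign
  names(flag) <- igraph::V(net)$name
  kg <- stats::setNames(kingdom, igraph::V(net)$name)
  inc <- flag[el[, 1]] | flag[el[, 2]]
  partner <- ifelse(flag[el[, 1]], kg[el[, 2]], kg[el[, 1]])
  frac <- function(cond) {
    n <- sum(inc & cond, na.rm = TRUE)
    if (n == 0) return(NA_real_)
    sum(inc & cond & sgn == "+", na.rm = TRUE) / n
  }
  summary <- data.frame(
    group_nodes = length(gidx),
    group_share_of_prokaryotes = if (prok > 0) length(gidx) / prok
                                 else NA_real_,
    fraction_connected_to_group =
      length(setdiff(nb, gidx)) / max(igraph::vcount(net) - length(gidx), 1),
    positive_fraction_bacterial_partners = frac(partner == "Bacteria"),
    positive_fraction_fungal_partners = frac(partner == "Fungi"))
  list(subnetwork = sub, summary = summary)
}
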