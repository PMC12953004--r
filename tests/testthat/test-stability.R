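named_graph <- function(g, prefix = "v") {
  igraph::V(g)$name <- paste0(prefix, seq_len(igraph::vcount(g)))
  g
}

test_that("robustness closed forms hold on complete and star graphs", {
  k10 <- named_graph(igraph::make_full_graph(10))
  r <- robustness(k10, "random", fraction = 0.5, n_perm = 50, rng_seed = 1)
  expect_equal(r, rep(0.5, 50), ignore_attr = TRUE)

  s10 <- named_graph(igraph::make_star(10, mode = "undirected", center = 1))
  curve <- robustness(s10, "targeted", nodes = "v1")
  expect_equal(curve$robustness, 0)  # hub removal isolates every leaf
})

test_that("robustness curves never increase and stay in [0,1]", {
  set.seed(99)
  for (i in 1:20) {
    g <- named_graph(igraph::sample_gnp(15, 0.25))
    g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
    if (igraph::vcount(g) < 5) next
    ord <- sample(igraph::V(g)$name, 5)
    curve <- robustness(g, "targeted", nodes = ord)
    expect_true(all(diff(curve$robustness) <= 1e-12))
    expect_true(all(curve$robustness >= 0 & curve$robustness <= 1))
  }
})

test_that("the secondary-extinction cascade is idempotent", {
  set.seed(7)
  for (i in 1:10) {
    g <- named_graph(igraph::sample_gnp(20, 0.1))
    once <- crustnet:::cascade(g)
    twice <- crustnet:::cascade(once)
    expect_identical(igraph::V(once)$name, igraph::V(twice)$name)
    expect_true(all(igraph::degree(once) > 0) || igraph::vcount(once) == 0)
  }
})

test_that("restricted random removal only touches the requested class", {
  g <- plant_keystone_network(40, 2, rng_seed = 5, n_connectors = 2,
                              flag_connectors = TRUE)
  cy <- igraph::V(g)$name[igraph::V(g)$is_cyanobacterium]
  r <- robustness(g, "random", fraction = 1, restrict_to = cy,
                  n_perm = 10, rng_seed = 2)
  # removing all flagged nodes is deterministic
  expect_equal(length(unique(r)), 1)
  expect_error(robustness(g, "random", restrict_to = "nope"), "unknown")
  expect_error(robustness(g, "targeted", nodes = "nope"), "unknown")
})

test_that("vulnerability closed forms and oracle agreement", {
  p3 <- named_graph(igraph::make_graph(~ a - b - c))
  expect_equal(vulnerability(p3), 1)  # removing the middle disconnects

  k4 <- named_graph(igraph::make_full_graph(4))
  expect_equal(vulnerability(k4), 0)

  # cycles: deleting any node of C_n leaves a path; computed consistently
  set.seed(3)
  for (i in 1:15) {
    g <- named_graph(igraph::sample_gnp(12, 0.3))
    if (igraph::ecount(g) == 0) next
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    expect_equal(vulnerability(g), vulnerability_oracle(adj),
                 tolerance = 1e-12)
  }

  expect_error(vulnerability(named_graph(igraph::make_empty_graph(
    5, directed = FALSE))), "efficiency")
})

test_that("group contrast detects planted connector dependence", {
  g <- plant_keystone_network(80, 4, rng_seed = 13, within_p = 0.2,
                              n_connectors = 4, connector_frac = 0.5,
                              flag_connectors = TRUE)
  cmp <- compare_with_without_group(g, rng_seed = 13)
  rb <- tapply(cmp$robustness$robustness, cmp$robustness$network, mean)
  expect_gt(rb["ctr"], rb["cyr"])
  expect_lt(cmp$p_value, 0.05)

  # node/edge counts of the reduced network equal brute-force deletion
  flagged <- igraph::V(g)$name[igraph::V(g)$is_cyanobacterium]
  manual <- igraph::delete_vertices(g, flagged)
  manual <- igraph::delete_vertices(manual, igraph::degree(manual) == 0)
  expect_equal(igraph::vcount(cmp$networks$cyr), igraph::vcount(manual))
  expect_equal(igraph::ecount(cmp$networks$cyr), igraph::ecount(manual))

  # a group with no effect: flag nothing -> error; flag all -> empty error
  g0 <- plant_keystone_network(20, 2, rng_seed = 1)
  expect_error(compare_with_without_group(g0), "empty")
})

test_that("focal subnetwork extraction matches brute-force edge scans", {
  g <- plant_keystone_network(40, 2, rng_seed = 6, n_connectors = 2,
                              flag_connectors = TRUE)
  # make some partners fungal and some edges negative, deterministically
  nv <- igraph::vcount(g)
  igraph::V(g)$kingdom <- rep(c("Bacteria", "Fungi"), length.out = nv)
  igraph::V(g)$kingdom[igraph::V(g)$is_cyanobacterium] <- "Bacteria"
  ne <- igraph::ecount(g)
  igraph::E(g)$sign <- rep(c("+", "+", "-"), length.out = ne)

  res <- extract_focal_subnetwork(g)
  flagged <- igraph::V(g)$name[igraph::V(g)$is_cyanobacterium]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  nbrs <- unique(unlist(lapply(flagged, function(v)
    names(which(adj[v, ] > 0)))))
  expect_setequal(igraph::V(res$subnetwork)$name, union(flagged, nbrs))

  # summary fractions against a direct edge scan
  el <- igraph::as_edgelist(g)
  sgn <- igraph::E(g)$sign
  kg <- stats::setNames(igraph::V(g)$kingdom, igraph::V(g)$name)
  fl <- stats::setNames(igraph::V(g)$is_cyanobacterium,
                        igraph::V(g)$name)
  inc <- fl[el[, 1]] | fl[el[, 2]]
  partner <- ifelse(fl[el[, 1]], kg[el[, 2]], kg[el[, 1]])
  for (kingdom in c("Bacteria", "Fungi")) {
    sel <- inc & partner == kingdom
    expected <- if (any(sel)) mean(sgn[sel] == "+") else NA_real_
    got <- if (kingdom == "Bacteria")
      res$summary$positive_fraction_bacterial_partners
    else res$summary$positive_fraction_fungal_partners
    expect_equal(got, expected)
  }

  # group = all nodes -> subnetwork is the whole network
  igraph::V(g)$is_cyanobacterium <- TRUE
  all_res <- extract_focal_subnetwork(g)
  expect_equal(igraph::vcount(all_res$subnetwork), igraph::vcount(g))
  expect_equal(igraph::ecount(all_res$subnetwork), igraph::ecount(g))
})
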