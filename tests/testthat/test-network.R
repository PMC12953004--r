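test_that("taxon filter applies strict abundance and prevalence rules", {
  # 10 taxa x 9 replicates of one stage, engineered margins
  n <- 10
  counts <- matrix(0, n, 9, dimnames = list(paste0("t", 1:n),
                                            paste0("s", 1:9)))
  counts[1, ] <- 10000        # abundant, 9/9
  counts[2, 1:7] <- 10000     # abundant, exactly 7/9
  counts[3, 1:6] <- 10000     # abundant, only 6/9 -> drop
  counts[3, 1] <- 9771        # tune the grand total (see below)
  counts[4, ] <- 1            # 9/9 but rare -> drop
  # taxon 5 at exactly 0.1% of the final total (220/220000): the strict
  # "greater than" rule must drop it despite full prevalence
  stopifnot(sum(counts) == 219780)
  counts[5, ] <- c(212, rep(1, 8))
  sm <- data.frame(sample_id = colnames(counts), stage = "algal",
                   replicate = 1:9)
  tm <- data.frame(taxon_id = rownames(counts), kingdom = "Bacteria",
                   is_cyanobacterium = FALSE)
  tab <- abundance_table(counts, sm, tm)
  kept <- rownames(filter_taxa(tab, stage = "algal")$counts)
  expect_setequal(kept, c("t1", "t2"))

  # brute-force oracle over a random table
  fx <- small_table(n_taxa = 40, seed = 6, depth = 3000,
                    regime = "homogeneous")
  st <- "algal"
  ft <- filter_taxa(fx$table, stage = st)
  sub <- fx$table$counts[, fx$table$sample_meta$stage == st]
  rel <- rowSums(sub) / sum(sub)
  prev <- rowSums(sub > 0)
  expect_setequal(rownames(ft$counts),
                  rownames(sub)[rel > 0.001 & prev >= 7])
})

test_that("network construction honours inclusive thresholds", {
  taxa <- paste0("t", 1:4)
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.65    # boundary: kept
  rho[1, 3] <- rho[3, 1] <- 0.64    # below: dropped
  rho[2, 4] <- rho[4, 2] <- -0.80   # negative association: kept
  pval <- matrix(0.01, 4, 4)
  pval[1, 2] <- pval[2, 1] <- 0.05  # boundary p: kept
  dimnames(rho) <- dimnames(pval) <- list(taxa, taxa)
  counts <- matrix(25, 4, 8, dimnames = list(taxa, paste0("s", 1:8)))
  tab <- abundance_table(counts,
                         data.frame(sample_id = colnames(counts),
                                    stage = "a", replicate = 1:8),
                         data.frame(taxon_id = taxa, kingdom = "Bacteria",
                                    is_cyanobacterium = c(TRUE, FALSE,
                                                          FALSE, FALSE)))
  corr <- structure(list(rho = rho, pval = pval), class = "sparcc_result")
  net <- build_network(corr, tab)
  el <- igraph::as_edgelist(net)
  expect_equal(nrow(el), 2)
  expect_setequal(paste(el[, 1], el[, 2]), c("t1 t2", "t2 t4"))
  expect_false("t3" %in% igraph::V(net)$name)  # isolated node dropped
  signs <- igraph::E(net)$sign
  expect_setequal(signs, c("+", "-"))
  expect_true(igraph::vertex_attr(net, "is_cyanobacterium")[
    igraph::V(net)$name == "t1"])

  rho[1, 2] <- rho[2, 1] <- 0.1
  rho[2, 4] <- rho[4, 2] <- 0.1
  corr0 <- structure(list(rho = rho, pval = pval), class = "sparcc_result")
  expect_error(build_network(corr0, tab), "no edges")
})

test_that("topology summary matches independent recomputation", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  ts <- topology_summary(tri)
  expect_equal(ts$density, 1)
  expect_equal(ts$clustering, 1)

  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- paste0("v", 1:6)
  expect_equal(topology_summary(star)$mean_degree, 2 * 5 / 6)

  g <- plant_keystone_network(40, 2, rng_seed = 8, within_p = 0.4)
  ts <- topology_summary(g)
  el <- igraph::as_edgelist(g)
  n <- igraph::vcount(g)
  m <- nrow(el)
  expect_equal(ts$edges, m)
  expect_equal(ts$mean_degree, 2 * m / n)
  expect_equal(ts$density, m / choose(n, 2))
})

test_that("module detection is deterministic and recovers planted blocks", {
  # two disconnected cliques are their own modules
  cl <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  igraph::V(cl)$name <- paste0("v", 1:10)
  mem <- detect_modules(cl)
  expect_equal(length(unique(mem[1:5])), 1)
  expect_equal(length(unique(mem[6:10])), 1)
  expect_false(mem[1] == mem[10])

  aris <- vapply(1:5, function(s) {
    g <- plant_keystone_network(80, 4, rng_seed = s)
    mem <- detect_modules(g)
    mclust::adjustedRandIndex(mem, igraph::V(g)$module_truth)
  }, numeric(1))
  expect_true(all(aris >= 0.9))

  g <- plant_keystone_network(60, 3, rng_seed = 4)
  expect_identical(detect_modules(g), detect_modules(g))
})

test_that("zi/pi match the defining formulas", {
  # node with degree 4 split over 4 modules -> Pi = 0.75
  g <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(g)$name <- paste0("v", 1:5)
  mem <- stats::setNames(c(1L, 1L, 2L, 3L, 4L), igraph::V(g)$name)
  zp <- zipi(g, mem)
  expect_equal(zp$pi[zp$taxon == "v1"], 1 - (2 * (1 / 4)^2 + 2 * (1 / 16)))
  # leaves have all their edges outside... v2 shares module 1 with the hub
  expect_equal(zp$pi[zp$taxon == "v2"], 0)
  expect_equal(zp$pi[zp$taxon == "v3"], 0)  # single edge, Pi = 1 - 1 = 0

  # direct-formula oracle on a planted network
  g <- plant_keystone_network(60, 3, rng_seed = 12)
  mem <- detect_modules(g)
  zp <- zipi(g, mem)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  for (v in sample(igraph::V(g)$name, 10)) {
    nb <- names(which(adj[v, ] > 0))
    k <- length(nb)
    k_by_mod <- table(mem[nb])
    pi_hand <- if (k == 0) 0 else 1 - sum((as.numeric(k_by_mod) / k)^2)
    expect_equal(zp$pi[zp$taxon == v], pi_hand, tolerance = 1e-12)
    own <- names(mem)[mem == mem[v]]
    kw <- vapply(own, function(u) sum(adj[u, own]), numeric(1))
    zi_hand <- if (sd(kw) == 0) 0 else
      (sum(adj[v, own]) - mean(kw)) / sd(kw)
    expect_equal(zp$zi[zp$taxon == v], unname(zi_hand), tolerance = 1e-12)
  }
})

test_that("role thresholds are applied exactly as defined", {
  expect_equal(classify_roles(3, 0.7), "network_hub")
  expect_equal(classify_roles(3, 0.62), "module_hub")   # Pi <= 0.62
  expect_equal(classify_roles(2.0, 0.7), "connector")
  expect_equal(classify_roles(2.5, 0.7), "connector")   # zi <= 2.5
  expect_equal(classify_roles(0, 0), "peripheral")
  expect_error(classify_roles(NaN, 0.5), "finite")
})

test_that("planted keystones are recovered", {
  hits <- 0; preds <- 0
  for (s in 1:10) {
    g <- plant_keystone_network(80, 4, rng_seed = s)
    zp <- classify_roles(zipi(g, detect_modules(g)))
    pred <- zp$taxon[zp$keystone]
    truth <- igraph::V(g)$name[igraph::V(g)$truth_role != "peripheral"]
    preds <- preds + length(pred)
    hits <- hits + length(intersect(pred, truth))
  }
  expect_gt(preds, 0)
  expect_gte(hits / preds, 0.8)
})
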