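# Independent oracles used across tests.  Deliberately naive: straight
# transcriptions of the defining formulas, no shared code with the package
# internals they check.

# abundance-weighted beta mean-nearest-taxon distance, direct double loop
bmntd_oracle <- function(a, b, d) {
  fa <- a[a > 0] / sum(a)
  fb <- b[b > 0] / sum(b)
  ta <- names(fa)
  tb <- names(fb)
  sa <- sum(vapply(seq_along(fa), function(i)
    fa[i] * min(d[ta[i], tb]), numeric(1)))
  sb <- sum(vapply(seq_along(fb), function(j)
    fb[j] * min(d[ta, tb[j]]), numeric(1)))
  0.5 * (sa + sb)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}

# exact null distribution of betaMNTD over every tip-label permutation
bmntd_exact_null <- function(a, b, d) {
  n <- nrow(d)
  taxa <- rownames(d)
  vapply(all_perms(n), function(perm) {
    dp <- d[perm, perm]
    dimnames(dp) <- list(taxa, taxa)
    bmntd_oracle(a, b, dp)
  }, numeric(1))
}

# straight transcription of the classical ACE estimator
ace_oracle <- function(x, cutoff = 10) {
  x <- x[x > 0]
  s_ab <- sum(x > cutoff)
  rare <- x[x <= cutoff]
  if (length(rare) == 0) return(s_ab)
  n_rare <- sum(rare)
  f <- vapply(1:cutoff, function(k) sum(rare == k), numeric(1))
  c_ace <- 1 - f[1] / n_rare
  g2 <- max(length(rare) / c_ace *
              sum((1:cutoff) * (0:(cutoff - 1)) * f) /
              (n_rare * (n_rare - 1)) - 1, 0)
  s_ab + length(rare) / c_ace + f[1] / c_ace * g2
}

# all-pairs shortest paths by Floyd-Warshall on an adjacency matrix
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

# global efficiency and max-node vulnerability from an adjacency matrix
vulnerability_oracle <- function(adj) {
  eff <- function(a) {
    if (nrow(a) < 2) return(0)
    d <- floyd_warshall(a)
    iv <- 1 / d[upper.tri(d)]
    mean(ifelse(is.finite(iv), iv, 0))
  }
  e0 <- eff(adj)
  max(vapply(seq_len(nrow(adj)), function(i)
    (e0 - eff(adj[-i, -i, drop = FALSE])) / e0, numeric(1)))
}

# small neutral community fixture shared by several tests
small_table <- function(n_taxa = 30, seed = 5, depth = 2000,
                        regime = "neutral", ...) {
  tree <- simulate_tree(n_taxa, seed + 1000L)
  cfg <- simulation_config(n_taxa = n_taxa, seq_depth = depth,
                           selection_regime = regime, rng_seed = seed, ...)
  list(tree = tree, table = simulate_communities(tree, cfg))
}
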