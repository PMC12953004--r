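#' Scale-free pseudocounted proportions
#'
#' Converts counts to proportions and applies the pseudocount at a fixed
#' reference depth: `p_i = (q_i * T + pc) / (T + D * pc)` with `q` the raw
#' proportions, `T` the reference depth and `D` the number of taxa.  This
#' reproduces the usual "add a pseudocount, renormalise" zero handling at
#' depth `T` while being exactly invariant to per-sample rescaling of the
#' counts — the compositional property the whole SparCC chain relies on.
#'
#' @param counts taxon-by-sample matrix.
#' @param pseudocount pseudocount in reference-depth read units.
#' @param ref_depth reference depth `T`.
#' @return strictly positive taxon-by-sample proportion matrix.
#' @export
pseudo_proportions <- function(counts, pseudocount = 1, ref_depth = 10000) {
  tot <- colSums(counts)
  if (any(tot <= 0)) abort_arg("samples with zero total counts")
  q <- sweep(counts, 2, tot, "/")
  (q * ref_depth + pseudocount) / (ref_depth + nrow(counts) * pseudocount)
}

#' Log-ratio variance matrix (SparCC step 1)
#'
#' `t_ij = Var_samples[ log(x_i / x_j) ]`, computed on pseudocounted
#' proportions.  Symmetric, zero diagonal, non-negative.
#'
#' @param counts taxon-by-sample count matrix with >= 4 samples.
#' @param pseudocount,ref_depth passed to [pseudo_proportions()].
#' @return taxon-by-taxon variance matrix.
#' @export
log_ratio_variances <- function(counts, pseudocount = 1, ref_depth = 10000) {
  if (ncol(counts) < 4) abort_arg("need >= 4 samples")
  L <- log(pseudo_proportions(counts, pseudocount, ref_depth))
  V <- stats::cov(t(L))
  d <- diag(V)
  t_mat <- outer(d, d, "+") - 2 * V
  t_mat[t_mat < 0] <- 0  # numerical floor
  diag(t_mat) <- 0
  dimnames(t_mat) <- list(rownames(counts), rownames(counts))
  t_mat
}

# linear system of the SparCC sparsity approximation:
#   sum_{j != i, (i,j) not excluded} t_ij
#     = (D_i - 1) w_i + sum_{j in partners(i)} w_j
# excluded: logical matrix of pairs removed from the basis system
solve_basis_system <- function(t_mat, excluded = NULL) {
  D <- nrow(t_mat)
  if (is.null(excluded)) excluded <- matrix(FALSE, D, D)
  partners <- !excluded
  diag(partners) <- FALSE
  M <- matrix(1, D, D)
  M[!partners] <- 0
  diag(M) <- rowSums(partners)
  rhs <- rowSums(t_mat * partners)
  solve(M, rhs)
}

#' Basis variances under the SparCC sparsity assumption (step 2)
#'
#' Solves `sum_{j != i} t_ij ~ (D - 1) w_i + sum_{j != i} w_j` for the
#' latent (basis) log-abundance variances `w = omega^2`.  Negative solutions
#' — possible when the sparsity assumption is badly violated — are floored
#' at a small positive epsilon with a warning.
#'
#' @param t_mat log-ratio variance matrix from [log_ratio_variances()].
#' @param excluded optional logical matrix of pairs excluded from the
#'   system (see [sparcc_correlations()]).
#' @param eps floor for negative variance solutions.
#' @return vector of basis variances omega^2.
#' @export
estimate_basis_variances <- function(t_mat, excluded = NULL, eps = 1e-8) {
  if (nrow(t_mat) < 3) abort_arg("need >= 3 taxa")
  w <- solve_basis_system(t_mat, excluded)
  if (any(w < eps)) {
    warning(sum(w < eps), " negative/near-zero basis variance(s) floored")
    w[w < eps] <- eps
  }
  names(w) <- rownames(t_mat)
  w
}

#' SparCC correlations
#'
#' Estimates basis correlations of compositional count data:
#' `rho_ij = (w_i + w_j - t_ij) / (2 * sqrt(w_i) * sqrt(w_j))`, clipped to
#' `[-1, 1]`.  The sparsity assumption is sharpened iteratively: in each
#' round the single strongest-|rho| pair above `exclusion_threshold` is
#' removed from the basis system and the variances re-solved, up to
#' `n_exclusion_iter` rounds (the original SparCC exclusion heuristic).
#'
#' @param counts taxon-by-sample count matrix (>= 3 taxa, >= 4 samples).
#' @param n_exclusion_iter maximum exclusion rounds.
#' @param exclusion_threshold only pairs with `|rho|` above this are
#'   eligible for exclusion.
#' @param pseudocount,ref_depth zero handling, see [pseudo_proportions()].
#' @return a `sparcc_result` list: `rho` (symmetric, unit diagonal),
#'   `excluded_pairs` (two-column matrix of taxon IDs), `basis_variances`.
#' @export
sparcc_correlations <- function(counts, n_exclusion_iter = 10,
                                exclusion_threshold = 0.1,
                                pseudocount = 1, ref_depth = 10000) {
  t_mat <- log_ratio_variances(counts, pseudocount, ref_depth)
  D <- nrow(t_mat)
  excluded <- matrix(FALSE, D, D)
  rho <- NULL
  for (iter in seq_len(n_exclusion_iter + 1)) {
    w <- suppressWarnings(estimate_basis_variances(t_mat, excluded))
    om <- sqrt(w)
    rho <- (outer(w, w, "+") - t_mat) / (2 * outer(om, om))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    if (iter > n_exclusion_iter) break
    cand <- abs(rho)
    cand[excluded | upper.tri(cand) == FALSE] <- 0  # scan upper triangle
    mx <- which(cand == max(cand), arr.ind = TRUE)[1, ]
    if (cand[mx[1], mx[2]] <= exclusion_threshold) break
    # keep every taxon in the system with >= 2 partners
    ex2 <- excluded
    ex2[mx[1], mx[2]] <- ex2[mx[2], mx[1]] <- TRUE
    if (any(rowSums(!ex2) - 1 < 2)) break
    # stop excluding rather than leave an unsolvable basis system
    ok <- tryCatch({solve_basis_system(t_mat, ex2); TRUE},
                   error = function(e) FALSE)
    if (!ok) break
    excluded <- ex2
  }
  if (all(excluded[upper.tri(excluded)]))
    abort_arg("all pairs excluded from the basis system")
  dimnames(rho) <- dimnames(t_mat)
  ep <- which(excluded & upper.tri(excluded), arr.ind = TRUE)
  structure(list(rho = rho,
                 excluded_pairs = cbind(rownames(t_mat)[ep[, 1]],
                                        rownames(t_mat)[ep[, 2]]),
                 basis_variances = w),
            class = "sparcc_result")
}

#' Permutation pseudo p-values for SparCC correlations
#'
#' Each bootstrap permutes every taxon's counts across samples independently
#' (destroying all between-taxon association while preserving marginals),
#' recomputes SparCC, and the two-sided pseudo p-value is the add-one
#' estimator `p_ij = (1 + #{ |rho_boot| >= |rho_obs| }) / (n_boot + 1)`.
#'
#' @param counts taxon-by-sample count matrix.
#' @param rho_obs observed correlation matrix (from
#'   [sparcc_correlations()]).
#' @param n_boot number of permutations (>= 20).
#' @param rng_seed integer seed.
#' @param ... passed on to [sparcc_correlations()].
#' @return symmetric p-value matrix in `[1/(n_boot+1), 1]`.
#' @export
bootstrap_pvalues <- function(counts, rho_obs, n_boot = 100, rng_seed = NULL,
                              ...) {
  if (n_boot < 20) abort_arg("n_boot must be >= 20")
  ns <- ncol(counts)
  ge <- matrix(0L, nrow(counts), nrow(counts))
  with_seed(rng_seed, {
    for (b in seq_len(n_boot)) {
      perm <- counts
      for (i in seq_len(nrow(counts)))
        perm[i, ] <- counts[i, sample.int(ns)]
      rb <- sparcc_correlations(perm, ...)$rho
      ge <- ge + (abs(rb) >= abs(rho_obs))
    }
  })
  p <- (1 + ge) / (n_boot + 1)
  diag(p) <- 1 / (n_boot + 1)
  dimnames(p) <- dimnames(rho_obs)
  p
}

#' SparCC correlations with permutation p-values
#'
#' Convenience wrapper running [sparcc_correlations()] and
#' [bootstrap_pvalues()].
#'
#' @inheritParams sparcc_correlations
#' @inheritParams bootstrap_pvalues
#' @return a `sparcc_result` with elements `rho`, `pval`, `n_boot`,
#'   `excluded_pairs`.
#' @export
sparcc <- function(counts, n_boot = 100, rng_seed = NULL,
                   n_exclusion_iter = 10, exclusion_threshold = 0.1,
                   pseudocount = 1, ref_depth = 10000) {
  res <- sparcc_correlations(counts, n_exclusion_iter, exclusion_threshold,
                             pseudocount, ref_depth)
  res$pval <- bootstrap_pvalues(counts, res$rho, n_boot, rng_seed,
                                n_exclusion_iter = n_exclusion_iter,
                                exclusion_threshold = exclusion_threshold,
                                pseudocount = pseudocount,
                                ref_depth = ref_depth)
  res$n_boot <- n_boot
  res
}

#' @export
print.sparcc_result <- function(x, ...) {
  cat("<sparcc_result> ", nrow(x$rho), " taxa; ",
      nrow(x$excluded_pairs), " pair(s) excluded from the basis system\n",
      sep = "")
  invisible(x)
}

#' Write SparCC results as TSV
#'
#' Square rho/p matrices with taxon headers, plus a long-format edge
#' candidate table (`taxon_i`, `taxon_j`, `rho`, `p`).
#'
#' @param result a `sparcc_result` with `pval`.
#' @param rho_path,pval_path,edges_path output TSV paths.
#' @return invisibly, the paths.
#' @export
write_sparcc_result <- function(result, rho_path, pval_path, edges_path) {
  wr <- function(m, path) {
    df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(result$rho, rho_path)
  wr(result$pval, pval_path)
  ut <- which(upper.tri(result$rho), arr.ind = TRUE)
  edges <- data.frame(taxon_i = rownames(result$rho)[ut[, 1]],
                      taxon_j = rownames(result$rho)[ut[, 2]],
                      rho = result$rho[ut], p = result$pval[ut],
                      stringsAsFactors = FALSE)
  utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(rho_path, pval_path, edges_path))
}
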