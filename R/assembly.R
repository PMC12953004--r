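#' Cophenetic (patristic) distances between tree tips
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @return symmetric taxon-by-taxon distance matrix with zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  if (is.null(tree$edge.length)) abort_arg("tree has no branch lengths")
  ape::cophenetic.phylo(tree)
}

prep_communities <- function(comm_a, comm_b, dist) {
  if (sum(comm_a) == 0 || sum(comm_b) == 0)
    abort_arg("empty community")
  taxa <- rownames(dist)
  if (is.null(names(comm_a)) || is.null(names(comm_b)))
    abort_arg("communities must be named count vectors")
  if (!all(names(comm_a) %in% taxa) || !all(names(comm_b) %in% taxa))
    abort_arg("community taxa must be present in the distance matrix")
  w <- matrix(0, nrow(dist), 2, dimnames = list(taxa, c("a", "b")))
  w[names(comm_a), 1] <- comm_a
  w[names(comm_b), 2] <- comm_b
  w
}

#' Beta mean-nearest-taxon distance between two communities
#'
#' Abundance-weighted mean phylogenetic distance from each taxon in one
#' community to its nearest taxon in the other, averaged over both
#' directions:
#' `0.5 * (sum_i fA_i min_j d_ij + sum_j fB_j min_i d_ij)`
#' with `f` the within-community relative abundances.
#'
#' @param comm_a,comm_b named non-negative count vectors.
#' @param dist cophenetic distance matrix covering all named taxa.
#' @param weighted if `FALSE`, presence/absence weights are used.
#' @return the betaMNTD value (0 for identical communities).
#' @export
beta_mntd <- function(comm_a, comm_b, dist, weighted = TRUE) {
  w <- prep_communities(comm_a, comm_b, dist)
  if (!weighted) w <- (w > 0) * 1
  bmntd_obs_cpp(dist, w, matrix(c(1L, 2L), 1))[1]
}

#' Standardised effect size of betaMNTD (betaNTI)
#'
#' `(betaMNTD_obs - mean(betaMNTD_null)) / sd(betaMNTD_null)`, with the null
#' generated by shuffling taxon labels across the full taxon pool of the
#' distance matrix (richness and abundances preserved, phylogenetic
#' relationships randomised) — the standard null of the Stegen
#' community-assembly framework.
#'
#' @inheritParams beta_mntd
#' @param n_null number of null permutations (>= 99).
#' @param rng_seed integer seed.
#' @param details if `TRUE`, return a list with the observed value and the
#'   null mean/sd alongside the standardised effect size.
#' @return the betaNTI value (or a detail list); `NaN` with a warning when
#'   the null distribution has zero spread.
#' @export
beta_nti <- function(comm_a, comm_b, dist, n_null = 999, rng_seed = NULL,
                     weighted = TRUE, details = FALSE) {
  if (n_null < 99) abort_arg("n_null must be >= 99")
  w <- prep_communities(comm_a, comm_b, dist)
  if (!weighted) w <- (w > 0) * 1
  pairs <- matrix(c(1L, 2L), 1)
  obs <- bmntd_obs_cpp(dist, w, pairs)[1]
  n <- nrow(dist)
  with_seed(rng_seed, {
    perms <- t(replicate(n_null, sample.int(n)))
  })
  null <- as.numeric(bmntd_null_cpp(dist, w, pairs, perms))
  m <- mean(null)
  s <- stats::sd(null)
  ses <- if (s == 0) {
    warning("null betaMNTD has zero spread; betaNTI undefined")
    NaN
  } else (obs - m) / s
  if (details) list(bnti = ses, obs = obs, null_mean = m, null_sd = s)
  else ses
}

#' Classify community-assembly process from betaNTI
#'
#' `betaNTI < -2` indicates lower-than-expected phylogenetic turnover
#' (homogeneous selection), `betaNTI > 2` higher-than-expected turnover
#' (variable selection), and `|betaNTI| < 2` stochastic assembly.  Values at
#' exactly +/-2 fall in the stochastic class (strict inequalities).
#'
#' @param bnti numeric vector of betaNTI values.
#' @return character vector in `{homogeneous_selection, variable_selection,
#'   stochastic, unclassified}` (`unclassified` for non-finite input, with a
#'   warning).
#' @export
classify_assembly <- function(bnti) {
  out <- rep("stochastic", length(bnti))
  bad <- !is.finite(bnti)
  if (any(bad)) {
    warning(sum(bad), " non-finite betaNTI value(s) left unclassified")
    out[bad] <- "unclassified"
  }
  out[!bad & bnti < -2] <- "homogeneous_selection"
  out[!bad & bnti > 2] <- "variable_selection"
  out
}

#' Per-stage assembly-process fractions
#'
#' Evaluates betaNTI for every within-stage sample pair (optionally all
#' pairs) and reports, per stage, the share of pairs assigned to homogeneous
#' selection, variable selection and stochasticity.
#'
#' @param table an [abundance_table].
#' @param tree phylogeny covering the table's taxa (taxa missing from the
#'   tree are dropped with a warning).
#' @param n_null null permutations per pair (one shared shuffle ensemble is
#'   applied to all pairs, the standard matrix-shuffle null).
#' @param rng_seed integer seed.
#' @param all_pairs if `TRUE`, between-stage pairs are evaluated too (they
#'   appear in the pair table; stage fractions remain within-stage).
#' @param exclude_cyanobacteria drop flagged cyanobacterial taxa before the
#'   analysis (some studies build the bacterial tree without them).
#' @return an `assembly_result` list: `bnti` (pair table with `sample_a`,
#'   `sample_b`, stages, `bmntd_obs`, `bnti`, `classification`),
#'   `stage_fractions`, and `n_null`.
#' @export
stage_fractions <- function(table, tree, n_null = 999, rng_seed = NULL,
                            all_pairs = FALSE,
                            exclude_cyanobacteria = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  if (exclude_cyanobacteria &&
      "is_cyanobacterium" %in% names(table$taxon_meta)) {
    keep <- table$taxon_meta$taxon_id[!table$taxon_meta$is_cyanobacterium]
    table <- subset_table(table, taxa = keep)
  }
  taxa <- intersect(rownames(table$counts), tree$tip.label)
  if (length(taxa) < nrow(table$counts))
    warning(nrow(table$counts) - length(taxa),
            " taxa absent from the tree were dropped")
  if (length(taxa) < 2) abort_arg("fewer than 2 taxa shared with the tree")
  counts <- table$counts[taxa, , drop = FALSE]
  dist <- ape::cophenetic.phylo(ape::keep.tip(tree, taxa))[taxa, taxa]

  sm <- table$sample_meta
  ns <- ncol(counts)
  tab_stage <- table(sm$stage)
  small <- names(tab_stage)[tab_stage < 2]
  if (length(small) && !all_pairs)
    warning("stage(s) with < 2 samples skipped: ",
            paste(small, collapse = ", "))

  idx <- utils::combn(ns, 2)
  same_stage <- sm$stage[idx[1, ]] == sm$stage[idx[2, ]]
  use <- if (all_pairs) rep(TRUE, ncol(idx)) else same_stage
  pairs <- t(idx[, use, drop = FALSE])
  if (nrow(pairs) == 0) abort_arg("no sample pairs to evaluate")

  obs <- bmntd_obs_cpp(dist, counts, pairs)
  with_seed(rng_seed, {
    perms <- t(replicate(n_null, sample.int(length(taxa))))
  })
  null <- bmntd_null_cpp(dist, counts, pairs, perms)
  nm <- rowMeans(null)
  nsd <- apply(null, 1, stats::sd)
  bnti <- ifelse(nsd == 0, NaN, (obs - nm) / nsd)
  cls <- classify_assembly(bnti)

  pair_df <- data.frame(
    sample_a = colnames(counts)[pairs[, 1]],
    sample_b = colnames(counts)[pairs[, 2]],
    stage_a = sm$stage[pairs[, 1]],
    stage_b = sm$stage[pairs[, 2]],
    bmntd_obs = obs, bnti = bnti, classification = cls,
    stringsAsFactors = FALSE)

  within <- pair_df[pair_df$stage_a == pair_df$stage_b, , drop = FALSE]
  frac <- do.call(rbind, lapply(split(within, within$stage_a), function(df) {
    ok <- df$classification != "unclassified"
    n_ok <- sum(ok)
    data.frame(
      stage = df$stage_a[1],
      homogeneous_selection =
        sum(df$classification == "homogeneous_selection") / n_ok,
      variable_selection =
        sum(df$classification == "variable_selection") / n_ok,
      stochastic = sum(df$classification == "stochastic") / n_ok,
      n_pairs = nrow(df), stringsAsFactors = FALSE)
  }))
  rownames(frac) <- NULL
  structure(list(bnti = pair_df, stage_fractions = frac, n_null = n_null),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("<assembly_result> ", nrow(x$bnti), " sample pairs, n_null = ",
      x$n_null, "\n", sep = "")
  print(x$stage_fractions, ...)
  invisible(x)
}
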