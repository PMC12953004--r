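#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads.  Samples with fewer reads than `depth` are dropped with a warning —
#' the standard practice for uneven amplicon libraries.
#'
#' @param table an [abundance_table].
#' @param depth target reads per sample (the cyanobacterial tables of the
#'   motivating study were rarefied to 1648 reads).
#' @param rng_seed integer seed; a fixed seed gives identical output.
#' @return a rarefied [abundance_table].
#' @export
rarefy <- function(table, depth, rng_seed = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (depth < 1) abort_arg("depth must be >= 1")
  tot <- colSums(table$counts)
  keep <- tot >= depth
  if (!any(keep))
    abort_arg("all samples have fewer than ", depth, " reads")
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(names(tot)[!keep], collapse = ", "))
  counts <- table$counts[, keep, drop = FALSE]
  with_seed(rng_seed, {
    for (j in seq_len(ncol(counts))) {
      x <- counts[, j]
      if (sum(x) == depth) next  # already at depth: returned unchanged
      reads <- rep.int(seq_along(x), x)
      counts[, j] <- tabulate(sample(reads, depth), nbins = length(x))
    }
  })
  abundance_table(counts,
                  table$sample_meta[keep, , drop = FALSE],
                  table$taxon_meta)
}

#' Shannon diversity of a count vector
#'
#' `H = -sum(p_i * log(p_i))` over positive-count taxa, in natural-log units.
#'
#' @param x non-negative count (or proportion) vector.
#' @return Shannon index (>= 0).
#' @export
shannon <- function(x) {
  if (all(x == 0)) abort_arg("need at least one positive count")
  if (any(x < 0)) abort_arg("negative counts")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator.  Taxa with count `<= rare_threshold`
#' are "rare"; with `S_abund` abundant taxa, `S_rare` rare taxa holding
#' `N_rare` reads, `F1` singletons and sample coverage
#' `C_ace = 1 - F1 / N_rare`:
#' `ACE = S_abund + S_rare / C_ace + (F1 / C_ace) * gamma2`, where `gamma2`
#' is the squared coefficient of variation of rare-taxon frequencies,
#' floored at 0.  When every rare taxon is a singleton (`C_ace = 0`) the
#' estimator is undefined and the function falls back to Chao1 with a
#' warning.
#'
#' @param x non-negative count vector.
#' @param rare_threshold counts at or below this are "rare" (classical 10).
#' @return estimated richness (>= observed abundant richness).
#' @export
ace <- function(x, rare_threshold = 10) {
  if (all(x == 0)) abort_arg("need at least one positive count")
  x <- x[x > 0]
  rare <- x <= rare_threshold
  s_abund <- sum(!rare)
  s_rare <- sum(rare)
  if (s_rare == 0) return(s_abund)
  n_rare <- sum(x[rare])
  f1 <- sum(x == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) {
    warning("all rare taxa are singletons; falling back to Chao1")
    f2 <- sum(x == 2)
    return(length(x) + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
  fk <- tabulate(x[rare], nbins = rare_threshold)
  i <- seq_len(rare_threshold)
  gamma2 <- max(s_rare / c_ace * sum(i * (i - 1) * fk) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Per-sample alpha-diversity table
#'
#' @param table an [abundance_table].
#' @param rare_threshold passed to [ace()].
#' @return data.frame with `sample_id`, `stage`, `shannon`, `ace`,
#'   `richness`.
#' @export
alpha_diversity <- function(table, rare_threshold = 10) {
  stopifnot(inherits(table, "abundance_table"))
  data.frame(
    sample_id = colnames(table$counts),
    stage = table$sample_meta$stage,
    shannon = apply(table$counts, 2, shannon),
    ace = apply(table$counts, 2, ace, rare_threshold = rare_threshold),
    richness = colSums(table$counts > 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param table an [abundance_table] with >= 2 samples.
#' @return symmetric sample-by-sample matrix with zero diagonal, entries between 0 and 1.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (ncol(table$counts) < 2) abort_arg("need >= 2 samples")
  as.matrix(vegan::vegdist(t(table$counts), method = "bray"))
}

#' Shared/unique taxon partition across groups
#'
#' Assigns every taxon to exactly one presence-pattern cell (which of the
#' `2^k - 1` group combinations it occurs in, by pooled counts) and reports
#' each cell's taxa and pooled relative abundance per group — the machinery
#' behind "shared across all crust types" style summaries.
#'
#' @param table an [abundance_table].
#' @param group_by sample-metadata column defining groups (default `stage`).
#' @return data.frame with `cell` (group names joined by `&`), `n_taxa`, one
#'   relative-abundance column per group, and a list-column `taxa`.
#' @export
shared_unique_partition <- function(table, group_by = "stage") {
  stopifnot(inherits(table, "abundance_table"))
  grp <- table$sample_meta[[group_by]]
  groups <- unique(grp)
  if (length(groups) < 2) abort_arg("need >= 2 groups")
  pooled <- vapply(groups, function(g)
    rowSums(table$counts[, grp == g, drop = FALSE]), numeric(nrow(table$counts)))
  colnames(pooled) <- groups
  present <- pooled > 0
  seen <- rowSums(present) > 0
  pat <- apply(present[seen, , drop = FALSE], 1, function(z)
    paste(groups[z], collapse = "&"))
  cells <- unique(pat)
  rel <- sweep(pooled, 2, colSums(pooled), "/")
  out <- data.frame(cell = cells, n_taxa = as.integer(table(pat)[cells]),
                    stringsAsFactors = FALSE)
  for (g in groups)
    out[[paste0("rel_abund_", g)]] <- vapply(cells, function(cl)
      sum(rel[seen, , drop = FALSE][pat == cl, g]), numeric(1))
  out$taxa <- lapply(cells, function(cl)
    rownames(table$counts)[seen][pat == cl])
  out
}

#' Aggregate a count table at a lineage rank
#'
#' Counts are summed over taxa sharing the rank value; lineages without a
#' value at that rank are pooled under `"unclassified <parent>"`, the parent
#' being the nearest classified higher rank.
#'
#' @param table an [abundance_table].
#' @param rank name of a lineage column of `taxon_meta` (e.g. `"family"`).
#' @return an [abundance_table] whose taxa are rank values.
#' @export
aggregate_by_rank <- function(table, rank) {
  stopifnot(inherits(table, "abundance_table"))
  tm <- table$taxon_meta
  if (!rank %in% names(tm)) abort_arg("unknown rank: ", rank)
  canonical <- c("kingdom", "phylum", "class", "order", "family", "genus")
  higher <- rev(intersect(canonical[seq_len(match(rank, canonical,
                                                  nomatch = 1L) - 1L)],
                          names(tm)))
  val <- as.character(tm[[rank]])
  miss <- is.na(val) | val == ""
  if (any(miss)) {
    parent <- rep("unknown", sum(miss))
    for (h in higher) {
      hv <- as.character(tm[[h]])[miss]
      fill <- parent == "unknown" & !is.na(hv) & hv != ""
      parent[fill] <- hv[fill]
    }
    val[miss] <- paste("unclassified", parent)
  }
  counts <- rowsum(table$counts, val)
  is_cy <- tapply(tm$is_cyanobacterium %||% logical(nrow(tm)), val, any)
  kingdom <- if ("kingdom" %in% names(tm))
    tapply(tm$kingdom, val, function(k) names(sort(table(k),
                                                   decreasing = TRUE))[1])
  else rep(NA_character_, nrow(counts))
  tm2 <- data.frame(taxon_id = rownames(counts),
                    kingdom = as.character(kingdom[rownames(counts)]),
                    is_cyanobacterium = as.logical(is_cy[rownames(counts)]),
                    stringsAsFactors = FALSE)
  abundance_table(counts, table$sample_meta, tm2)
}
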