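#' Pipeline configuration
#'
#' Aggregates every stage's parameters with the field-standard defaults:
#' rarefaction to 1648 reads (optional), the `> 0.1%` / `>= 7 replicates`
#' taxon filter, SparCC with 100 permutation bootstraps, network thresholds
#' `|r| >= 0.65` and `p <= 0.05`, 999 null permutations for betaNTI, and
#' random removal of 50% of nodes with 100 permutations for robustness.
#'
#' @param counts,taxonomy,metadata,tree input file paths (TSV / newick);
#'   may be `NULL` when the objects are passed directly to
#'   [run_full_pipeline()].
#' @param outdir output directory.
#' @param rarefaction_depth reads/sample, or `NULL` to skip rarefaction.
#' @param min_rel_abund,min_prevalence taxon filter.
#' @param pseudocount,sparcc_exclusion_iter,sparcc_exclusion_threshold,n_boot
#'   SparCC parameters.
#' @param r_min,p_max network edge thresholds.
#' @param n_null betaNTI null permutations.
#' @param removal_fraction,n_perm robustness parameters.
#' @param rng_seed integer seed governing every stochastic stage.
#' @param strict error (rather than warn) on taxa missing from tree or
#'   taxonomy.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(counts = NULL, taxonomy = NULL, metadata = NULL,
                            tree = NULL, outdir = "crustnet_out",
                            rarefaction_depth = NULL,
                            min_rel_abund = 0.001, min_prevalence = 7,
                            pseudocount = 1, sparcc_exclusion_iter = 10,
                            sparcc_exclusion_threshold = 0.1, n_boot = 100,
                            r_min = 0.65, p_max = 0.05, n_null = 999,
                            removal_fraction = 0.5, n_perm = 100,
                            rng_seed = 1, strict = FALSE) {
  stopifnot(r_min >= 0, r_min <= 1, p_max >= 0, p_max <= 1,
            min_rel_abund >= 0, min_rel_abund < 1, min_prevalence >= 1,
            removal_fraction > 0, removal_fraction <= 1, n_null >= 99,
            n_boot >= 20)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' Flat key-value YAML mirroring the [pipeline_config()] argument names;
#' unknown keys error.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file is read.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) abort_arg("unknown config key(s): ",
                             paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Read and cross-validate pipeline inputs
#'
#' Loads the count/taxonomy/metadata TSVs and the newick tree, and checks
#' that the identifiers cross-reference.  Taxa present in the table but
#' absent from the tree are an error in strict mode and are dropped with a
#' warning otherwise.
#'
#' @param counts,taxonomy,metadata,tree file paths.
#' @param strict logical.
#' @return list with `table` (an [abundance_table]) and `tree`
#'   ([ape::phylo], or `NULL` when no tree path is given).
#' @export
read_inputs <- function(counts, taxonomy, metadata, tree = NULL,
                        strict = FALSE) {
  table <- read_abundance_table(counts, taxonomy, metadata)
  phylo <- NULL
  if (!is.null(tree)) {
    phylo <- tryCatch(suppressWarnings(ape::read.tree(tree)),
                      error = function(e)
                        abort_arg("malformed newick in ", tree, ": ",
                                  conditionMessage(e)))
    if (is.null(phylo)) abort_arg("malformed newick in ", tree)
    missing <- setdiff(rownames(table$counts), phylo$tip.label)
    if (length(missing)) {
      msg <- paste0(length(missing), " table taxa absent from tree (e.g. ",
                    paste(utils::head(missing, 3), collapse = ", "), ")")
      if (strict) abort_arg(msg)
      warning(msg, "; dropping them")
      table <- subset_table(table,
                            taxa = setdiff(rownames(table$counts), missing))
    }
  }
  list(table = table, tree = phylo)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Chains rarefaction (optional), alpha diversity, per-stage community
#' assembly (betaNTI fractions), per-stage taxon filtering, SparCC,
#' network construction, Zi-Pi keystone classification, and the
#' with/without-cyanobacteria stability contrast.  Every output is a plain
#' TSV / GraphML / JSON file under `config$outdir`; a manifest JSON records
#' parameters, seed, package version and input checksums, so that the whole
#' bundle is reproducible from the manifest alone.
#'
#' @param config a [pipeline_config].
#' @param table,tree optional in-memory inputs overriding the config paths.
#' @return invisibly, a list with the main in-memory results and the output
#'   paths.
#' @export
run_full_pipeline <- function(config, table = NULL, tree = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage_ctx <- "input"
  on_stage <- function(s) stage_ctx <<- s
  tryCatch({
    if (is.null(table)) {
      inp <- read_inputs(config$counts, config$taxonomy, config$metadata,
                         config$tree, config$strict)
      table <- inp$table
      tree <- inp$tree
    }
    if (is.null(tree) && !is.null(config$tree))
      tree <- ape::read.tree(config$tree)

    if (!is.null(config$rarefaction_depth)) {
      on_stage("rarefaction")
      table <- rarefy(table, config$rarefaction_depth,
                      split_seed(config$rng_seed, "rarefy"))
    }

    on_stage("diversity")
    div <- alpha_diversity(table)
    paths$diversity <- write_tsv(div, file.path(config$outdir,
                                                "diversity.tsv"))

    asm <- NULL
    if (!is.null(tree)) {
      on_stage("assembly")
      asm <- stage_fractions(table, tree, n_null = config$n_null,
                             rng_seed = split_seed(config$rng_seed,
                                                   "assembly"))
      paths$bnti <- write_tsv(asm$bnti, file.path(config$outdir,
                                                  "bnti_pairs.tsv"))
      paths$assembly <- write_tsv(asm$stage_fractions,
                                  file.path(config$outdir,
                                            "assembly_fractions.tsv"))
    }

    stages <- unique(table$sample_meta$stage)
    nets <- list()
    roles_all <- list()
    stab_all <- list()
    for (st in stages) {
      on_stage(paste0("network[", st, "]"))
      net <- tryCatch({
        ft <- filter_taxa(table, stage = st,
                          min_rel_abund = config$min_rel_abund,
                          min_prevalence = config$min_prevalence)
        corr <- sparcc(ft$counts, n_boot = config$n_boot,
                       rng_seed = split_seed(config$rng_seed,
                                             paste0("sparcc-", st)),
                       n_exclusion_iter = config$sparcc_exclusion_iter,
                       exclusion_threshold =
                         config$sparcc_exclusion_threshold,
                       pseudocount = config$pseudocount)
        build_network(corr, ft, config$r_min, config$p_max)
      }, error = function(e) NULL)
      if (is.null(net)) {
        warning("stage ", st, ": no network (filter or thresholds too ",
                "strict); skipped")
        next
      }
      nets[[st]] <- net
      mem <- detect_modules(net)
      roles <- classify_roles(zipi(net, mem))
      roles$stage <- st
      roles_all[[st]] <- roles
      write_network(net,
                    file.path(config$outdir, paste0("network_", st,
                                                    ".graphml")),
                    file.path(config$outdir, paste0("nodes_", st, ".csv")),
                    file.path(config$outdir, paste0("edges_", st, ".csv")))

      on_stage(paste0("stability[", st, "]"))
      if (any(as.logical(igraph::V(net)$is_cyanobacterium)) &&
          igraph::vcount(net) >= 3) {
        cmp <- tryCatch(
          compare_with_without_group(
            net, fraction = config$removal_fraction,
            n_perm = config$n_perm,
            rng_seed = split_seed(config$rng_seed,
                                  paste0("stability-", st))),
          error = function(e) NULL)
        if (!is.null(cmp)) {
          rb <- tapply(cmp$robustness$robustness, cmp$robustness$network,
                       mean)
          stab_all[[st]] <- data.frame(
            stage = st,
            robustness_ctr = unname(rb["ctr"]),
            robustness_cyr = unname(rb["cyr"]),
            vulnerability_ctr = unname(cmp$vulnerability["ctr"]),
            vulnerability_cyr = unname(cmp$vulnerability["cyr"]),
            p_value = cmp$p_value, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(roles_all))
      paths$roles <- write_tsv(do.call(rbind, roles_all),
                               file.path(config$outdir, "zipi_roles.tsv"))
    if (length(stab_all))
      paths$stability <- write_tsv(do.call(rbind, stab_all),
                                   file.path(config$outdir,
                                             "stability.tsv"))

    on_stage("manifest")
    infiles <- unlist(config[c("counts", "taxonomy", "metadata", "tree")])
    manifest <- list(
      package = "crustnet",
      version = as.character(utils::packageVersion("crustnet")),
      parameters = config[setdiff(names(config),
                                  c("counts", "taxonomy", "metadata",
                                    "tree", "outdir"))],
      inputs = if (length(infiles))
        as.list(tools::md5sum(infiles[file.exists(infiles)])) else NULL,
      outputs = lapply(paths, basename))
    paths$manifest <- file.path(config$outdir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         null = "null", digits = NA, pretty = TRUE)
    invisible(list(table = table, diversity = div, assembly = asm,
                   networks = nets,
                   roles = if (length(roles_all)) do.call(rbind, roles_all),
                   stability = if (length(stab_all))
                     do.call(rbind, stab_all),
                   paths = paths))
  }, error = function(e) {
    # keep whatever was written, flagged as partial
    for (p in unlist(paths))
      if (file.exists(p)) file.rename(p, paste0(p, ".partial"))
    stop("pipeline failed at stage '", stage_ctx, "': ",
         conditionMessage(e), call. = FALSE)
  })
}
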