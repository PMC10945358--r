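#' Configure a full pipeline run
#'
#' @param rarefaction_depth Reads per sample after rarefaction. The study
#'   convention is 39575; `NULL` (default) rarefies to the smallest sample
#'   total so synthetic or shallower datasets run unchanged.
#' @param top_n Number of most abundant taxa used for network inference
#'   (default 2000).
#' @param sparcc A [sparcc_config()].
#' @param group_var Metadata column splitting samples into independently
#'   analysed networks (default `"land_use"`, i.e. separate natural and
#'   cultivated networks).
#' @param gs_trait Trait used for gene significance (default `"CMR"`).
#' @param module_method Module detection algorithm, see [detect_modules()].
#' @param seed Integer seed for rarefaction (SparCC carries its own seed).
#' @param out_dir Optional directory; when set, every stage's tables plus a
#'   run manifest are written beneath it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(rarefaction_depth = NULL, top_n = 2000,
                       sparcc = sparcc_config(), group_var = "land_use",
                       gs_trait = "CMR", module_method = "greedy",
                       seed = 1, out_dir = NULL) {
  structure(list(rarefaction_depth = rarefaction_depth, top_n = top_n,
                 sparcc = sparcc, group_var = group_var, gs_trait = gs_trait,
                 module_method = module_method, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

analyse_one_group <- function(table, metadata, traits, config, group_label,
                              annotations) {
  log <- character()
  note <- function(msg) log <<- c(log, paste0("[", group_label, "] ", msg))

  table <- stage("remove_archaea", remove_archaea(table))
  depth <- config$rarefaction_depth
  if (is.null(depth)) depth <- min(colSums(table$counts))
  table <- stage("rarefy", rarefy(table, depth = depth, seed = config$seed))
  table <- stage("top_abundant", top_abundant(table, n = config$top_n))
  note(paste(utils::tail(table$provenance, 3), collapse = "; "))

  rho <- stage("sparcc", sparcc(table, config$sparcc))
  pval <- stage("permutation_pvalues",
                permutation_pvalues(table, rho, config$sparcc))
  net <- stage("build_network", build_network(rho, pval, config$sparcc))
  part <- stage("detect_modules",
                detect_modules(net, seed = config$seed,
                               method = config$module_method))
  roles <- stage("node_roles", node_roles(net, part))
  rel <- stage("relative_abundance", relative_abundance(table))
  eigs <- stage("module_eigengene", module_eigengene(rel, part))
  mt <- stage("module_trait_correlation",
              module_trait_correlation(eigs, traits))
  scores <- stage("gene_scores",
                  gene_scores(rel, part, eigs, traits,
                              trait_name = config$gs_trait))
  scores <- hub_genes(scores, alpha = config$sparcc$alpha)
  keystones <- stage("keystone_report",
                     suppressWarnings(
                       keystone_report(scores, roles,
                                       taxonomy = table$taxonomy,
                                       annotations = annotations)))
  list(group = group_label, table = table, rho = rho, pval = pval,
       network = net, partition = part, roles = roles, eigengenes = eigs,
       module_trait = mt, scores = scores, keystones = keystones,
       summary = topology_summary(net, part), log = log)
}

write_group_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(res$table, file.path(dir, "filtered_otu.tsv"),
                  taxonomy_path = file.path(dir, "taxonomy.tsv"))
  write_network(res$network, dir)
  utils::write.table(res$roles, file.path(dir, "node_roles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$eigengenes$eigengenes)) {
    eg <- data.frame(sample_id = rownames(res$eigengenes$eigengenes),
                     res$eigengenes$eigengenes, check.names = FALSE)
    utils::write.table(eg, file.path(dir, "eigengenes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(res$module_trait, file.path(dir, "module_trait.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$scores, file.path(dir, "gene_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$keystones, file.path(dir, "keystones.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$summary, file.path(dir, "topology_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Run the full keystone-taxa analysis per group
#'
#' Executes, independently for each level of the grouping variable
#' (natural and cultivated by default): archaea removal, rarefaction,
#' most-abundant-taxa selection, SparCC correlation, permutation p-values,
#' network thresholding, module detection, Zi-Pi role classification,
#' module eigengenes, module-trait correlations, GS/MM gene scores,
#' hub-gene calls and the keystone report. With an output directory
#' configured, all stage tables plus a manifest (package version, seed,
#' configuration echo, md5 of every written file) are emitted per group.
#'
#' @param counts A [otu_table()].
#' @param metadata Sample metadata with `sample_id` and the grouping
#'   column.
#' @param traits Trait data.frame with `sample_id`.
#' @param config A [run_config()].
#' @param annotations Optional per-taxon C-metabolism annotation table, see
#'   [keystone_report()].
#' @return A named list with one result bundle per group level.
#' @export
run_group_analysis <- function(counts, metadata, traits,
                               config = run_config(), annotations = NULL) {
  stopifnot(inherits(counts, "peatnet_otu"), inherits(config, "run_config"))
  if (!config$group_var %in% names(metadata)) {
    stop("grouping variable `", config$group_var, "` not in metadata",
         call. = FALSE)
  }
  groups <- unique(metadata[[config$group_var]])
  results <- list()
  for (g in groups) {
    ids <- metadata$sample_id[metadata[[config$group_var]] == g]
    ids <- intersect(ids, colnames(counts$counts))
    sub <- counts
    sub$counts <- counts$counts[, ids, drop = FALSE]
    sub <- log_step(sub, paste0("subset to group ", g, ": ",
                                length(ids), " samples"))
    results[[g]] <- analyse_one_group(sub, metadata, traits, config, g,
                                      annotations)
    if (!is.null(config$out_dir)) {
      write_group_outputs(results[[g]], file.path(config$out_dir, g))
    }
  }
  if (!is.null(config$out_dir)) {
    write_manifest(results, config)
  }
  results
}

write_manifest <- function(results, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "MANIFEST.txt"]
  md5 <- tools::md5sum(files)
  lines <- c(
    paste0("peatnet version: ",
           as.character(utils::packageVersion("peatnet"))),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("seed: ", config$seed),
    paste0("sparcc seed: ", config$sparcc$seed),
    paste0("rarefaction depth: ",
           ifelse(is.null(config$rarefaction_depth), "min sample total",
                  config$rarefaction_depth)),
    paste0("top_n: ", config$top_n),
    paste0("correlation threshold: ", config$sparcc$correlation_threshold),
    paste0("alpha: ", config$sparcc$alpha),
    paste0("n_resamples: ", config$sparcc$n_resamples),
    paste0("n_permutations: ", config$sparcc$n_permutations),
    paste0("group_var: ", config$group_var),
    paste0("gs_trait: ", config$gs_trait),
    "",
    "files (md5):",
    paste0(md5, "  ", substring(names(md5), nchar(config$out_dir) + 2))
  )
  writeLines(lines, file.path(config$out_dir, "MANIFEST.txt"))
  invisible(NULL)
}
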