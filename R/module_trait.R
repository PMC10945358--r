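#' Module eigengenes
#'
#' For each module, member relative abundances are standardized per taxon
#' (mean 0, sd 1 across samples) and the eigengene is the first principal
#' component of the resulting samples-by-members matrix: a single unit-norm
#' profile (one score per sample) summarizing the module. Principal
#' components are sign-ambiguous, so each eigengene is oriented to
#' correlate positively with the mean standardized member profile; the
#' fraction of member variance it explains is reported. Constant-abundance
#' members are dropped with a warning; a module reduced below 2 members is
#' skipped and reported.
#'
#' @param rel_abund Relative-abundance matrix (taxa x samples), e.g. from
#'   [relative_abundance()].
#' @param part A [detect_modules()] partition whose nodes are rows of
#'   `rel_abund`.
#' @return An object of class `eigengene_set`: `eigengenes` (samples x
#'   modules matrix, unit-norm columns), `variance_explained` (named
#'   fraction per module), `skipped` (module indices not computable).
#' @export
module_eigengene <- function(rel_abund, part) {
  stopifnot(inherits(part, "module_partition"))
  mods <- sort(unique(part$membership))
  n <- ncol(rel_abund)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  eig <- list()
  varexp <- c()
  skipped <- integer()
  for (m in mods) {
    members <- names(part$membership)[part$membership == m]
    members <- intersect(members, rownames(rel_abund))
    X <- t(rel_abund[members, , drop = FALSE])  # samples x members
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0)) {
      warning("module ", m, ": dropped ", sum(sds == 0),
              " constant-abundance member(s)", call. = FALSE)
      X <- X[, sds > 0, drop = FALSE]
    }
    if (ncol(X) < 2) {
      skipped <- c(skipped, m)
      next
    }
    Xs <- scale(X)
    sv <- svd(Xs)
    e <- sv$u[, 1]  # unit Euclidean norm by construction
    profile <- rowMeans(Xs)
    # orientation undefined when members cancel to a flat mean profile
    if (stats::sd(profile) > 0 && stats::cor(e, profile) < 0) e <- -e
    eig[[as.character(m)]] <- e
    varexp[as.character(m)] <- sv$d[1]^2 / sum(sv$d^2)
  }
  if (length(skipped)) {
    warning("module(s) skipped (fewer than 2 usable members): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  E <- do.call(cbind, eig)
  if (!is.null(E)) {
    rownames(E) <- colnames(rel_abund)
    colnames(E) <- paste0("module", names(eig))
  }
  structure(list(eigengenes = E, variance_explained = varexp,
                 skipped = skipped),
            class = "eigengene_set")
}

#' Module-trait correlations
#'
#' Pearson correlation (with two-sided p-value and significance stars:
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001) between every module
#' eigengene and every soil trait. Sample IDs are aligned by name; missing
#' trait values are dropped pairwise. Associations with fewer than 3
#' complete pairs are marked not-computable (NA).
#'
#' @param eigs An [module_eigengene()] result.
#' @param traits Trait data.frame with a `sample_id` column.
#' @return A data.frame with columns `module`, `trait`, `r`, `p`, `n`,
#'   `stars`.
#' @export
module_trait_correlation <- function(eigs, traits) {
  stopifnot(inherits(eigs, "eigengene_set"))
  E <- eigs$eigengenes
  common <- intersect(rownames(E), traits$sample_id)
  if (length(common) < 3) {
    stop("fewer than 3 samples shared between eigengenes and traits",
         call. = FALSE)
  }
  E <- E[common, , drop = FALSE]
  tr <- traits[match(common, traits$sample_id), , drop = FALSE]
  trait_names <- setdiff(names(tr), "sample_id")
  out <- expand.grid(module = colnames(E), trait = trait_names,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i) {
    pearson_with_p(E[, out$module[i]], tr[[out$trait[i]]])
  })
  out$r <- vapply(res, `[[`, numeric(1), "r")
  out$p <- vapply(res, `[[`, numeric(1), "p")
  out$n <- vapply(res, `[[`, numeric(1), "n")
  out$stars <- p_stars(out$p)
  out
}

#' Gene significance (GS) and module membership (MM) per taxon
#'
#' GS is the Pearson correlation (with p) of each taxon's standardized
#' abundance with an external trait (default CMR); MM is the correlation
#' with the taxon's own-module eigengene. Both are computed on the same
#' aligned sample set. Constant taxon profiles are flagged with NA scores.
#'
#' @param rel_abund Relative-abundance matrix (taxa x samples).
#' @param part A [detect_modules()] partition.
#' @param eigs The matching [module_eigengene()] result.
#' @param traits Trait data.frame with `sample_id`.
#' @param trait_name Trait used for GS (default `"CMR"`).
#' @return A data.frame with columns `node`, `module`, `GS`, `GS_p`, `MM`,
#'   `MM_p`.
#' @export
gene_scores <- function(rel_abund, part, eigs, traits, trait_name = "CMR") {
  stopifnot(inherits(part, "module_partition"),
            inherits(eigs, "eigengene_set"))
  if (!trait_name %in% names(traits)) {
    stop("trait `", trait_name, "` not found in trait table", call. = FALSE)
  }
  E <- eigs$eigengenes
  common <- intersect(rownames(E), traits$sample_id)
  tr <- traits[[trait_name]][match(common, traits$sample_id)]
  nodes <- names(part$membership)
  nodes <- intersect(nodes, rownames(rel_abund))
  out <- data.frame(node = nodes,
                    module = as.integer(part$membership[nodes]),
                    GS = NA_real_, GS_p = NA_real_,
                    MM = NA_real_, MM_p = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(nodes)) {
    x <- rel_abund[nodes[i], common]
    if (stats::sd(x) == 0) next  # constant profile: scores undefined
    gs <- pearson_with_p(x, tr)
    out$GS[i] <- gs$r
    out$GS_p[i] <- gs$p
    mod_col <- paste0("module", out$module[i])
    if (mod_col %in% colnames(E)) {
      mm <- pearson_with_p(x, E[common, mod_col])
      out$MM[i] <- mm$r
      out$MM_p[i] <- mm$p
    }
  }
  out
}

#' Hub-gene calls
#'
#' A taxon is a hub gene when both its gene significance and its module
#' membership are significant: `GS_p < alpha` AND `MM_p < alpha` (raw
#' p-values, alpha = 0.05 by default).
#'
#' @param scores A [gene_scores()] result.
#' @param alpha Significance level applied to both p-values.
#' @return `scores` with an added logical `hub_gene` column (NA scores give
#'   FALSE).
#' @export
hub_genes <- function(scores, alpha = 0.05) {
  scores$hub_gene <- !is.na(scores$GS_p) & !is.na(scores$MM_p) &
    scores$GS_p < alpha & scores$MM_p < alpha
  scores
}

#' Keystone-taxon report
#'
#' Combines both lines of evidence: a taxon is a keystone candidate when it
#' is a hub gene OR a critical node (module hub, connector or network hub),
#' and a keystone when it additionally carries a carbon-metabolism function
#' flag. The function flag is a user-supplied annotation (literature-based
#' functional assignment is outside computational scope); when no
#' annotation table is given, all candidates pass the function gate and a
#' warning notes that criterion 2 was not screened.
#'
#' @param scores A [hub_genes()] result.
#' @param roles A [node_roles()] table for the same network.
#' @param taxonomy Optional named lineage vector used to annotate the
#'   report.
#' @param annotations Optional data.frame with columns `node` and
#'   `function_flag` (logical: known C-metabolism function).
#' @return A data.frame (one row per node) with the full evidence trail:
#'   taxonomy, module, role, GS/MM p-values, `hub_gene`, `critical_node`,
#'   `function_flag` and the final `keystone` call.
#' @export
keystone_report <- function(scores, roles, taxonomy = NULL,
                            annotations = NULL) {
  stopifnot(inherits(roles, "node_roles"))
  critical <- c("module hub", "connector", "network hub")
  out <- merge(scores, roles[, c("node", "Zi", "Pi", "role")], by = "node",
               sort = TRUE)
  out$critical_node <- out$role %in% critical
  if (is.null(annotations)) {
    warning("no function annotations supplied: C-metabolism criterion ",
            "not screened, all candidates pass", call. = FALSE)
    out$function_flag <- TRUE
  } else {
    stopifnot(all(c("node", "function_flag") %in% names(annotations)))
    out$function_flag <- annotations$function_flag[
      match(out$node, annotations$node)]
    out$function_flag[is.na(out$function_flag)] <- FALSE
  }
  out$keystone <- (out$hub_gene | out$critical_node) & out$function_flag
  if (!is.null(taxonomy)) {
    out$taxonomy <- unname(taxonomy[out$node])
  }
  out
}
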