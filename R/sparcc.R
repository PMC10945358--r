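#' Configure SparCC inference and network construction
#'
#' SparCC estimates correlations between latent (basis) taxon abundances
#' from compositional fractions via log-ratio variances, sidestepping the
#' spurious negative correlations induced by the fixed per-sample total.
#' The iteration internals (Dirichlet resample count, strongly-correlated
#' pair exclusion, median aggregation, +1 pseudocount, shuffle-per-taxon
#' permutation null with an add-one p-value estimator) follow the original
#' method's conventions; every value is configurable.
#'
#' @param n_resamples Dirichlet posterior draws per estimate (default 20).
#' @param exclusion_threshold Pairs with |rho| above this are iteratively
#'   excluded from the basis-variance system (default 0.1).
#' @param max_exclusion_rounds Maximum exclusion iterations (default 10).
#' @param n_permutations Permutations for the significance test
#'   (default 100).
#' @param correlation_threshold Absolute correlation needed to keep an edge
#'   (default 0.6).
#' @param alpha Significance level for edge retention (default 0.05).
#' @param p_adjust `"none"` (raw p-values, the default) or `"BH"` for
#'   Benjamini-Hochberg adjustment across off-diagonal pairs before
#'   thresholding.
#' @param seed Integer seed controlling resampling and permutations.
#' @return An object of class `sparcc_config`.
#' @export
sparcc_config <- function(n_resamples = 20, exclusion_threshold = 0.1,
                          max_exclusion_rounds = 10, n_permutations = 100,
                          correlation_threshold = 0.6, alpha = 0.05,
                          p_adjust = c("none", "BH"), seed = 1) {
  p_adjust <- match.arg(p_adjust)
  if (n_resamples < 1 || max_exclusion_rounds < 0) {
    stop("resample and round counts must be >= 1 (rounds >= 0)", call. = FALSE)
  }
  if (exclusion_threshold <= 0 || exclusion_threshold >= 1 ||
      correlation_threshold <= 0 || correlation_threshold >= 1 ||
      alpha <= 0 || alpha >= 1) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  structure(list(n_resamples = as.integer(n_resamples),
                 exclusion_threshold = exclusion_threshold,
                 max_exclusion_rounds = as.integer(max_exclusion_rounds),
                 n_permutations = as.integer(n_permutations),
                 correlation_threshold = correlation_threshold,
                 alpha = alpha, p_adjust = p_adjust,
                 seed = as.integer(seed)),
            class = "sparcc_config")
}

#' Pairwise log-ratio variances
#'
#' The SparCC summary statistic: `t[i, j]` is the variance across samples
#' of `log(x_i / x_j)`. Computed from the covariance matrix of log
#' fractions, so `t[i, j] = var(log x_i) + var(log x_j) -
#' 2 cov(log x_i, log x_j)`.
#'
#' @param fractions Strictly positive fraction matrix, taxa x samples
#'   (pseudocounts applied upstream).
#' @return A symmetric matrix with zero diagonal.
#' @export
log_ratio_variances <- function(fractions) {
  p <- nrow(fractions)
  if (p < 4) {
    stop("SparCC needs at least 4 taxa (basis system under-determined)",
         call. = FALSE)
  }
  if (any(fractions <= 0)) {
    stop("fractions must be strictly positive", call. = FALSE)
  }
  L <- log(fractions)
  C <- stats::cov(t(L))
  v <- diag(C)
  t_mat <- outer(v, v, "+") - 2 * C
  t_mat[t_mat < 0] <- 0  # numerical noise on near-proportional pairs
  diag(t_mat) <- 0
  t_mat
}

#' Basis correlations from log-ratio variances
#'
#' Solves the SparCC linear system for basis variances omega (matrix with
#' p - 1 on the diagonal and 1 elsewhere, right-hand side the row sums of
#' the log-ratio variance matrix), forms
#' `rho[i, j] = (omega_i + omega_j - t[i, j]) / (2 sqrt(omega_i omega_j))`,
#' then iteratively excludes the most strongly correlated pair
#' (|rho| above the exclusion threshold, strongest first) from the system
#' and re-solves, up to the configured number of rounds. Correlations are
#' clamped to [-1, 1] with a unit diagonal; non-positive basis variances
#' are floored at a tiny epsilon with a warning.
#'
#' @param t_mat Log-ratio variance matrix from [log_ratio_variances()].
#' @param config A [sparcc_config()].
#' @return The estimated basis correlation matrix.
#' @export
basis_correlations <- function(t_mat, config = sparcc_config()) {
  p <- nrow(t_mat)
  if (p < 4) stop("need at least 4 taxa", call. = FALSE)
  M <- matrix(1, p, p)
  diag(M) <- p - 1
  t_work <- t_mat
  excluded <- matrix(FALSE, p, p)
  floored <- FALSE
  rho <- NULL
  for (round in 0:config$max_exclusion_rounds) {
    omega <- tryCatch(solve(M, rowSums(t_work)),
                      error = function(e) stop(
                        "SparCC basis system is singular: ",
                        conditionMessage(e), call. = FALSE))
    if (any(omega <= 0)) {
      floored <- TRUE
      omega[omega <= 0] <- 1e-10
    }
    rho <- (outer(omega, omega, "+") - t_mat) /
      (2 * sqrt(outer(omega, omega, "*")))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    if (round == config$max_exclusion_rounds) break
    cand <- abs(rho)
    cand[excluded] <- -Inf
    diag(cand) <- -Inf
    # never let a component lose so many partners that the system turns
    # singular: keep every diagonal entry of M at 2 or more
    repeat {
      best <- which.max(cand)
      if (cand[best] <= config$exclusion_threshold) break
      i <- (best - 1L) %% p + 1L
      j <- (best - 1L) %/% p + 1L
      if (M[i, i] - 1 >= 2 && M[j, j] - 1 >= 2) break
      cand[best] <- -Inf
      cand[j + (i - 1L) * p] <- -Inf
    }
    if (cand[best] <= config$exclusion_threshold) break
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    t_work[i, j] <- t_work[j, i] <- 0
  }
  if (floored) {
    warning("non-positive basis variance(s) floored at 1e-10", call. = FALSE)
  }
  rho
}

counts_matrix <- function(table) {
  if (inherits(table, "peatnet_otu")) table$counts else as.matrix(table)
}

sparcc_once <- function(counts, config) {
  p <- nrow(counts)
  n <- ncol(counts)
  # one Dirichlet posterior draw of fractions per sample (+1 pseudocount)
  g <- matrix(stats::rgamma(p * n, shape = counts + 1), nrow = p)
  fractions <- sweep(g, 2L, colSums(g), "/")
  basis_correlations(log_ratio_variances(fractions), config)
}

#' SparCC correlation matrix for an OTU table
#'
#' Runs [basis_correlations()] on `n_resamples` Dirichlet-smoothed fraction
#' draws (counts + 1 pseudocount as Dirichlet parameters, one independent
#' draw per sample) and returns the element-wise median. Deterministic
#' under a fixed seed.
#'
#' @param table A [otu_table()] or a counts matrix (taxa x samples).
#' @param config A [sparcc_config()].
#' @return A symmetric correlation matrix with unit diagonal, named by
#'   taxon.
#' @export
sparcc <- function(table, config = sparcc_config()) {
  counts <- counts_matrix(table)
  set.seed(config$seed)
  draws <- withCallingHandlers(
    lapply(seq_len(config$n_resamples), function(r) sparcc_once(counts, config)),
    warning = function(w) {
      if (grepl("basis variance", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  rho <- apply(simplify2array(draws), c(1, 2), stats::median)
  dimnames(rho) <- list(rownames(counts), rownames(counts))
  diag(rho) <- 1
  rho
}

#' Permutation p-values for SparCC correlations
#'
#' Builds the null by independently shuffling each taxon's counts across
#' samples (destroying all between-taxon association while preserving each
#' taxon's marginal distribution), recomputing the full SparCC matrix per
#' permutation, and applying the add-one estimator
#' `p[i, j] = (1 + #\{perm : |rho_perm| >= |rho_obs|\}) / (1 + n_permutations)`.
#' Two-sided by construction; the diagonal is set to 0 by convention.
#'
#' @param table A [otu_table()] or counts matrix used for the observed
#'   estimate.
#' @param rho_obs The observed SparCC matrix from [sparcc()].
#' @param config The same [sparcc_config()] used for the observed estimate.
#' @return A symmetric p-value matrix.
#' @export
permutation_pvalues <- function(table, rho_obs, config = sparcc_config()) {
  if (config$n_permutations < 1) {
    stop("`n_permutations` must be >= 1", call. = FALSE)
  }
  counts <- counts_matrix(table)
  p <- nrow(counts)
  n <- ncol(counts)
  exceed <- matrix(0, p, p)
  abs_obs <- abs(rho_obs)
  set.seed(config$seed + 1L)
  for (b in seq_len(config$n_permutations)) {
    perm <- counts
    for (i in seq_len(p)) perm[i, ] <- perm[i, sample.int(n)]
    # nested seed per permutation keeps the Dirichlet stream reproducible
    sub_cfg <- config
    sub_cfg$seed <- config$seed + 1L + b
    rho_perm <- sparcc(perm, sub_cfg)
    exceed <- exceed + (abs(rho_perm) >= abs_obs)
  }
  pval <- (1 + exceed) / (1 + config$n_permutations)
  diag(pval) <- 0
  dimnames(pval) <- dimnames(rho_obs)
  pval
}

#' Threshold correlations into a co-occurrence network
#'
#' Retains off-diagonal pairs with `|rho| >= correlation_threshold` AND
#' `p < alpha` (both configurable; optionally BH-adjusted p-values). Edge
#' signs follow the sign of the retained correlation.
#'
#' @param rho Symmetric SparCC correlation matrix.
#' @param pval Symmetric permutation p-value matrix.
#' @param config A [sparcc_config()].
#' @return An object of class `correlation_network` with fields `taxa`,
#'   `rho`, `pval`, `adjacency`, `edge_sign` and a `summary` of node/edge
#'   counts.
#' @export
build_network <- function(rho, pval, config = sparcc_config()) {
  if (!isSymmetric(unname(rho), tol = 1e-8) ||
      !isSymmetric(unname(pval), tol = 1e-8)) {
    stop("`rho` and `pval` must be symmetric", call. = FALSE)
  }
  if (!all(dim(rho) == dim(pval))) {
    stop("`rho` and `pval` must be conformable", call. = FALSE)
  }
  p_use <- pval
  if (config$p_adjust == "BH") {
    ut <- upper.tri(pval)
    adj <- stats::p.adjust(pval[ut], method = "BH")
    p_use[ut] <- adj
    p_use <- pmin(p_use, t(p_use))
    diag(p_use) <- 0
  }
  adjacency <- (abs(rho) >= config$correlation_threshold) &
    (p_use < config$alpha)
  diag(adjacency) <- FALSE
  adjacency <- adjacency * 1L
  edge_sign <- sign(rho) * adjacency
  n_edges <- sum(adjacency[upper.tri(adjacency)])
  net <- structure(list(
    taxa = rownames(rho),
    rho = rho, pval = pval, adjacency = adjacency, edge_sign = edge_sign,
    summary = list(
      n_nodes = nrow(rho),
      n_edges = n_edges,
      n_positive = sum(edge_sign[upper.tri(edge_sign)] > 0),
      n_negative = sum(edge_sign[upper.tri(edge_sign)] < 0)
    )
  ), class = "correlation_network")
  net
}

#' @export
print.correlation_network <- function(x, ...) {
  s <- x$summary
  cat("Co-occurrence network:", s$n_nodes, "nodes,", s$n_edges, "edges (",
      s$n_positive, "positive /", s$n_negative, "negative )\n")
  invisible(x)
}

#' Edge list of a thresholded network
#'
#' @param net A [build_network()] result.
#' @return A data.frame with columns `source`, `target`, `rho`, `p`, `sign`.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "correlation_network"))
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1, arr.ind = TRUE)
  data.frame(
    source = net$taxa[idx[, 1]],
    target = net$taxa[idx[, 2]],
    rho = net$rho[idx],
    p = net$pval[idx],
    sign = ifelse(net$rho[idx] >= 0, 1L, -1L),
    stringsAsFactors = FALSE
  )
}

#' Convert a network to an igraph object
#'
#' Unweighted, unsigned graph over all nodes (isolated nodes included);
#' edges carry `rho`, `p` and `sign` attributes.
#'
#' @param net A [build_network()] result.
#' @return An igraph graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "correlation_network"))
  edges <- network_edges(net)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = net$taxa))
}

#' Write network artifacts
#'
#' Writes the correlation and p-value matrices (TSV, symmetric with
#' header), the edge list, and a GraphML export of the thresholded graph.
#'
#' @param net A [build_network()] result.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_network <- function(net, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sym <- function(m, path) {
    df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_sym(net$rho, file.path(dir, paste0(prefix, "_rho.tsv")))
  write_sym(net$pval, file.path(dir, paste0(prefix, "_pval.tsv")))
  utils::write.table(network_edges(net),
                     file.path(dir, paste0(prefix, "_edges.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  igraph::write_graph(as_igraph(net),
                      file.path(dir, paste0(prefix, ".graphml")),
                      format = "graphml")
  invisible(dir)
}
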