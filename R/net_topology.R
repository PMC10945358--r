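#' Detect modules in a co-occurrence network
#'
#' Partitions the non-isolated nodes of the thresholded network into
#' modules (clusters of closely connected nodes) by greedy modularity
#' maximization (Clauset-Newman-Moore) on the unweighted, unsigned
#' adjacency; edge signs play no role in topology and are kept for
#' reporting only. The greedy algorithm is deterministic; `method =
#' "louvain"` is available with seed control for users who prefer it.
#' Isolated nodes are excluded from the partition and reported.
#'
#' @param net A [build_network()] result with at least one edge.
#' @param seed Integer seed (used by the Louvain option).
#' @param method `"greedy"` (default) or `"louvain"`.
#' @return An object of class `module_partition`: `membership` (named
#'   integer vector over non-isolated nodes), `modularity_Q`, `n_modules`,
#'   `isolated` (node names left out).
#' @export
detect_modules <- function(net, seed = 1, method = c("greedy", "louvain")) {
  stopifnot(inherits(net, "correlation_network"))
  method <- match.arg(method)
  if (net$summary$n_edges == 0) {
    stop("network has no edges; nothing to partition", call. = FALSE)
  }
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  isolated <- names(deg)[deg == 0]
  g <- igraph::delete_vertices(g, isolated)
  if (method == "greedy") {
    comm <- igraph::cluster_fast_greedy(g)
    # cut the dendrogram at the fewest communities whose modularity ties
    # the maximum within numerical tolerance (floating-point noise in the
    # merge sequence can otherwise leave a spurious extra module, e.g. on
    # a single clique)
    qs <- comm$modularity
    q_best <- max(qs)
    n_comms <- igraph::vcount(g) - (which(qs >= q_best - 1e-10) - 1L)
    target <- min(n_comms)
    membership <- if (target == length(igraph::membership(comm))) {
      igraph::membership(comm)
    } else {
      igraph::cut_at(comm, no = target)
    }
    names(membership) <- igraph::V(g)$name
    q_final <- igraph::modularity(g, membership)
  } else {
    set.seed(seed)
    comm <- igraph::cluster_louvain(g)
    membership <- igraph::membership(comm)
    q_final <- igraph::modularity(comm)
  }
  # relabel modules 1..K in order of first appearance by node ID for a
  # deterministic, input-order-independent labelling
  node_order <- sort(names(membership))
  first_seen <- membership[node_order][!duplicated(membership[node_order])]
  relabel <- setNames(seq_along(first_seen), first_seen)
  membership <- setNames(as.integer(relabel[as.character(membership)]),
                         names(membership))
  structure(list(
    membership = membership,
    modularity_Q = q_final,
    n_modules = length(unique(membership)),
    isolated = isolated
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Module partition:", x$n_modules, "modules over",
      length(x$membership), "nodes (Q =", round(x$modularity_Q, 3), ")\n")
  if (length(x$isolated)) {
    cat("Isolated nodes excluded:", length(x$isolated), "\n")
  }
  invisible(x)
}

#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' For every non-isolated node: `k_i` is its total degree; `k_is` its
#' number of links to members of its own module s;
#' `Zi = (k_is - mean_s) / sd_s` with mean and sd taken over the nodes of
#' module s (Zi = 0 when sd_s = 0, e.g. in small or degree-regular
#' modules); `Pi = 1 - sum_t (k_it / k_i)^2` over modules t. Nodes are
#' classified as module hubs (Zi > 2.5, Pi <= 0.625), connectors
#' (Zi <= 2.5, Pi > 0.625), network hubs (Zi > 2.5, Pi > 0.625) or
#' peripheral otherwise; module hubs, connectors and network hubs together
#' are the "critical nodes". Boundary values (Zi = 2.5, Pi = 0.625) fall in
#' the lower category.
#'
#' @param net A [build_network()] result.
#' @param part A [detect_modules()] partition of the same network.
#' @return A data.frame (class `node_roles`) with columns `node`, `module`,
#'   `k_i`, `k_is`, `Zi`, `Pi`, `role`.
#' @export
node_roles <- function(net, part) {
  stopifnot(inherits(net, "correlation_network"),
            inherits(part, "module_partition"))
  nodes <- names(part$membership)
  A <- net$adjacency[nodes, nodes, drop = FALSE]
  memb <- part$membership[nodes]
  mods <- sort(unique(memb))
  # K[i, t]: links of node i into module t (matrix form)
  ind <- vapply(mods, function(m) as.numeric(memb == m),
                numeric(length(nodes)))
  K <- A %*% ind
  k_i <- rowSums(K)
  k_is <- K[cbind(seq_along(nodes), match(memb, mods))]
  zi <- numeric(length(nodes))
  for (m in mods) {
    members <- which(memb == m)
    mu <- mean(k_is[members])
    sdv <- stats::sd(k_is[members])
    zi[members] <- if (is.na(sdv) || sdv == 0) 0 else (k_is[members] - mu) / sdv
  }
  pi_c <- 1 - rowSums((K / pmax(k_i, 1))^2)
  pi_c[k_i == 0] <- NA_real_
  role <- classify_role(zi, pi_c)
  out <- data.frame(node = nodes, module = as.integer(memb),
                    k_i = as.integer(k_i), k_is = as.integer(k_is),
                    Zi = zi, Pi = pi_c, role = role,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("node_roles", "data.frame")
  out
}

#' Classify nodes on the Zi-Pi plane
#'
#' Strict-inequality thresholds: module hub (Zi > 2.5, Pi <= 0.625),
#' connector (Zi <= 2.5, Pi > 0.625), network hub (Zi > 2.5, Pi > 0.625),
#' peripheral otherwise. Boundary values (Zi = 2.5 or Pi = 0.625) fall in
#' the lower category.
#'
#' @param zi,pi_c Numeric vectors of Zi and Pi values.
#' @param zi_threshold,pi_threshold Classification cut-offs.
#' @return Character vector of roles.
#' @export
classify_role <- function(zi, pi_c, zi_threshold = 2.5,
                          pi_threshold = 0.625) {
  ifelse(zi > zi_threshold & pi_c > pi_threshold, "network hub",
  ifelse(zi > zi_threshold, "module hub",
  ifelse(pi_c > pi_threshold, "connector", "peripheral")))
}

#' Topological summary of a network
#'
#' The quantities compared between the natural and cultivated networks:
#' node, edge, positive-edge, negative-edge and module counts plus
#' modularity Q.
#'
#' @param net A [build_network()] result.
#' @param part Optional [detect_modules()] partition; when absent (e.g.
#'   for an empty network) module count and Q are reported as 0.
#' @return A one-row data.frame.
#' @export
topology_summary <- function(net, part = NULL) {
  stopifnot(inherits(net, "correlation_network"))
  s <- net$summary
  data.frame(
    n_nodes = s$n_nodes,
    n_edges = s$n_edges,
    n_positive = s$n_positive,
    n_negative = s$n_negative,
    n_modules = if (is.null(part)) 0L else part$n_modules,
    modularity_Q = if (is.null(part)) 0 else part$modularity_Q
  )
}
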