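# Small programmatic fixtures shared across test files.

# A tiny OTU table with hand-set counts and mixed taxonomy dialects.
tiny_otu <- function() {
  counts <- matrix(
    c(10L, 5L, 0L,
      3L,  1L, 2L,
      7L,  0L, 1L,
      0L,  4L, 6L),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("T", 1:4), paste0("S", 1:3))
  )
  tax <- c(T1 = "d__Bacteria;p__Acidobacteriota",
           T2 = "d__Archaea;p__Crenarchaeota",
           T3 = "Bacteria;Proteobacteria",
           T4 = "Archaea;Euryarchaeota")
  otu_table(counts, tax)
}

# metadata for an arbitrary number of samples
fake_metadata <- function(n) {
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             site = "JC", land_use = "natural", plot = "P1",
             depth = "0-15 cm", stringsAsFactors = FALSE)
}

# a 100-sample design for simulation-based tests
design_100 <- function() design_spec(n_sites = 5, n_plots_per_type = 5)

# Build a correlation_network directly from hand-set rho/pval matrices.
manual_network <- function(rho, pval, threshold = 0.6, alpha = 0.05) {
  build_network(rho, pval,
                sparcc_config(correlation_threshold = threshold,
                              alpha = alpha))
}

# A network made of two disconnected 5-cliques (nodes n01..n10).
two_cliques_network <- function() {
  p <- 10
  ids <- sprintf("n%02d", 1:p)
  rho <- diag(p)
  dimnames(rho) <- list(ids, ids)
  for (blk in list(1:5, 6:10)) {
    rho[blk, blk] <- 0.9
  }
  diag(rho) <- 1
  pval <- matrix(0.001, p, p, dimnames = dimnames(rho))
  diag(pval) <- 0
  manual_network(rho, pval)
}

# Random sparse network over `p` nodes, for matrix-vs-loop oracles.
random_network <- function(p, seed, edge_prob = 0.15) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(p))
  rho <- matrix(0, p, p, dimnames = list(ids, ids))
  pval <- matrix(1, p, p, dimnames = list(ids, ids))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (stats::runif(1) < edge_prob) {
        r <- stats::runif(1, 0.6, 0.95) * sample(c(-1, 1), 1)
        rho[i, j] <- rho[j, i] <- r
        pval[i, j] <- pval[j, i] <- 0.001
      }
    }
  }
  diag(rho) <- 1
  diag(pval) <- 0
  manual_network(rho, pval)
}

# Per-node loop oracle for Zi and Pi, independent of the matrix code path.
zipi_loop_oracle <- function(net, part) {
  nodes <- names(part$membership)
  A <- net$adjacency[nodes, nodes]
  memb <- part$membership[nodes]
  mods <- sort(unique(memb))
  k_is <- sapply(nodes, function(v) {
    own <- nodes[memb == memb[v]]
    sum(A[v, own])
  })
  zi <- sapply(nodes, function(v) {
    own <- nodes[memb == memb[v]]
    mu <- mean(k_is[own]); sdv <- stats::sd(k_is[own])
    if (is.na(sdv) || sdv == 0) 0 else (k_is[[v]] - mu) / sdv
  })
  pi_c <- sapply(nodes, function(v) {
    k <- sum(A[v, ])
    1 - sum(sapply(mods, function(m) {
      (sum(A[v, nodes[memb == m]]) / k)^2
    }))
  })
  list(Zi = zi, Pi = pi_c)
}
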