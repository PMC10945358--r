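# partition helper: assign given taxa to one module without running
# detection (module machinery is independent of how the partition arose)
manual_partition <- function(members, module = 1L) {
  structure(list(membership = setNames(rep(as.integer(module),
                                           length(members)), members),
                 modularity_Q = NA_real_,
                 n_modules = length(unique(module)),
                 isolated = character()),
            class = "module_partition")
}

rel_matrix <- function(m) {
  sweep(m, 2, colSums(m), "/")
}

test_that("a rank-one module gives a perfect eigengene", {
  set.seed(1)
  base <- runif(10, 1, 5)
  # three members with identical standardized profiles (scaled copies)
  m <- rbind(a = base, b = 2 * base, c = 0.5 * base,
             d = runif(10, 1, 5))
  colnames(m) <- paste0("s", 1:10)
  rel <- rel_matrix(m)
  # use raw proportional profiles: after standardization rows a,b,c of the
  # *numerator* matrix are identical, so feed the numerator matrix itself
  part <- manual_partition(c("a", "b", "c"))
  eigs <- module_eigengene(m, part)
  expect_equal(unname(eigs$variance_explained["1"]), 1, tolerance = 1e-12)
  prof <- scale(m["a", ])[, 1]
  expect_equal(abs(cor(eigs$eigengenes[, "module1"], prof)), 1,
               tolerance = 1e-12)
  expect_equal(sum(eigs$eigengenes[, "module1"]^2), 1, tolerance = 1e-12)
})

test_that("eigengene orientation follows the mean member profile", {
  set.seed(2)
  m <- matrix(rlnorm(5 * 12), 5, 12,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:12)))
  part <- manual_partition(paste0("t", 1:5))
  eigs <- module_eigengene(m, part)
  prof <- rowMeans(scale(t(m)))
  expect_gt(cor(eigs$eigengenes[, "module1"], prof), 0)
})

test_that("eigengene matches an independent eigen-decomposition oracle", {
  set.seed(3)
  m <- matrix(rlnorm(3 * 15), 3, 15,
              dimnames = list(paste0("t", 1:3), paste0("s", 1:15)))
  part <- manual_partition(paste0("t", 1:3))
  eigs <- module_eigengene(m, part)
  # oracle: eigenvector route through the sample covariance of scores
  Xs <- scale(t(m))
  ev <- eigen(Xs %*% t(Xs), symmetric = TRUE)
  oracle <- ev$vectors[, 1]
  if (cor(oracle, rowMeans(Xs)) < 0) oracle <- -oracle
  expect_equal(unname(eigs$eigengenes[, "module1"]), oracle,
               tolerance = 1e-8)
  expect_equal(unname(eigs$variance_explained["1"]),
               ev$values[1] / sum(pmax(ev$values, 0)), tolerance = 1e-8)
})

test_that("eigengene variance explained dominates any single member", {
  set.seed(4)
  m <- matrix(rlnorm(6 * 20), 6, 20,
              dimnames = list(paste0("t", 1:6), paste0("s", 1:20)))
  part <- manual_partition(paste0("t", 1:6))
  eigs <- module_eigengene(m, part)
  Xs <- scale(t(m))
  e <- eigs$eigengenes[, "module1"]
  # fraction of total standardized variance captured by projecting on any
  # single member's profile can never beat the first component
  total <- sum(Xs^2)
  for (j in 1:6) {
    u <- Xs[, j] / sqrt(sum(Xs[, j]^2))
    captured <- sum((t(Xs) %*% u)^2) / total
    expect_gte(unname(eigs$variance_explained["1"]), captured - 1e-10)
  }
})

test_that("constant members are dropped and thin modules skipped", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2), c = c(4, 3, 2, 1))
  colnames(m) <- paste0("s", 1:4)
  part <- manual_partition(c("a", "b", "c"))
  expect_warning(eigs <- module_eigengene(m, part), "constant-abundance")
  expect_equal(ncol(eigs$eigengenes), 1)
  thin <- rbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2))
  colnames(thin) <- paste0("s", 1:4)
  part2 <- manual_partition(c("a", "b"))
  expect_warning(expect_warning(e2 <- module_eigengene(thin, part2),
                                "constant-abundance"),
                 "skipped")
  expect_equal(e2$skipped, 1L)
})

test_that("module-trait correlation recovers exact and null relations", {
  set.seed(5)
  m <- matrix(rlnorm(4 * 20), 4, 20,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:20)))
  part <- manual_partition(paste0("t", 1:4))
  eigs <- module_eigengene(m, part)
  traits <- data.frame(sample_id = paste0("s", 1:20),
                       mirror = eigs$eigengenes[, "module1"],
                       noise = rnorm(20))
  mt <- module_trait_correlation(eigs, traits)
  expect_equal(mt$r[mt$trait == "mirror"], 1, tolerance = 1e-12)
  expect_equal(mt$stars[mt$trait == "mirror"], "***")
  expect_true(abs(mt$r[mt$trait == "noise"]) < 1)
})

test_that("independent traits rarely cross the n = 24 critical value", {
  set.seed(6)
  m <- matrix(rlnorm(4 * 24), 4, 24,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:24)))
  part <- manual_partition(paste0("t", 1:4))
  eigs <- module_eigengene(m, part)
  # |r| critical value at alpha = 0.05, n = 24
  r_crit <- sqrt(qt(0.975, 22)^2 / (qt(0.975, 22)^2 + 22))
  hits <- sapply(1:200, function(s) {
    set.seed(1000 + s)
    traits <- data.frame(sample_id = paste0("s", 1:24), x = rnorm(24))
    mt <- module_trait_correlation(eigs, traits)
    abs(mt$r[1]) < r_crit
  })
  expect_gte(mean(hits), 0.90)
})

test_that("GS and MM match a per-pair correlation oracle", {
  set.seed(7)
  m <- matrix(rlnorm(5 * 15), 5, 15,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:15)))
  part <- manual_partition(paste0("t", 1:5))
  eigs <- module_eigengene(m, part)
  traits <- data.frame(sample_id = paste0("s", 1:15), CMR = rnorm(15))
  sc <- gene_scores(m, part, eigs, traits)
  for (i in 1:5) {
    ct_gs <- cor.test(m[i, ], traits$CMR)
    expect_equal(sc$GS[i], unname(ct_gs$estimate), tolerance = 1e-12)
    expect_equal(sc$GS_p[i], ct_gs$p.value, tolerance = 1e-10)
    ct_mm <- cor.test(m[i, ], eigs$eigengenes[, "module1"])
    expect_equal(sc$MM[i], unname(ct_mm$estimate), tolerance = 1e-12)
    expect_equal(sc$MM_p[i], ct_mm$p.value, tolerance = 1e-10)
  }
})

test_that("an OTU equal to its eigengene or trait scores r = 1", {
  set.seed(8)
  m <- matrix(rlnorm(4 * 12), 4, 12,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:12)))
  part <- manual_partition(paste0("t", 1:4))
  eigs <- module_eigengene(m, part)
  # append a taxon tracking the eigengene exactly and one tracking a trait
  e <- eigs$eigengenes[, "module1"]
  trait_vec <- rnorm(12)
  m2 <- rbind(m, mirror_e = e - min(e) + 0.1,
              mirror_t = trait_vec - min(trait_vec) + 0.1)
  part2 <- manual_partition(rownames(m2))
  eigs2 <- module_eigengene(m2, part2)
  traits <- data.frame(sample_id = paste0("s", 1:12), CMR = trait_vec)
  sc <- gene_scores(m2, part2, eigs2, traits)
  expect_equal(sc$GS[sc$node == "mirror_t"], 1, tolerance = 1e-12)
  own_e <- eigs2$eigengenes[, "module1"]
  mm_direct <- cor(m2["mirror_e", ], own_e)
  expect_equal(sc$MM[sc$node == "mirror_e"], mm_direct, tolerance = 1e-12)
})

test_that("hub-gene and keystone logic follow the two printed criteria", {
  scores <- data.frame(
    node = paste0("t", 1:6),
    module = 1L,
    GS = 0.5, MM = 0.5,
    GS_p = c(0.01, 0.001, 0.20, 0.01, 0.20, NA),
    MM_p = c(0.20, 0.001, 0.01, 0.01, 0.20, 0.01),
    stringsAsFactors = FALSE
  )
  hg <- hub_genes(scores)
  expect_equal(hg$hub_gene, c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  roles <- data.frame(
    node = paste0("t", 1:6),
    module = 1L, k_i = 3L, k_is = 2L, Zi = 0, Pi = 0,
    role = c("peripheral", "peripheral", "connector", "module hub",
             "network hub", "peripheral"),
    stringsAsFactors = FALSE
  )
  class(roles) <- c("node_roles", "data.frame")
  ann <- data.frame(node = paste0("t", 1:6),
                    function_flag = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  rep <- keystone_report(hg, roles, annotations = ann)
  rep <- rep[match(paste0("t", 1:6), rep$node), ]
  # t1: not hub, peripheral -> no; t2: hub gene + function -> yes
  # t3: connector (critical) -> yes; t4: hub+module hub but function FALSE
  # t5: network hub -> yes; t6: nothing -> no
  expect_equal(rep$keystone, c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(rep$critical_node,
               c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  # absent annotations: pass-with-warning
  expect_warning(rep2 <- keystone_report(hg, roles), "not screened")
  expect_true(all(rep2$function_flag))
  expect_equal(sum(rep2$keystone), 4)  # t2 hub, t3, t4, t5 critical
})

test_that("pearson_with_p matches cor.test across random vectors", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    ours <- pearson_with_p(x, y)
    ct <- cor.test(x, y)
    expect_equal(ours$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(ours$p, ct$p.value, tolerance = 1e-12)
  }
  expect_equal(pearson_with_p(1:10, 1:10)$r, 1)
  expect_equal(pearson_with_p(1:10, -(1:10))$r, -1)
  cst <- pearson_with_p(rep(1, 5), rnorm(5))
  expect_true(is.na(cst$r) && is.na(cst$p))
})
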