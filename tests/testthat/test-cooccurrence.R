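test_that("top-ASV selection ranks by total relative abundance deterministically", {
  m <- cbind(S1 = c(10L, 5L, 1L, 1L), S2 = c(10L, 6L, 2L, 2L))
  rownames(m) <- c("b_high", "c_mid", "a_tie", "z_tie")
  x <- makeAsv(m)
  top3 <- selectTopAsvs(x, 3L)
  expect_setequal(rownames(top3), c("b_high", "c_mid", "a_tie"))  # tie: lexicographic
  expect_warning(selectTopAsvs(x, 200L), "keeping all")
  expect_equal(nrow(suppressWarnings(selectTopAsvs(x, 200L))), 4L)
})

test_that("Spearman matrix matches rank-covariance evaluation, with ties", {
  m <- rbind(x = c(1, 2, 3, 4, 5),
             y = c(10, 20, 20, 30, 40),
             z = c(5, 4, 3, 2, 1))
  sp <- spearmanMatrix(m)
  expect_equal(sp$rho["x", "z"], -1)
  expect_equal(sp$rho["x", "x"], 1)
  # frozen from the rank-covariance formula with midranks:
  # rx=(1..5), ry=(1,2.5,2.5,4,5) -> rho = 9.5/sqrt(10*9.5)
  expect_equal(sp$rho["x", "y"], 0.9746794345, tolerance = 1e-9)
  # two-sided t-approximation p with n-2 = 3 df, frozen
  expect_equal(sp$p["x", "y"], 0.004818230468, tolerance = 1e-9)
  expect_equal(sp$p["x", "z"], 0)   # perfect anti-correlation
  expect_equal(diag(sp$p), c(x = 0, y = 0, z = 0))

  # constant rows are excluded and reported
  m2 <- rbind(m, w = c(2, 2, 2, 2, 2))
  sp2 <- spearmanMatrix(m2)
  expect_equal(sp2$excluded, "w")
  expect_false("w" %in% rownames(sp2$rho))

  expect_error(spearmanMatrix(m[, 1:3]), "at least 4 samples")
})

test_that("exact permutation p agrees with the t approximation in direction", {
  m <- rbind(a = c(1, 3, 2, 5, 4, 6),
             b = c(2, 1, 4, 3, 6, 5),
             c = c(6, 5, 4, 3, 2, 1))
  spt <- spearmanMatrix(m)
  spe <- spearmanMatrix(m, pMethod = "exact")
  expect_equal(spt$rho, spe$rho)
  # strong |rho| pairs get smaller p than weak pairs under both methods
  expect_lt(spe$p["a", "c"], spe$p["a", "b"])
  expect_true(all(spe$p >= 0 & spe$p <= 1))
})

test_that("BH-FDR adjustment reproduces the step-up arithmetic", {
  expect_equal(adjustFdr(0.03), 0.03)
  expect_equal(adjustFdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjustFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # matrix form adjusts the strict upper triangle and mirrors
  p <- matrix(0, 3, 3)
  p[upper.tri(p)] <- c(0.01, 0.02, 0.03)
  p <- p + t(p)
  adj <- adjustFdr(p)
  expect_equal(adj[upper.tri(adj)], c(0.03, 0.03, 0.03))
  expect_equal(adj, t(adj))
  expect_error(adjustFdr(c(0.5, 1.2)), "0, 1")
})

test_that("network edges require both the rho gate and the FDR gate", {
  ids <- c("n1", "n2", "n3", "n4")
  tax <- data.frame(asv = ids, domain = "Bacteria", phylum = "Proteobacteria",
                    class = "Alphaproteobacteria")
  rho <- diag(4); dimnames(rho) <- list(ids, ids)
  pAdj <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(pAdj) <- 0

  # all |rho| <= 0.6: zero edges
  rho[1, 2] <- rho[2, 1] <- 0.6
  net <- buildNetwork(rho, pAdj, tax)
  expect_equal(nrow(networkEdges(net)), 0L)

  # strong but not significant: still no edge (AND semantics)
  rho[1, 2] <- rho[2, 1] <- 0.9
  pAdj[1, 2] <- pAdj[2, 1] <- 0.2
  expect_equal(nrow(networkEdges(buildNetwork(rho, pAdj, tax))), 0L)

  # exactly the two qualifying pairs become edges
  pAdj[1, 2] <- pAdj[2, 1] <- 0.01
  rho[3, 4] <- rho[4, 3] <- -0.8
  pAdj[3, 4] <- pAdj[4, 3] <- 0.001
  net <- buildNetwork(rho, pAdj, tax)
  e <- networkEdges(net)
  expect_equal(nrow(e), 2L)
  expect_setequal(paste(e$source, e$target), c("n1 n2", "n3 n4"))
  expect_equal(sort(e$sign), c(-1, 1))
  expect_error(buildNetwork(rho, pAdj, tax[-1, ]), "taxonomy lacks")
})

test_that("raising the rho threshold never adds edges", {
  asv <- simulateAsvTable(communitySimConfig(nSamples = 12, nAsvs = 30,
                                             withinGuildRho = 0.7, seed = 3))
  sp <- spearmanMatrix(asv)
  pAdj <- adjustFdr(sp$p)
  tax <- data.frame(asv = rownames(asv),
                    domain = rowData(asv)$domain,
                    phylum = rowData(asv)$phylum,
                    class = rowData(asv)$class)
  prev <- Inf
  for (thr in c(0.5, 0.6, 0.7, 0.8, 0.9)) {
    n_e <- nrow(networkEdges(buildNetwork(sp$rho, pAdj, tax,
                                          rThreshold = thr)))
    expect_lte(n_e, prev)
    prev <- n_e
  }
})

test_that("modularity of two disconnected triangles is 0.5", {
  ids <- paste0("n", 1:6)
  tax <- data.frame(asv = ids, domain = "Bacteria", phylum = "Proteobacteria",
                    class = "c")
  rho <- diag(6); dimnames(rho) <- list(ids, ids)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    rho[p[1], p[2]] <- rho[p[2], p[1]] <- 0.9
  pAdj <- matrix(0, 6, 6, dimnames = list(ids, ids))
  net <- networkModularity(buildNetwork(rho, pAdj, tax), seed = 1)
  expect_equal(modularityQ(net), 0.5, tolerance = 1e-9)
  expect_equal(length(unique(modulePartition(net))), 2L)

  # a single clique: one module, Q = 0
  rho6 <- matrix(0.9, 6, 6, dimnames = list(ids, ids)); diag(rho6) <- 1
  net1 <- networkModularity(buildNetwork(rho6, pAdj, tax), seed = 1)
  expect_equal(modularityQ(net1), 0, tolerance = 1e-9)
})

test_that("Louvain Q never exceeds the exhaustive-partition maximum", {
  set.seed(17)
  for (rep in 1:5) {
    g <- igraph::sample_gnp(8, 0.4)
    if (igraph::ecount(g) == 0) next
    best <- maxModularityOracle(g)
    set.seed(rep)
    cl <- igraph::cluster_louvain(g)
    q <- igraph::modularity(g, igraph::membership(cl))
    expect_lte(q, best + 1e-9)
  }
})

test_that("edgeless networks get an undefined modularity marker", {
  ids <- c("a", "b", "c", "d")
  tax <- data.frame(asv = ids, domain = "Bacteria", phylum = "P", class = "c")
  rho <- diag(4); dimnames(rho) <- list(ids, ids)
  pAdj <- matrix(1, 4, 4, dimnames = list(ids, ids))
  net <- buildNetwork(rho, pAdj, tax)
  expect_message(net <- networkModularity(net), "undefined")
  expect_true(is.na(modularityQ(net)))
  expect_length(modulePartition(net), 4L)
})

test_that("edge sign summaries count positives per taxonomy stratum", {
  ids <- c("a1", "a2", "b1", "b2")
  tax <- data.frame(asv = ids,
                    domain = c("Archaea", "Archaea", "Bacteria", "Bacteria"),
                    phylum = c("Crenarchaeota", "Crenarchaeota",
                               "Proteobacteria", "Cyanobacteria"),
                    class = "c")
  rho <- diag(4); dimnames(rho) <- list(ids, ids)
  link <- function(i, j, v) rho[i, j] <<- rho[j, i] <<- v
  link(1, 2, 0.9); link(3, 4, 0.8); link(1, 3, 0.7); link(2, 4, -0.7)
  pAdj <- matrix(0, 4, 4, dimnames = list(ids, ids))
  net <- buildNetwork(rho, pAdj, tax)
  ss <- edgeSignSummary(net)
  expect_equal(ss$prop_positive[ss$stratum == "overall"], 0.75)  # 3 of 4
  expect_equal(ss$prop_positive[ss$stratum == "archaea-archaea"], 1)
  expect_equal(ss$prop_positive[ss$stratum == "bacteria-bacteria"], 1)
  expect_equal(ss$prop_positive[ss$stratum == "archaea-bacteria"], 0.5)
  expect_equal(ss$n_edges[ss$stratum == "overall"], 4L)

  # all-bacterial network omits archaeal strata
  tax$domain <- "Bacteria"
  ss2 <- edgeSignSummary(buildNetwork(rho, pAdj, tax))
  expect_false(any(grepl("archaea", ss2$stratum)))
})

test_that("network construction is invariant to sample order", {
  asv <- simulateAsvTable(communitySimConfig(nSamples = 12, nAsvs = 24,
                                             seed = 6))
  set.seed(1)
  perm <- sample(ncol(asv))
  n1 <- cooccurrenceNetwork(asv, top = 24, seed = 5)
  n2 <- cooccurrenceNetwork(asv[, perm], top = 24, seed = 5)
  e1 <- networkEdges(n1); e2 <- networkEdges(n2)
  o1 <- order(e1$source, e1$target); o2 <- order(e2$source, e2$target)
  expect_equal(e1[o1, ], e2[o2, ], ignore_attr = TRUE)
  expect_equal(modularityQ(n1), modularityQ(n2))
})

test_that("Louvain is reproducible and stable on the planted-guild network", {
  asv <- simulateAsvTable(communitySimConfig(seed = 11))
  base <- cooccurrenceNetwork(asv, seed = 42)
  again <- cooccurrenceNetwork(asv, seed = 42)
  expect_identical(modulePartition(base), modulePartition(again))
  qs <- vapply(1:20, function(s)
    modularityQ(networkModularity(base, seed = s)), 0)
  expect_lt(max(qs) - min(qs), 0.05)
  expect_true(all(qs > 0.4))
})
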