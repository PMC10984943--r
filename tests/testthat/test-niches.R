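test_that("ILR basis is orthonormal and orthogonal to the all-ones vector", {
  for (d in c(2, 5, 37)) {
    B <- ilr_basis(d)
    expect_equal(B %*% t(B), diag(d - 1), tolerance = 1e-10)
    expect_equal(rowSums(B), rep(0, d - 1), tolerance = 1e-10)
  }
  expect_error(ilr_basis(1), "at least 2")
})

test_that("two-part ILR matches its closed form", {
  expect_equal(as.vector(ilr_transform(c(0.5, 0.5))), 0, tolerance = 1e-6)
  p <- exp(1) / (1 + exp(1))
  got <- as.vector(ilr_transform(matrix(c(p, 1 - p), 1), 1e-12))
  expect_equal(got, 1 / sqrt(2), tolerance = 1e-8)
  for (pp in c(0.1, 0.35, 0.9)) {
    got <- as.vector(ilr_transform(matrix(c(pp, 1 - pp), 1), 1e-12))
    expect_equal(got, (1 / sqrt(2)) * log(pp / (1 - pp)), tolerance = 1e-7)
  }
})

test_that("ILR is an isometry for the Aitchison geometry", {
  set.seed(5)
  for (i in 1:20) {
    d <- sample(3:12, 1)
    x <- rdirichlet(1, runif(d, 0.5, 3))[1, ]
    y <- rdirichlet(1, runif(d, 0.5, 3))[1, ]
    # oracle on the same pseudocounted composition the transform sees
    adj <- function(v) { v <- v + mean(v) * 1e-12; v / sum(v) }
    a_dist <- sqrt(sum((clr_oracle(adj(x)) - clr_oracle(adj(y)))^2))
    i_dist <- sqrt(sum((ilr_transform(x, 1e-12) - ilr_transform(y, 1e-12))^2))
    expect_equal(i_dist, a_dist, tolerance = 1e-8)
  }
})

test_that("elementwise perturbation shifts ILR coordinates by a constant", {
  set.seed(6)
  x <- rdirichlet(5, rep(2, 6))
  g <- runif(6, 0.5, 2)
  xp <- sweep(x, 2, g, `*`); xp <- xp / rowSums(xp)
  shift <- ilr_transform(xp, 1e-12) - ilr_transform(x, 1e-12)
  expect_lt(max(abs(sweep(shift, 2, shift[1, ]))), 1e-6)
})

test_that("single-batch balanced kNN equals brute-force kNN", {
  set.seed(9)
  emb <- matrix(rnorm(100 * 4), 100)
  g <- batch_balanced_knn(emb, rep("b1", 100), k = 4)
  d <- as.matrix(dist(emb)); diag(d) <- Inf
  brute <- lapply(1:100, function(i) sort(order(d[i, ])[1:4]))
  mine <- lapply(1:100, function(i)
    sort(g$edges[g$edges[, 1] == i, 2]))
  expect_identical(mine, brute)
  # symmetrized union graph contains every brute-force edge
  el <- igraph::as_edgelist(g$graph)
  keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  for (i in 1:100)
    expect_true(all(paste(pmin(i, brute[[i]]), pmax(i, brute[[i]])) %in% keys))
})

test_that("batch balance: k out-edges into every sufficiently large batch", {
  set.seed(10)
  emb <- matrix(rnorm(90 * 3), 90)
  batch <- rep(c("a", "b", "c"), each = 30)
  k <- 3
  g <- batch_balanced_knn(emb, batch, k = k)
  out_batch <- table(factor(g$edges[, 1], 1:90), batch[g$edges[, 2]])
  expect_true(all(out_batch == k))
  # duplicated batch: each node's cross-batch neighbour is its duplicate
  emb2 <- rbind(emb[1:20, ], emb[1:20, ])
  b2 <- rep(c("x", "y"), each = 20)
  g2 <- batch_balanced_knn(emb2, b2, k = 1)
  cross <- g2$edges[g2$edges[, 1] <= 20 & g2$edges[, 2] > 20, ]
  expect_equal(cross[order(cross[, 1]), 2], 21:40)
})

test_that("Leiden separates disjoint cliques and keeps one clique whole", {
  g <- igraph::make_full_graph(8) + igraph::make_full_graph(6)
  lab <- detect_niches(g, resolution = 0.6, seed = 1)
  expect_equal(max(lab), 2L)
  expect_equal(lab[1:8], rep(1L, 8))   # larger clique renumbered first
  expect_equal(length(unique(lab[9:14])), 1L)
  one <- detect_niches(igraph::make_full_graph(10), resolution = 0.6, seed = 1)
  expect_equal(max(one), 1L)
  expect_error(detect_niches(igraph::make_empty_graph(0)), "empty")
})

test_that("planted niches are recovered across batches at resolution 0.6", {
  s <- small_sim(seed = 42, n_sections = 2, spots = 250, d = 10,
                 niches = 3, conc = 300, batch_sd = 0.3)
  # denser graph than the many-batch default: with only 2 batches, k = 3
  # per batch leaves communities too sparse for stable modularity optimization
  nm <- fit_niche_model(s$sim$sections, k_within_batch = 10, seed = 2)
  truth <- truth_labels(s$sim)
  aris <- vapply(1:10, function(sd) {
    lab <- detect_niches(nm$graph, seed = sd)
    mclust::adjustedRandIndex(lab, truth)
  }, numeric(1))
  expect_gte(sum(aris >= 0.9), 9)
  expect_equal(max(nm$niche_labels), 3L)
})

test_that("niche labels are invariant to spot-order permutation", {
  s <- small_sim(seed = 43, n_sections = 2, spots = 150, d = 8, niches = 3)
  secs <- s$sim$sections
  nm1 <- fit_niche_model(secs, seed = 4)
  perm <- lapply(secs, function(sec) {
    set.seed(99)
    ix <- sample(length(sec$spot_ids))
    new_section(sec$section_id, sec$spot_ids[ix], sec$coords[ix, ],
                sec$spot_diameter, sec$abundance[ix, ])
  })
  nm2 <- fit_niche_model(perm, seed = 4)
  common <- names(nm1$niche_labels)
  expect_equal(mclust::adjustedRandIndex(nm1$niche_labels[common],
                                         nm2$niche_labels[common]), 1)
})

test_that("centroids are member means and trivial mappings return themselves", {
  s <- small_sim(seed = 47, n_sections = 2, spots = 120, d = 8, niches = 3)
  nm <- fit_niche_model(s$sim$sections, seed = 6)
  for (k in unique(nm$niche_labels)) {
    expect_equal(nm$centroids[as.character(k), ],
                 colMeans(nm$embedding[nm$niche_labels == k, , drop = FALSE]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  mapped <- map_niches(nm, s$sim$sections)
  agree <- mean(mapped$niche == nm$niche_labels[mapped$spot_id])
  expect_gte(agree, 0.95)   # training spots map back to their own niche
  bad <- s$sim$sections[[1]]
  colnames(bad$abundance)[1] <- "Mystery"
  expect_error(map_niches(nm, list(bad)), "mismatch")
})

test_that("held-out spots are assigned their planted niche by centroid mapping", {
  s <- small_sim(seed = 53, n_sections = 4, spots = 300, d = 12, niches = 4,
                 conc = 150, batch_sd = 0.3)
  secs <- s$sim$sections
  set.seed(8)
  train <- list(); test <- list()
  for (i in seq_along(secs)) {
    n <- length(secs[[i]]$spot_ids)
    ho <- sample(n, round(0.2 * n))
    sub <- function(ix) new_section(secs[[i]]$section_id,
                                    secs[[i]]$spot_ids[ix],
                                    secs[[i]]$coords[ix, ],
                                    secs[[i]]$spot_diameter,
                                    secs[[i]]$abundance[ix, ])
    train[[i]] <- sub(setdiff(seq_len(n), ho)); test[[i]] <- sub(ho)
  }
  nm <- fit_niche_model(train, k_within_batch = 5, seed = 3)
  truth <- unlist(unname(s$sim$truth$niche_labels))
  # majority map: model niche -> planted niche, from training spots
  conf <- table(nm$niche_labels, truth[names(nm$niche_labels)])
  to_planted <- colnames(conf)[max.col(conf)]
  mapped <- map_niches(nm, test)
  agree <- mean(to_planted[mapped$niche] == truth[mapped$spot_id])
  expect_gte(agree, 0.85)
})
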