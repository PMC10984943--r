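test_that("singleton pair distances are symmetric and Euclidean", {
  cm <- make_cellmap(c("A", "B"), x = c(0, 3), y = c(0, 4))
  tab <- nearest_distance_table(cm)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$nearest_distance[tab$reference_type == "A"], 5)
  expect_equal(tab$nearest_distance[tab$reference_type == "B"], 5)
})

test_that("a single cell type yields an empty table; sections are not pooled", {
  cm <- make_cellmap(rep("A", 5), x = 1:5, y = 1:5)
  expect_equal(nrow(nearest_distance_table(cm)), 0L)
  # type B present only in S02: no A->B rows for S01
  cm2 <- rbind(make_cellmap(c("A", "A"), c(0, 1), c(0, 0), "S01"),
               make_cellmap(c("A", "B"), c(100, 0), c(0, 0), "S02"))
  class(cm2) <- c("ect_cellmap", "data.frame")
  tab <- nearest_distance_table(cm2)
  expect_false(any(tab$section_id == "S01"))
  expect_equal(tab$nearest_distance[tab$section_id == "S02" &
                                    tab$reference_type == "A"], 100)
})

test_that("nearest distances equal the all-pairs brute-force oracle", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    cm <- make_cellmap(sample(LETTERS[1:4], n, replace = TRUE),
                       x = runif(n, 0, 1000), y = runif(n, 0, 1000))
    tab <- nearest_distance_table(cm)
    full <- as.matrix(dist(cbind(cm$x_um, cm$y_um)))
    for (r in sample(nrow(tab), 50)) {
      row <- tab[r, ]
      tgt <- which(cm$cell_type == row$target_type)
      expect_equal(row$nearest_distance, min(full[row$cell_index, tgt]),
                   tolerance = 1e-10)
    }
    # completeness: one row per (cell, other type present)
    expect_equal(nrow(tab), sum(vapply(seq_len(n), function(i)
      length(setdiff(unique(cm$cell_type), cm$cell_type[i])), 1L)))
  }
})

test_that("ranking by median distance reproduces planted ring order", {
  # anchor at origin; type Near on a ring at 10, Mid at 50, Far at 200
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  cm <- make_cellmap(
    c("Anchor", rep(c("Near", "Mid", "Far"), each = 12)),
    x = c(0, 10 * cos(ang), 50 * cos(ang), 200 * cos(ang)),
    y = c(0, 10 * sin(ang), 50 * sin(ang), 200 * sin(ang)))
  rk <- rank_by_median_distance(nearest_distance_table(cm), "Anchor")
  expect_equal(rk$reference_type, c("Near", "Mid", "Far"))
  expect_equal(rk$median_distance, c(10, 50, 200))
  # permuting rows leaves the ranking unchanged
  tab <- nearest_distance_table(cm)
  set.seed(2)
  rk2 <- rank_by_median_distance(tab[sample(nrow(tab)), ], "Anchor")
  expect_equal(rk2, rk)
  expect_error(rank_by_median_distance(tab, "Ghost"), "absent")
})

test_that("Shannon index matches closed forms and is maximal at uniformity", {
  expect_equal(shannon_index(c(1, 0, 0)), 0)
  expect_equal(shannon_index(rep(1, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(shannon_index(c(2, 1, 1)), shannon_index(c(0.5, 0.25, 0.25)))
  set.seed(4)
  h_max <- shannon_index(rep(1 / 6, 6))
  for (i in 1:200) expect_lte(shannon_index(rdirichlet(1, rep(1, 6))[1, ]), h_max)
  expect_error(shannon_index(c(0, 0)), "all-zero")
  expect_error(shannon_index(c(-1, 2)), "non-negative")
})

test_that("annotation transfer applies the cancer threshold before majority", {
  # spot disc of diameter 55 at origin; half-plane polygons split it exactly
  sec <- make_section(matrix(1, 1, dimnames = list(NULL, "A")),
                      coords = cbind(x = 0, y = 0))
  box <- function(x1, x2) cbind(c(x1, x2, x2, x1, x1), c(-60, -60, 60, 60, -60))
  # cancer covers x > 5.55 (about 40% of the disc), stroma the rest
  q40 <- qbeta(0.6, 1.5, 1.5) * 55 - 27.5   # x-cut giving ~40% disc area
  ann <- new_annotations(list(
    list(label = "Cancer cells", rings = list(box(q40, 60))),
    list(label = "Intratumor stroma", rings = list(box(-60, q40)))))
  expect_equal(unname(transfer_annotations(ann, sec)), "Cancer cells")

  # cancer 20%, stroma 60%, 20% uncovered -> majority label wins
  q20 <- qbeta(0.8, 1.5, 1.5) * 55 - 27.5
  q80 <- qbeta(0.2, 1.5, 1.5) * 55 - 27.5
  ann2 <- new_annotations(list(
    list(label = "Cancer cells", rings = list(box(q20, 60))),
    list(label = "Intratumor stroma", rings = list(box(q80, q20)))))
  expect_equal(unname(transfer_annotations(ann2, sec)), "Intratumor stroma")

  # fully outside every polygon
  far <- new_annotations(list(
    list(label = "Cancer cells", rings = list(box(1000, 1100)))))
  expect_equal(unname(transfer_annotations(far, sec)), "unassigned")
  expect_error(transfer_annotations(ann, sec, cancer_threshold = 1.2),
               "cancer_threshold")
})

test_that("annotation transfer is invariant to polygon vertex rotation", {
  sec <- make_section(matrix(1, 3, dimnames = list(NULL, "A")),
                      coords = cbind(x = c(0, 120, 240), y = 0))
  ring <- cbind(c(-50, 170, 170, -50, -50), c(-50, -50, 50, 50, -50))
  rot <- rbind(ring[3:4, ], ring[1:2, ], ring[3, ])
  a1 <- new_annotations(list(list(label = "Cancer cells", rings = list(ring))))
  a2 <- new_annotations(list(list(label = "Cancer cells", rings = list(rot))))
  expect_identical(transfer_annotations(a1, sec), transfer_annotations(a2, sec))
})

test_that("planted 3-niche annotations round-trip through spot transfer", {
  s <- small_sim(seed = 37, n_sections = 1, spots = 300, niches = 3)
  sec <- s$sim$sections[[1]]
  lab <- s$sim$truth$niche_labels[[1]]
  mapping <- setNames(ect_compartments()[c(3, 1, 2)], as.character(1:3))
  ann <- generate_annotations(sec, lab, mapping)
  got <- transfer_annotations(ann, sec)
  expect_gte(mean(got == mapping[as.character(lab)]), 0.95)
})

test_that("rank-sum p values match exhaustive enumeration and wilcox.test", {
  # independent enumeration oracle over all group assignments
  enum_p <- function(x, y) {
    n <- length(x) + length(y)
    rk <- rank(c(x, y))
    w <- sum(rk[seq_along(x)])
    ws <- apply(utils::combn(n, length(x)), 2, function(ix) sum(rk[ix]))
    min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
  }
  set.seed(11)
  for (i in 1:8) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- round(runif(nx), if (i %% 2) 1 else 3)   # odd i: heavy ties
    y <- round(runif(ny), if (i %% 2) 1 else 3)
    expect_equal(rank_sum_test(x, y)$p_value, enum_p(x, y), tolerance = 1e-12)
  }
  # tie-free case agrees with the standard exact implementation
  x <- c(1.1, 2.3, 5.2, 7.9); y <- c(0.4, 3.3, 4.1, 6.6, 8.8)
  expect_equal(rank_sum_test(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  # large samples: normal approximation close to the standard one
  set.seed(3)
  x <- rnorm(30); y <- rnorm(35, 0.5)
  expect_equal(rank_sum_test(x, y)$p_value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-6)
  # identical samples are not distinguishable
  expect_equal(rank_sum_test(rep(0.3, 4), rep(0.3, 6))$p_value, 1)
})

test_that("compartment enrichment flags an always-dominant state", {
  # 4 sections, state S1 always 100% of parent cells in "Cancer cells" spots
  cells <- do.call(rbind, lapply(1:4, function(s) {
    data.frame(cell_type = c(rep("S1", 10), rep("S2", 5), rep("S3", 5)),
               x_um = 0, y_um = 0,
               spot_id = c(rep(paste0("c", s), 10), rep(paste0("o", s), 10)),
               section_id = paste0("S", s))
  }))
  class(cells) <- c("ect_cellmap", "data.frame")
  ann <- setNames(rep(c("Cancer cells", "Peritumor stroma"), each = 4),
                  c(paste0("c", 1:4), paste0("o", 1:4)))
  res <- compartment_enrichment(cells, ann, c("S1", "S2", "S3"))
  r <- res$enrichment
  s1 <- r[r$state == "S1" & r$compartment == "Cancer cells", ]
  expect_equal(s1$direction, "enriched")
  # smallest attainable two-sided enumeration p for 4 vs 8 all-distinct ranks
  expect_equal(s1$p_value, 2 / choose(12, 4), tolerance = 1e-9)
  s1p <- r[r$state == "S1" & r$compartment == "Peritumor stroma", ]
  expect_equal(s1p$direction, "depleted")
  expect_true(res$pooled_fisher_p >= 0 && res$pooled_fisher_p <= 1)
})

test_that("identical state proportions give p = 1", {
  cells <- do.call(rbind, lapply(1:3, function(s)
    data.frame(cell_type = rep(c("S1", "S2"), each = 5), x_um = 0, y_um = 0,
               spot_id = paste0("c", s), section_id = paste0("S", s))))
  class(cells) <- c("ect_cellmap", "data.frame")
  ann <- setNames(rep("Cancer cells", 3), paste0("c", 1:3))
  res <- compartment_enrichment(cells, ann, c("S1", "S2"))
  expect_true(all(res$enrichment$p_value == 1))
  expect_true(all(res$enrichment$direction == "none"))
  expect_true(is.na(res$pooled_fisher_p))   # one compartment: no pooled table
})
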