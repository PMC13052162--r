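test_that("Jaccard dissimilarity matches hand enumeration and vegdist", {
  pres <- rbind(B1 = c(a = TRUE, b = TRUE, c = TRUE, d = FALSE),
                B2 = c(a = FALSE, b = TRUE, c = TRUE, d = TRUE),
                B3 = c(a = TRUE, b = TRUE, c = TRUE, d = FALSE),
                B4 = c(a = FALSE, b = FALSE, c = FALSE, d = TRUE))
  D <- jaccard_dissimilarity(make_community(pres))
  expect_equal(D["B1", "B2"], 0.5)     # shared 2 of 4
  expect_equal(D["B1", "B3"], 0)       # identical sets
  expect_equal(D["B1", "B4"], 1)       # disjoint sets
  skip_if_not_installed("vegan")
  vd <- as.matrix(vegan::vegdist(pres * 1, "jaccard", binary = TRUE))
  expect_equal(unclass(D)[, ], vd[, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Jaccard satisfies the triangle inequality on random triples", {
  set.seed(6)
  for (rep in 1:50) {
    pres <- matrix(runif(3 * 12) < 0.5, 3, 12,
                   dimnames = list(c("x", "y", "z"), sprintf("a%d", 1:12)))
    D <- suppressWarnings(jaccard_dissimilarity(make_community(pres)))
    expect_lte(D["x", "z"], D["x", "y"] + D["y", "z"] + 1e-12)
  }
})

test_that("PCoA reconstructs Euclidean configurations", {
  # 3-4-5 right triangle: recovered inter-point distances equal the input
  D <- matrix(c(0, 3, 5, 3, 0, 4, 5, 4, 0), 3,
              dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  ord <- pcoa(D)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(rec[, ], D[, ], tolerance = 1e-8, ignore_attr = TRUE)
  # duplicated label rows land on coincident coordinates
  D2 <- rbind(cbind(D, p2 = D[, "p"]), p2 = c(D["p", ], 0))
  ord2 <- pcoa(D2)
  expect_equal(ord2$coordinates["p", ], ord2$coordinates["p2", ],
               tolerance = 1e-8)
  # axis sign convention: largest-magnitude loading positive
  for (ax in seq_len(ncol(ord$coordinates))) {
    v <- ord$coordinates[, ax]
    expect_gte(v[which.max(abs(v))], 0)
  }
  expect_equal(ncol(pcoa(D * 0)$coordinates), 0)
})

test_that("random Euclidean inputs produce no negative-eigenvalue axes", {
  set.seed(8)
  for (rep in 1:10) {
    D <- random_dist_matrix(7)
    ord <- pcoa(D)
    expect_true(all(ord$eigenvalues > 0))
    rec <- as.matrix(dist(ord$coordinates))
    expect_equal(rec[, ], D[, ], tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("ANOSIM matches a brute-force computation and vegan", {
  set.seed(17)
  D <- random_dist_matrix(6)
  g <- c("A", "A", "A", "B", "B", "B")
  res <- anosim_test(D, g, n_permutations = 499, seed = 3)
  # brute force from the definition
  pairs <- t(combn(6, 2))
  d <- D[pairs]
  rk <- rank(d)
  within <- g[pairs[, 1]] == g[pairs[, 2]]
  R <- (mean(rk[!within]) - mean(rk[within])) / (length(d) / 2)
  expect_equal(res$statistic, R, tolerance = 1e-12)
  skip_if_not_installed("vegan")
  va <- vegan::anosim(stats::as.dist(D), g, permutations = 99)
  expect_equal(res$statistic, unname(va$statistic), tolerance = 1e-12)
})

test_that("perfect group separation gives ANOSIM R = 1", {
  pts <- rbind(matrix(rnorm(8, 0, 0.01), 4), matrix(rnorm(8, 50, 0.01), 4))
  D <- as.matrix(dist(pts)); dimnames(D) <- list(letters[1:8], letters[1:8])
  res <- anosim_test(D, rep(c("A", "B"), each = 4), seed = 2)
  expect_equal(res$statistic, 1)
  expect_lte(res$p_value, 0.05)
  expect_error(anosim_test(D, c("A", rep("B", 7))), "2 groups")
})

test_that("Mantel r equals 1 for identical and affine-related matrices", {
  D <- random_dist_matrix(7)
  expect_equal(mantel_test(D, D, seed = 1)$statistic, 1)
  expect_equal(mantel_test(D, 3 * D + 2, seed = 1)$statistic, 1)
  skip_if_not_installed("vegan")
  D2 <- random_dist_matrix(7)
  r_mine <- mantel_test(D, D2, seed = 1)$statistic
  r_vegan <- unname(vegan::mantel(stats::as.dist(D), stats::as.dist(D2),
                                  permutations = 99)$statistic)
  expect_equal(r_mine, r_vegan, tolerance = 1e-12)
})

test_that("permutation p-values obey the (1+k)/(1+N) convention", {
  set.seed(20)
  D <- random_dist_matrix(6)
  res <- mantel_test(D, D, n_permutations = 199, seed = 4)
  expect_gte(res$p_value, 1 / 200)
  expect_lte(res$p_value, 1)
  res2 <- anosim_test(D, rep(c("A", "B"), 3), n_permutations = 199, seed = 4)
  expect_true(res2$p_value %in% ((seq(0, 199) + 1) / 200))
})

test_that("richness summaries and the rank-sum comparison are correct", {
  pres <- rbind(L1 = c(rep(TRUE, 1), rep(FALSE, 11)),
                L2 = c(rep(TRUE, 2), rep(FALSE, 10)),
                L3 = c(rep(TRUE, 3), rep(FALSE, 9)),
                A1 = c(rep(FALSE, 2), rep(TRUE, 10)),
                A2 = c(rep(FALSE, 1), rep(TRUE, 11)),
                A3 = rep(TRUE, 12))
  colnames(pres) <- sprintf("a%02d", 1:12)
  side <- setNames(rep(c("ligurian", "adriatic"), each = 3), rownames(pres))
  rs <- richness_by_side(make_community(pres, side))
  expect_equal(rs$per_basin$richness[rs$per_basin$basin_id == "A3"], 12)
  # richness vectors (1,2,3) vs (10,11,12): exact two-sided p = 0.1
  expect_equal(rs$wilcoxon$p.value, 0.1)
  adr <- rs$per_side[rs$per_side$side == "adriatic", ]
  expect_equal(adr$mean, mean(c(10, 11, 12)))
  expect_equal(adr$side_total, 12)
})

test_that("the reported W statistic equals a brute-force rank computation", {
  set.seed(30)
  pres <- matrix(runif(10 * 40) < 0.4, 10, 40,
                 dimnames = list(sprintf("B%02d", 1:10), sprintf("a%02d", 1:40)))
  side <- setNames(rep(c("adriatic", "ligurian"), each = 5), rownames(pres))
  rs <- richness_by_side(make_community(pres, side))
  rich <- rowSums(pres)
  grp1 <- names(side)[side == "adriatic"]   # first alphabetically
  rk <- rank(rich[c(grp1, setdiff(names(side), grp1))])
  w_oracle <- sum(rk[seq_along(grp1)]) - length(grp1) * (length(grp1) + 1) / 2
  expect_equal(unname(rs$wilcoxon$statistic), w_oracle)
})
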