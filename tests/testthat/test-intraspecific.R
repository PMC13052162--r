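test_that("species selection requires occurrences in at least two basins", {
  pres <- rbind(B1 = c(a1 = TRUE, a2 = FALSE, a3 = TRUE),
                B2 = c(a1 = FALSE, a2 = TRUE, a3 = FALSE),
                B3 = c(a1 = FALSE, a2 = FALSE, a3 = FALSE))
  tax <- data.frame(
    asv_id = c("a1", "a2", "a3"),
    taxon_path = c("Actinopterygii;O;F;G;Sp one",
                   "Actinopterygii;O;F;G;Sp one",
                   "Actinopterygii;O;F;G;Sp two"),
    confidence = 90)
  comm <- make_community(pres)
  expect_equal(select_species(comm, tax), "Sp one")  # Sp two: one basin only
})

test_that("betaMPD reproduces the worked cross-pair example", {
  # b1 = {h1, h2}, b2 = {h2, h3}: cross pairs (h1,h2)=2, (h1,h3)=4,
  # (h2,h2)=0, (h2,h3)=1 -> mean 1.75
  D <- matrix(0, 3, 3, dimnames = list(c("h1", "h2", "h3"),
                                       c("h1", "h2", "h3")))
  D["h1", "h2"] <- D["h2", "h1"] <- 2
  D["h1", "h3"] <- D["h3", "h1"] <- 4
  D["h2", "h3"] <- D["h3", "h2"] <- 1
  pres <- rbind(b1 = c(h1 = TRUE, h2 = TRUE, h3 = FALSE),
                b2 = c(h1 = FALSE, h2 = TRUE, h3 = TRUE))
  bm <- beta_mpd(make_community(pres), c("h1", "h2", "h3"), D)
  expect_equal(bm["b1", "b2"], 1.75)
  # two basins sharing one identical haplotype score zero
  pres0 <- rbind(b1 = c(h1 = TRUE, h2 = FALSE, h3 = FALSE),
                 b2 = c(h1 = TRUE, h2 = FALSE, h3 = FALSE))
  expect_equal(beta_mpd(make_community(pres0), "h1", D)["b1", "b2"], 0)
})

test_that("betaMPD equals the double-loop oracle on random instances", {
  set.seed(41)
  for (rep in 1:10) {
    nb <- sample(3:8, 1); na <- sample(4:20, 1)
    ids <- sprintf("h%02d", 1:na)
    D <- as.matrix(dist(matrix(runif(na * 2) * 10, na)))
    dimnames(D) <- list(ids, ids)
    pres <- matrix(runif(nb * na) < 0.5, nb, na,
                   dimnames = list(sprintf("B%02d", 1:nb), ids))
    comm <- make_community(pres)
    expect_equal(beta_mpd(comm, ids, D), oracle_betampd(pres, D),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("betaMPD agrees with picante::comdist on occupied communities", {
  skip_if_not_installed("picante")
  set.seed(99)
  na <- 12; nb <- 5
  ids <- sprintf("h%02d", 1:na)
  D <- as.matrix(dist(matrix(runif(na * 2) * 8, na)))
  dimnames(D) <- list(ids, ids)
  pres <- matrix(FALSE, nb, na, dimnames = list(sprintf("B%d", 1:nb), ids))
  while (any(rowSums(pres) == 0)) {
    pres <- matrix(runif(nb * na) < 0.4, nb, na,
                   dimnames = list(sprintf("B%d", 1:nb), ids))
  }
  bm <- beta_mpd(make_community(pres), ids, D)
  cd <- as.matrix(picante::comdist(pres * 1, D, abundance.weighted = FALSE))
  expect_equal(bm[rownames(cd), colnames(cd)], cd, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("betaMPD is symmetric, zero-diagonal and relabel-invariant", {
  set.seed(13)
  ids <- sprintf("h%d", 1:8)
  D <- as.matrix(dist(matrix(runif(16), 8))); dimnames(D) <- list(ids, ids)
  pres <- matrix(runif(32) < 0.6, 4, 8,
                 dimnames = list(paste0("B", 1:4), ids))
  bm <- beta_mpd(make_community(pres), ids, D)
  expect_equal(bm, t(bm))
  expect_equal(unname(diag(bm)), rep(0, 4))
  # relabelling ASVs leaves values unchanged
  perm <- sample(8)
  ids2 <- sprintf("z%d", 1:8)
  D2 <- D[perm, perm]; dimnames(D2) <- list(ids2, ids2)
  pres2 <- pres[, perm]; colnames(pres2) <- ids2
  expect_equal(beta_mpd(make_community(pres2), ids2, D2), bm,
               ignore_attr = TRUE)
  # all-zero distances give an all-zero matrix
  expect_true(all(beta_mpd(make_community(pres), ids, D * 0) == 0))
})

test_that("whole-community betaMPD caps cross-species pairs", {
  # species 1: {h1, h2} with D = 3; species 2: {g1} — cap = 3
  pres <- rbind(B1 = c(h1 = TRUE, h2 = FALSE, g1 = TRUE),
                B2 = c(h1 = FALSE, h2 = TRUE, g1 = FALSE))
  D1 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("h1", "h2"),
                                                 c("h1", "h2")))
  D2 <- matrix(0, 1, 1, dimnames = list("g1", "g1"))
  comm <- make_community(pres)
  bm <- community_beta_mpd(comm, list(s1 = c("h1", "h2"), s2 = "g1"),
                           list(s1 = D1, s2 = D2))
  # cross pairs: (h1,h2)=3, (g1,h2)=cap=3 -> mean 3
  expect_equal(bm["B1", "B2"], 3)
  # excluding cross-species pairs leaves only the intraspecific pair
  bm_ex <- community_beta_mpd(comm, list(s1 = c("h1", "h2"), s2 = "g1"),
                              list(s1 = D1, s2 = D2),
                              cross_species = "exclude")
  expect_equal(bm_ex["B1", "B2"], 3)
  # one-species community equals plain betaMPD
  bm1 <- community_beta_mpd(comm, list(s1 = c("h1", "h2")), list(s1 = D1))
  expect_equal(bm1, beta_mpd(comm, c("h1", "h2"), D1), ignore_attr = TRUE)
})
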