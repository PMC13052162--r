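flat_raster <- function(nr, nc, value = 1, cell_km = 1) {
  m <- matrix(value, nr, nc)
  attr(m, "cellsize_km") <- cell_km
  m
}

test_that("conductance rasters assign exactly the scheme's values", {
  rs <- generate_riverscape(riverscape_scenario(n_basins_per_side = 2, seed = 1))
  riv <- build_conductance_raster(rs$dem, rs$rivers, rs$sea, "river_following")
  expect_equal(riv[rs$rivers == 1][1], 50000)
  expect_equal(riv[rs$sea == 1][1], 150)
  expect_setequal(unique(as.vector(riv)), c(50000, 150, 1e-4))
  elev <- build_conductance_raster(rs$dem, scheme = "elevation_weighted")
  expect_true(all(unique(as.vector(elev)) %in% c(1e6, 1e5, 1000, 100, 0.001)))
  # band edges: 1700 m -> 100; 99.9 -> 1e6; 500 -> 1000; 2000 -> 0.001
  dem <- matrix(c(1700, 99.9, 500, 2000), 2)
  attr(dem, "cellsize_km") <- 1
  expect_equal(as.vector(build_conductance_raster(dem,
                                                  scheme = "elevation_weighted")),
               c(100, 1e6, 1000, 0.001))
  dem[1, 1] <- NA
  expect_error(build_conductance_raster(dem, scheme = "elevation_weighted"),
               "undefined elevation")
})

test_that("uniform rasters give cost = distance / conductance", {
  cond <- flat_raster(10, 10, value = 20, cell_km = 1)
  attr(cond, "scheme") <- "uniform"
  pts <- data.frame(basin_id = c("p", "q"), row = c(5, 5), col = c(2, 5))
  cd <- cost_distance(cond, pts)
  expect_equal(cd$cost["p", "q"], 3 / 20, tolerance = 1e-12)
  expect_equal(cd$cost["p", "p"], 0)
  # diagonal pair: sqrt(2)-scaled steps
  pts2 <- data.frame(basin_id = c("p", "q"), row = c(2, 6), col = c(2, 6))
  cd2 <- cost_distance(cond, pts2)
  expect_equal(cd2$cost["p", "q"], 4 * sqrt(2) / 20, tolerance = 1e-12)
})

test_that("cost distances equal the textbook Dijkstra oracle", {
  set.seed(23)
  for (rep in 1:5) {
    nr <- sample(15:25, 1); nc <- sample(15:25, 1)
    cond <- matrix(exp(rnorm(nr * nc, 0, 1.5)), nr, nc)
    attr(cond, "cellsize_km") <- 0.5
    pts <- data.frame(basin_id = paste0("p", 1:3),
                      row = sample(nr, 3), col = sample(nc, 3))
    cd <- cost_distance(cond, pts)
    src <- (pts$col - 1) * nr + pts$row
    oracle <- oracle_cost_matrix(cond, 0.5, src)
    expect_equal(unclass(cd$cost)[, ], oracle, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("LCP matrices satisfy metric properties and cost monotonicity", {
  set.seed(3)
  cond <- matrix(exp(rnorm(400, 0, 1)), 20, 20)
  attr(cond, "cellsize_km") <- 1
  pts <- data.frame(basin_id = paste0("p", 1:4),
                    row = c(2, 18, 9, 14), col = c(2, 18, 15, 4))
  cd <- cost_distance(cond, pts)$cost
  expect_equal(cd, t(cd))
  expect_true(all(diag(cd) == 0))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    expect_lte(cd[i, j], cd[i, k] + cd[k, j] + 1e-12)
  }
  # lowering any conductance never decreases any pairwise cost
  cond2 <- cond
  cells <- sample(400, 20)
  cond2[cells] <- cond2[cells] / 10
  cd2 <- cost_distance(cond2, pts)$cost
  expect_true(all(cd2 >= cd - 1e-12))
})

test_that("km transformation is anchored, homogeneous and order-preserving", {
  cond <- flat_raster(8, 12, value = 50000)
  attr(cond, "scheme") <- "river_following"
  pts <- data.frame(basin_id = c("p", "q"), row = c(4, 4), col = c(1, 11))
  km <- cost_to_km(cost_distance(cond, pts))$km
  expect_equal(km["p", "q"], 10)   # all-water straight path of 10 km
  # scaling all conductances by k scales km by 1/k
  cond5 <- cond * 5
  km5 <- cost_to_km(cost_distance(cond5, pts))$km
  expect_equal(km5["p", "q"], 10 / 5)
  # ordering by cost equals ordering by km
  set.seed(40)
  condr <- matrix(exp(rnorm(96)), 8, 12)
  attr(condr, "cellsize_km") <- 1
  pts4 <- data.frame(basin_id = paste0("p", 1:4),
                     row = c(1, 8, 3, 6), col = c(1, 12, 9, 4))
  res <- cost_to_km(cost_distance(condr, pts4))
  lt <- lower.tri(res$cost)
  expect_equal(order(res$cost[lt]), order(res$km[lt]))
})

test_that("haversine distances match the closed form and are metric", {
  pts <- data.frame(basin_id = c("o", "n"), lon = c(0, 0), lat = c(0, 1))
  km <- euclidean_km(pts)
  expect_equal(km["o", "n"], 6371.0088 * pi / 180, tolerance = 1e-4)
  expect_equal(km["o", "o"], 0)
  set.seed(9)
  tri <- data.frame(basin_id = c("a", "b", "c"),
                    lon = runif(3, 7, 10), lat = runif(3, 43, 45))
  m <- euclidean_km(tri)
  expect_lte(m["a", "c"], m["a", "b"] + m["b", "c"] + 1e-9)
  expect_error(euclidean_km(data.frame(basin_id = "x", lon = 500, lat = 0)))
})
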