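#' Build a conductance raster
#'
#' Two schemes. `"river_following"` codes ease of movement along the river
#' network: water 50000, land 0.0001 (a near-impenetrable barrier), marine
#' waters 150. `"elevation_weighted"` codes five elevation bands (metres):
#' below 100 -> 1e6; 100–500 -> 1e5; 500–1500 -> 1000; 1500–2000 -> 100; at
#' or above 2000 -> 0.001. All values are configurable but default to the
#' scheme's standard figures.
#'
#' @param dem elevation raster (matrix, metres).
#' @param rivers 0/1 river raster co-registered with `dem`.
#' @param sea 0/1 marine mask co-registered with `dem`.
#' @param scheme `"river_following"` or `"elevation_weighted"`.
#' @param values named numeric overrides: for river_following
#'   `c(water=, land=, sea=)`; for elevation_weighted a vector of five band
#'   conductances.
#' @return conductance matrix (all cells > 0) with attributes
#'   `cellsize_km` (inherited from `dem`) and `scheme`.
#' @export
build_conductance_raster <- function(dem, rivers = NULL, sea = NULL,
                                     scheme = c("river_following",
                                                "elevation_weighted"),
                                     values = NULL) {
  scheme <- match.arg(scheme)
  if (anyNA(dem)) {
    bad <- which(is.na(dem), arr.ind = TRUE)[1, ]
    stop("undefined elevation at cell (", bad[1], ", ", bad[2], ")")
  }
  if (scheme == "river_following") {
    stopifnot(!is.null(rivers), !is.null(sea))
    v <- c(water = 50000, land = 1e-4, sea = 150)
    if (!is.null(values)) v[names(values)] <- values
    cond <- matrix(v[["land"]], nrow(dem), ncol(dem))
    cond[sea == 1] <- v[["sea"]]
    cond[rivers == 1] <- v[["water"]]
  } else {
    v <- c(1e6, 1e5, 1000, 100, 0.001)
    if (!is.null(values)) v <- values
    band <- findInterval(dem, c(100, 500, 1500, 2000)) + 1L
    cond <- matrix(v[band], nrow(dem), ncol(dem))
  }
  attr(cond, "cellsize_km") <- attr(dem, "cellsize_km")
  attr(cond, "scheme") <- scheme
  cond
}

# 8-neighbour weighted graph over raster cells; edge cost between adjacent
# cells = centre distance / mean conductance (diagonals x sqrt(2))
.raster_graph <- function(cond, cell_km) {
  nr <- nrow(cond); nc <- ncol(cond)
  id <- matrix(seq_len(nr * nc), nr, nc)
  edges <- list(); w <- list()
  shift <- list(E = c(0, 1), S = c(1, 0), SE = c(1, 1), NE = c(-1, 1))
  for (s in names(shift)) {
    dr <- shift[[s]][1]; dc <- shift[[s]][2]
    rows <- seq_len(nr); cols <- seq_len(nc)
    r1 <- rows[rows + dr >= 1 & rows + dr <= nr]
    c1 <- cols[cols + dc >= 1 & cols + dc <= nc]
    from <- id[r1, c1, drop = FALSE]
    to <- id[r1 + dr, c1 + dc, drop = FALSE]
    d <- cell_km * if (dr != 0 && dc != 0) sqrt(2) else 1
    edges[[s]] <- cbind(as.vector(from), as.vector(to))
    w[[s]] <- d / ((cond[as.vector(from)] + cond[as.vector(to)]) / 2)
  }
  list(edges = do.call(rbind, edges), weights = unlist(w), id = id)
}

#' Least-cost-path distances between basin centroids
#'
#' Builds an 8-neighbour graph over the raster cells with edge cost
#' `distance / mean(conductance)` of the two cells (diagonal steps scaled
#' by sqrt(2)) and runs Dijkstra shortest paths between the cells holding
#' the centroids.
#'
#' @param cond conductance raster from [build_conductance_raster()].
#' @param points data frame with `basin_id`, `row`, `col` (grid
#'   coordinates; fractional values are rounded to the containing cell).
#' @return object of class `cost_distance`: list with `cost` (symmetric
#'   matrix, zero diagonal), `km` (`NULL` until [cost_to_km()]), `scheme`.
#' @export
cost_distance <- function(cond, points) {
  cell_km <- attr(cond, "cellsize_km")
  if (is.null(cell_km)) cell_km <- 1
  stopifnot(all(cond > 0), all(is.finite(cond)))
  rw <- round(points$row); cl <- round(points$col)
  stopifnot(all(rw >= 1), all(rw <= nrow(cond)),
            all(cl >= 1), all(cl <= ncol(cond)))
  g <- .raster_graph(cond, cell_km)
  gr <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  src <- g$id[cbind(rw, cl)]
  cost <- igraph::distances(gr, v = src, to = src, weights = g$weights,
                            algorithm = "dijkstra")
  dimnames(cost) <- list(points$basin_id, points$basin_id)
  cost <- (cost + t(cost)) / 2   # symmetrise numerical noise
  structure(list(cost = cost, km = NULL, scheme = attr(cond, "scheme")),
            class = "cost_distance")
}

#' Transform cost distances to kilometres
#'
#' Anchors the transformation to a reference conductance so that a path
#' running entirely through reference-conductance cells (water, in the
#' river-following scheme) reads as its along-path length in km:
#' `km = cost x reference_conductance`. Monotone and order-preserving.
#'
#' @param result a `cost_distance`.
#' @param reference_conductance anchor conductance (default: the water
#'   value of the river-following scheme).
#' @return the `cost_distance` with its `km` matrix filled.
#' @export
cost_to_km <- function(result, reference_conductance = 50000) {
  stopifnot(inherits(result, "cost_distance"))
  result$km <- result$cost * reference_conductance
  attr(result$km, "metric") <- paste0("LCP-km-", result$scheme)
  result
}

#' Great-circle distances between basin centroids
#'
#' Haversine distances on the mean Earth radius (6371.0088 km).
#'
#' @param points data frame with `basin_id`, `lon`, `lat` in decimal
#'   degrees.
#' @return symmetric km matrix with attribute `metric = "euclidean-km"`.
#' @export
euclidean_km <- function(points) {
  stopifnot(all(points$lon >= -180), all(points$lon <= 180),
            all(points$lat >= -90), all(points$lat <= 90))
  m <- geosphere::distm(cbind(points$lon, points$lat),
                        fun = function(p1, p2) {
                          geosphere::distHaversine(p1, p2, r = 6371008.8)
                        }) / 1000
  dimnames(m) <- list(points$basin_id, points$basin_id)
  attr(m, "metric") <- "euclidean-km"
  m
}
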