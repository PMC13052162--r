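#' Define a synthetic two-sided riverscape scenario
#'
#' The scenario emulates a coastal mountain range: a north-south main
#' drainage divide (MDD, the "ridge") splits the grid into a western
#' ("ligurian") and an eastern ("adriatic") slope, each draining through
#' independent river basins to its own sea margin.
#'
#' @param grid_shape integer (rows, cols) of the raster grid; at least
#'   (20, 20).
#' @param cell_size_km positive cell edge length in km.
#' @param ridge_col_fraction position of the divide column as a fraction of
#'   the grid width, in (0, 1).
#' @param n_basins_per_side basins on each side of the divide (>= 1).
#' @param sea_margin_cells width of the marine strip at each grid edge.
#' @param ridge_elevation_m summit elevation of the divide.
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class `riverscape_scenario`.
#' @export
riverscape_scenario <- function(grid_shape = c(40, 60), cell_size_km = 1,
                                ridge_col_fraction = 0.5,
                                n_basins_per_side = 2, sea_margin_cells = 2,
                                ridge_elevation_m = 2400, seed = 1) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 20),
            cell_size_km > 0, ridge_col_fraction > 0, ridge_col_fraction < 1,
            n_basins_per_side >= 1, sea_margin_cells >= 0)
  sc <- list(grid_shape = as.integer(grid_shape),
             cell_size_km = cell_size_km,
             ridge_col_fraction = ridge_col_fraction,
             n_basins_per_side = as.integer(n_basins_per_side),
             sea_margin_cells = as.integer(sea_margin_cells),
             ridge_elevation_m = ridge_elevation_m,
             seed = as.integer(seed))
  class(sc) <- "riverscape_scenario"
  sc
}

#' Generate the synthetic riverscape rasters and basin table
#'
#' Builds a DEM that peaks along the ridge column and decreases
#' monotonically toward the sea margin on each side, one river per basin
#' running from a headwater next to the ridge to the sea, a sea mask, and a
#' basin table with centroids (both grid coordinates and decimal-degree
#' lon/lat on a small coastal window) labelled by side of the divide. No
#' river crosses the ridge.
#'
#' @param scenario a [riverscape_scenario()].
#' @return list with elements `dem`, `rivers` (0/1), `sea` (logical as 0/1)
#'   — all matrices carrying `cellsize_km` attributes — and `basins`, a data
#'   frame with `basin_id`, `side`, `row`, `col`, `lon`, `lat`.
#' @export
generate_riverscape <- function(scenario) {
  stopifnot(inherits(scenario, "riverscape_scenario"))
  nr <- scenario$grid_shape[1]; nc <- scenario$grid_shape[2]
  nb <- scenario$n_basins_per_side
  margin <- scenario$sea_margin_cells
  ridge_col <- max(2L, min(nc - 1L, as.integer(round(nc * scenario$ridge_col_fraction))))

  # each basin needs a distinct river row; leave one grid row between rivers
  if (nr < 2 * nb + 4) {
    stop("configuration error: grid too small for ", nb, " basins per side")
  }

  set.seed(stage_seed(scenario$seed, "riverscape"))

  # DEM: purely column-dependent profile, highest on the ridge column,
  # strictly decreasing toward each margin; sea cells at 0
  col_idx <- seq_len(nc)
  west_w <- ridge_col - 1; east_w <- nc - ridge_col
  rel <- ifelse(col_idx <= ridge_col,
                1 - (ridge_col - col_idx) / west_w,
                1 - (col_idx - ridge_col) / east_w)
  elev_profile <- scenario$ridge_elevation_m * pmax(rel, 0)^1.4
  dem <- matrix(rep(elev_profile, each = nr), nrow = nr, ncol = nc)

  sea <- matrix(0, nr, nc)
  if (margin > 0) {
    sea[, seq_len(margin)] <- 1
    sea[, (nc - margin + 1):nc] <- 1
    dem[sea == 1] <- 0
  }

  # rivers: one straight row path per basin from a headwater adjacent to the
  # ridge to the sea margin on its own side
  river_rows <- round(seq(3, nr - 2, length.out = nb))
  rivers <- matrix(0, nr, nc)
  basins <- list()
  for (side in c("ligurian", "adriatic")) {
    for (b in seq_len(nb)) {
      rrow <- river_rows[b]
      if (side == "ligurian") {
        cols <- (margin + 1):(ridge_col - 1)   # west slope, drains west
      } else {
        cols <- (ridge_col + 1):(nc - margin)  # east slope, drains east
      }
      rivers[rrow, cols] <- 1
      bid <- sprintf("%s_%02d", ifelse(side == "ligurian", "LIG", "ADR"), b)
      basins[[bid]] <- data.frame(
        basin_id = bid, side = side,
        row = rrow, col = mean(cols), stringsAsFactors = FALSE)
    }
  }
  basins <- do.call(rbind, c(basins, list(make.row.names = FALSE)))

  # map grid coordinates to a small coastal lon/lat window (planar grids are
  # analysed with cell_size_km; lon/lat only feed the haversine distances)
  km_per_deg_lat <- 111.195
  lat0 <- 44.0; lon0 <- 8.0
  basins$lat <- lat0 + (nr - basins$row) * scenario$cell_size_km / km_per_deg_lat
  basins$lon <- lon0 + basins$col * scenario$cell_size_km /
    (km_per_deg_lat * cos(lat0 * pi / 180))

  for (g in c("dem", "rivers", "sea")) {
    m <- get(g)
    attr(m, "cellsize_km") <- scenario$cell_size_km
    assign(g, m)
  }
  list(dem = dem, rivers = rivers, sea = sea, basins = basins,
       ridge_col = ridge_col)
}
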