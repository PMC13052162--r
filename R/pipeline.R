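#' Per-species intraspecific analyses
#'
#' For every species with ASVs in at least two basins: progressive
#' alignment, pairwise genetic distances and between-basin betaMPD; plus
#' the whole-community betaMPD over all species-level ASVs.
#'
#' @param community a `community_matrix`.
#' @param sequences named character vector of the surviving ASV sequences.
#' @param taxonomy taxonomy data frame.
#' @param cross_species how [community_beta_mpd()] scores cross-species
#'   pairs.
#' @return list with `species` (selected names), `per_species` (named list
#'   of `alignment`, `distances`, `betampd`), `community_betampd`.
#' @export
intraspecific_analysis <- function(community, sequences, taxonomy,
                                   cross_species = "cap") {
  species <- select_species(community, taxonomy)
  ranks <- .split_taxa(taxonomy$taxon_path)
  sp_of <- setNames(ranks[, "species"], taxonomy$asv_id)
  per <- list()
  asv_sets <- list(); d_sets <- list()
  for (s in species) {
    ids <- intersect(names(sp_of)[sp_of == s], colnames(community$presence))
    ids <- intersect(ids, names(sequences))
    if (length(ids) < 2) next
    aln <- align_species(sequences[ids], species_name = s)
    gd <- pairwise_distances(aln)
    bm <- beta_mpd(community, ids, gd$D)
    per[[s]] <- list(alignment = aln, distances = gd, betampd = bm)
    asv_sets[[s]] <- ids
    d_sets[[s]] <- gd$D
  }
  comm_bm <- if (length(asv_sets) >= 1) {
    community_beta_mpd(community, asv_sets, d_sets,
                       cross_species = cross_species)
  } else NULL
  list(species = names(per), per_species = per,
       community_betampd = comm_bm)
}

#' Landscape distance matrices for a riverscape
#'
#' Euclidean (haversine between centroids), river-following least-cost
#' path, and elevation-weighted least-cost path, all in km.
#'
#' @param riverscape output of [generate_riverscape()].
#' @return named list of three symmetric km matrices: `euclidean`,
#'   `topographic`, `elevation_weighted`.
#' @export
landscape_distances <- function(riverscape) {
  basins <- riverscape$basins
  eu <- euclidean_km(basins)
  riv <- build_conductance_raster(riverscape$dem, riverscape$rivers,
                                  riverscape$sea, "river_following")
  elev <- build_conductance_raster(riverscape$dem, scheme = "elevation_weighted")
  topo <- cost_to_km(cost_distance(riv, basins))$km
  ew <- cost_to_km(cost_distance(elev, basins),
                   reference_conductance = 1e6)$km
  list(euclidean = eu, topographic = topo, elevation_weighted = ew)
}

#' Fit isolation-by-distance GDMs for each species and distance scheme
#'
#' Scales each species' betaMPD to the unit interval and fits one GDM per geographic
#' distance matrix.
#'
#' @param intra result of [intraspecific_analysis()].
#' @param distances named list of km matrices (see
#'   [landscape_distances()]).
#' @param n_splines I-splines per model.
#' @return nested list `fits[[species]][[scheme]]` of `gdm_fit` objects
#'   (`NULL` where a model is unidentifiable, e.g. constant distances).
#' @export
ibd_gdms <- function(intra, distances, n_splines = 3) {
  fits <- list()
  for (s in intra$species) {
    bm <- intra$per_species[[s]]$betampd
    tab0 <- tryCatch(scale_response(bm), error = function(e) NULL,
                     warning = function(w) suppressWarnings(scale_response(bm)))
    if (is.null(tab0)) next
    for (scheme in names(distances)) {
      dm <- distances[[scheme]]
      tab <- tab0
      tab$distance <- dm[cbind(tab$basin_i, tab$basin_j)]
      fits[[s]][[scheme]] <- tryCatch(
        fit_gdm(tab, n_splines = n_splines),
        error = function(e) NULL)
    }
  }
  fits
}

#' Default pipeline configuration
#'
#' Defaults follow the standard analysis constants: occurrence >= 2
#' samples, >= 10 total reads, 999 permutations, three I-splines, the
#' river-following and elevation-weighted conductance values.
#'
#' @param seed global seed; every stage derives its randomness from it.
#' @param scenario a [riverscape_scenario()].
#' @param ... overrides for `min_samples`, `min_total_reads`,
#'   `n_permutations`, `n_splines`, `cross_species`, `numt_mode`, and the
#'   synthetic planting counts (`n_numts`, `n_singletons`, `n_low_read`,
#'   `n_contaminants`, `n_marine`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            scenario = riverscape_scenario(
                              grid_shape = c(40, 60), n_basins_per_side = 5,
                              seed = seed),
                            ...) {
  cfg <- list(seed = as.integer(seed), scenario = scenario,
              min_samples = 2, min_total_reads = 10,
              n_permutations = 999, n_splines = 3,
              cross_species = "cap", numt_mode = "fixed-trim-15",
              n_numts = 20, n_singletons = 15, n_low_read = 10,
              n_contaminants = 5, n_marine = 5, lambda = 2,
              cross_divide_pairs = 1)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic pipeline
#'
#' simulate -> filter -> community statistics -> intraspecific ->
#' landscape -> GDM, all driven by one seed. When `out_dir` is given, every
#' stage's tables are written there along with the resolved configuration
#' and a provenance manifest (seed, package version, file checksums);
#' rerunning with an identical configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `dataset`, `filtered`, `community` (Jaccard, PCoA,
#'   ANOSIM, richness), `intraspecific`, `landscape`, `gdm`, `mantel`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ds <- synthesize_dataset(config$scenario,
                           n_numts = config$n_numts,
                           n_singletons = config$n_singletons,
                           n_low_read = config$n_low_read,
                           n_contaminants = config$n_contaminants,
                           n_marine = config$n_marine,
                           lambda = config$lambda,
                           cross_divide_pairs = config$cross_divide_pairs,
                           seed = config$seed)

  filt <- filter_asvs(ds$reads, ds$sequences, ds$taxonomy, ds$metadata,
                      min_samples = config$min_samples,
                      min_total_reads = config$min_total_reads,
                      numt_mode = config$numt_mode)
  comm <- filt$community

  jac_asv <- jaccard_dissimilarity(comm, "asv")
  jac_tax <- jaccard_dissimilarity(comm, "taxon", ds$taxonomy)
  side <- comm$side_of_divide
  community <- list(
    jaccard_asv = jac_asv, jaccard_taxon = jac_tax,
    pcoa_asv = pcoa(jac_asv),
    anosim_asv = anosim_test(jac_asv, side, config$n_permutations,
                             seed = config$seed),
    anosim_taxon = anosim_test(jac_tax, side, config$n_permutations,
                               seed = config$seed + 1L),
    richness_asv = richness_by_side(comm, "asv"),
    richness_taxon = richness_by_side(comm, "taxon", ds$taxonomy))

  intra <- intraspecific_analysis(comm, ds$sequences[filt$survivors],
                                  ds$taxonomy,
                                  cross_species = config$cross_species)

  mant <- if (!is.null(intra$community_betampd)) {
    # degenerate (zero-variance) matrices can occur in tiny scenarios
    tryCatch(mantel_test(jac_asv, intra$community_betampd,
                         config$n_permutations, seed = config$seed + 2L),
             error = function(e) NULL)
  } else NULL

  land <- landscape_distances(ds$riverscape)
  gdms <- ibd_gdms(intra, land, n_splines = config$n_splines)

  res <- list(dataset = ds, filtered = filt, community = community,
              intraspecific = intra, mantel = mant, landscape = land,
              gdm = gdms, config = config)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(res$dataset, file.path(out_dir, "simulated"))
  write_tsv(res$filtered$report, file.path(out_dir, "filter_report.tsv"))
  write_tsv(res$filtered$community$presence * 1,
            file.path(out_dir, "community_matrix.tsv"))
  write_tsv(res$community$jaccard_asv, file.path(out_dir, "jaccard_asv.tsv"))
  if (!is.null(res$intraspecific$community_betampd)) {
    write_tsv(res$intraspecific$community_betampd,
              file.path(out_dir, "community_betampd.tsv"))
  }
  for (s in names(res$landscape)) {
    write_tsv(res$landscape[[s]], file.path(out_dir, paste0("dist_", s, ".tsv")))
  }
  gdm_summary <- do.call(rbind, lapply(names(res$gdm), function(sp) {
    do.call(rbind, lapply(names(res$gdm[[sp]]), function(sch) {
      f <- res$gdm[[sp]][[sch]]
      if (is.null(f)) return(NULL)
      data.frame(species = sp, scheme = sch,
                 deviance_explained = f$percent_deviance_explained,
                 intercept = f$intercept,
                 t(setNames(f$coefficients,
                            paste0("beta_", seq_along(f$coefficients)))),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(gdm_summary)) {
    write_tsv(gdm_summary, file.path(out_dir, "gdm_fits.tsv"))
  }
  cfg <- res$config
  cfg$scenario <- unclass(cfg$scenario)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(seed = res$config$seed,
                   package_version = as.character(utils::packageVersion("ednadivide")),
                   checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
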