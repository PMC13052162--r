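#' Marine fish families excluded from freshwater analyses
#'
#' The nine families removed by the taxonomic filter; also the label pool
#' for planted marine ASVs in the synthetic data.
#' @export
marine_families <- c("Clupeidae", "Mugilidae", "Sparidae", "Moronidae",
                     "Engraulidae", "Scombridae", "Xiphiidae", "Carangidae",
                     "Istiophoridae")

# default species pool: wide-ranging species across both sides, one species
# restricted to one side, one single-basin species (excluded downstream by
# the two-basin coverage rule)
.default_species_pool <- function(basins, seq_length, lambda) {
  lig <- basins$basin_id[basins$side == "ligurian"]
  adr <- basins$basin_id[basins$side == "adriatic"]
  all_b <- basins$basin_id
  defs <- list(
    list("Telestes muticellus",  "Leuciscidae",  all_b),
    list("Phoxinus lumaireul",   "Leuciscidae",  all_b),
    list("Barbus plebejus",      "Cyprinidae",   all_b),
    list("Squalius squalus",     "Leuciscidae",  all_b),
    list("Salmo trutta",         "Salmonidae",   lig),
    list("Cottus gobio",         "Cottidae",     all_b[1]))
  lapply(defs, function(d) {
    genus <- strsplit(d[[1]], " ")[[1]][1]
    species_model(
      d[[1]],
      ancestral_sequence = random_coding_sequence(seq_length, 15),
      per_step_mutations = lambda,
      occupancy = d[[3]],
      taxon_path = c(class = "Actinopterygii", order = "Cypriniformes",
                     family = d[[2]], genus = genus, species = d[[1]]))
  })
}

#' Synthesise an eDNA metabarcoding dataset with known ground truth
#'
#' Generates the post-denoising outputs of a metabarcoding run over the
#' synthetic riverscape: a samples x ASVs read matrix including negative
#' controls, ASV sequences, taxonomic assignments, sample metadata, and a
#' ground-truth object recording exactly which ASVs are true haplotypes and
#' which are planted artefacts (NUMT pseudogenes, single-sample noise,
#' sub-threshold low-read noise, negative-control contaminants, marine
#' taxa).
#'
#' @param scenario a [riverscape_scenario()].
#' @param species list of [species_model()] objects; defaults to a six-
#'   species pool with one single-basin species.
#' @param n_numts,n_singletons,n_low_read,n_contaminants,n_marine planted
#'   artefact counts.
#' @param n_controls number of negative-control samples (>= 1).
#' @param samples_per_basin eDNA samples per basin (>= 2 so that true ASVs
#'   satisfy the two-sample occurrence rule by construction).
#' @param cross_divide_pairs cross-divide stepping-stone edges (mixing near
#'   one end of the alongshore chain).
#' @param seq_length ASV length in bp.
#' @param lambda default per-edge Poisson substitution mean for the default
#'   species pool.
#' @param seed integer seed; the run is deterministic given all arguments.
#' @return object of class `edna_dataset`: list with `reads`
#'   ([read_matrix()]), `sequences`, `taxonomy`, `metadata`, `ground_truth`,
#'   `riverscape`, `scenario`, `species`.
#' @export
synthesize_dataset <- function(scenario = riverscape_scenario(),
                               species = NULL,
                               n_numts = 20, n_singletons = 15,
                               n_low_read = 10, n_contaminants = 5,
                               n_marine = 5, n_controls = 2,
                               samples_per_basin = 2,
                               cross_divide_pairs = 1,
                               seq_length = 420, lambda = 2,
                               seed = scenario$seed) {
  stopifnot(n_controls >= 1, samples_per_basin >= 2)
  rs <- generate_riverscape(scenario)
  basins <- rs$basins
  set.seed(stage_seed(seed, "dataset"))
  if (is.null(species)) {
    species <- .default_species_pool(basins, seq_length, lambda)
  }

  # sample layout: samples nested in sites nested in basins, plus controls
  meta <- do.call(rbind, lapply(seq_len(nrow(basins)), function(i) {
    data.frame(
      sample_id = sprintf("%s_S%d", basins$basin_id[i],
                          seq_len(samples_per_basin)),
      site_id = sprintf("site_%s_%d", basins$basin_id[i],
                        seq_len(samples_per_basin)),
      basin_id = basins$basin_id[i], side = basins$side[i],
      year = rep_len(c(2021L, 2022L), samples_per_basin),
      is_control = FALSE, stringsAsFactors = FALSE)
  }))
  ctrl <- data.frame(sample_id = sprintf("NEG_%02d", seq_len(n_controls)),
                     site_id = NA_character_, basin_id = NA_character_,
                     side = NA_character_, year = 2021L, is_control = TRUE,
                     stringsAsFactors = FALSE)
  meta <- rbind(meta, ctrl)

  # evolve true haplotypes per species over the stepping-stone graph
  seqs <- character(0); seq_meta <- list()
  hap_of_species <- list()
  for (si in seq_along(species)) {
    sp <- species[[si]]
    occ <- sp$occupancy
    if (length(occ) >= 2) {
      graph <- basin_stepping_stone_graph(basins[basins$basin_id %in% occ, ],
                                          cross_divide_pairs)
      haps <- evolve_haplotypes(sp, graph, seed = seed + 1000L * si,
                                frame_offset = 15)
    } else {
      haps <- setNames(list(sp$ancestral_sequence), occ)
    }
    hap_of_species[[sp$species_name]] <- haps
    # collapse identical sequences shared between basins into one ASV
    uniq <- unique(unlist(haps))
    for (u in uniq) {
      bset <- names(haps)[vapply(haps, function(h) u %in% h, TRUE)]
      seqs <- c(seqs, u)
      seq_meta[[length(seqs)]] <- list(class = "true", species_idx = si,
                                       basins = bset)
    }
  }
  n_true <- length(seqs)

  draw_reads <- function(n, mean, size) 1L + rnbinom(n, size = size, mu = mean)

  add_unique_seq <- function(s) {
    if (s %in% seqs) stop("generator conflict: planted classes collide on one ASV")
    seqs[length(seqs) + 1L] <<- s
  }

  # NUMTs: copies of true haplotypes with ~2% substitutions plus a planted
  # in-frame stop codon at codon >= 10 of the trimmed frame
  for (i in seq_len(n_numts)) {
    src <- sample.int(n_true, 1)
    s <- .mutate_sequence(seqs[src], rbinom(1, seq_length, 0.02))
    n_codon <- (nchar(s) - 15L) %/% 3L
    cod <- sample(10:(n_codon - 1L), 1)
    pos <- 15L + (cod - 1L) * 3L + 1L
    substr(s, pos, pos + 2L) <- sample(.vert_mito_stops, 1)
    add_unique_seq(s)
    seq_meta[[length(seqs)]] <- list(class = "numt",
                                     species_idx = seq_meta[[src]]$species_idx,
                                     basins = seq_meta[[src]]$basins)
  }
  for (i in seq_len(n_singletons)) {
    add_unique_seq(random_coding_sequence(seq_length, 15))
    seq_meta[[length(seqs)]] <- list(class = "singleton", species_idx = 1L)
  }
  for (i in seq_len(n_low_read)) {
    add_unique_seq(random_coding_sequence(seq_length, 15))
    seq_meta[[length(seqs)]] <- list(class = "low_read", species_idx = 1L)
  }
  for (i in seq_len(n_contaminants)) {
    add_unique_seq(random_coding_sequence(seq_length, 15))
    seq_meta[[length(seqs)]] <- list(class = "contaminant", species_idx = 1L)
  }
  for (i in seq_len(n_marine)) {
    add_unique_seq(random_coding_sequence(seq_length, 15))
    seq_meta[[length(seqs)]] <- list(class = "marine",
                                     family = sample(marine_families, 1))
  }

  asv_ids <- sprintf("ASV_%04d", seq_along(seqs))
  names(seqs) <- asv_ids

  # read counts
  counts <- matrix(0L, nrow = nrow(meta), ncol = length(seqs),
                   dimnames = list(meta$sample_id, asv_ids))
  noncontrol <- meta$sample_id[!meta$is_control]
  for (k in seq_along(seqs)) {
    sm <- seq_meta[[k]]
    if (sm$class %in% c("true", "numt")) {
      smp <- meta$sample_id[!meta$is_control & meta$basin_id %in% sm$basins]
      mu <- if (sm$class == "true") species[[sm$species_idx]]$reads_mean else 500
      counts[smp, k] <- draw_reads(length(smp), mu,
                                   species[[sm$species_idx]]$reads_dispersion)
    } else if (sm$class == "singleton") {
      counts[sample(noncontrol, 1), k] <- 50L + rpois(1, 150)
    } else if (sm$class == "low_read") {
      smp <- sample(noncontrol, 2)
      counts[smp, k] <- c(4L, sample(1:5, 1))   # total < 10 across >= 2 samples
    } else if (sm$class == "contaminant") {
      ctrl_id <- sample(meta$sample_id[meta$is_control], 1)
      counts[ctrl_id, k] <- 60L + rpois(1, 40)
      smp <- sample(noncontrol, 3)
      counts[smp, k] <- sample(5:40, 3)          # all below the control count
    } else if (sm$class == "marine") {
      smp <- sample(noncontrol, 3)
      counts[smp, k] <- draw_reads(3, 2000, 2)
    }
  }

  # taxonomy: rank path Class;Order;Family;Genus;Species
  tax <- data.frame(asv_id = asv_ids, taxon_path = NA_character_,
                    confidence = round(runif(length(seqs), 60, 100), 1),
                    stringsAsFactors = FALSE)
  for (k in seq_along(seqs)) {
    sm <- seq_meta[[k]]
    if (sm$class == "marine") {
      tax$taxon_path[k] <- paste("Actinopterygii", "Clupeiformes", sm$family,
                                 "", "", sep = ";")
    } else {
      tp <- species[[sm$species_idx]]$taxon_path
      tax$taxon_path[k] <- paste(tp, collapse = ";")
    }
  }

  classes <- vapply(seq_meta, function(x) x$class, "")
  truth <- list(
    planted_numt_ids = asv_ids[classes == "numt"],
    planted_contaminant_ids = asv_ids[classes == "contaminant"],
    planted_noise_ids = asv_ids[classes %in% c("singleton", "low_read")],
    planted_marine_ids = asv_ids[classes == "marine"],
    true_haplotype_of_asv = setNames(lapply(which(classes == "true"),
      function(k) list(species = species[[seq_meta[[k]]$species_idx]]$species_name,
                       basins = seq_meta[[k]]$basins)),
      asv_ids[classes == "true"]),
    expected_survivor_count = n_true)

  structure(list(
    reads = read_matrix(counts, is_control = setNames(meta$is_control,
                                                      meta$sample_id)),
    sequences = seqs, taxonomy = tax, metadata = meta,
    ground_truth = truth, riverscape = rs, scenario = scenario,
    species = species), class = "edna_dataset")
}

#' Write an `edna_dataset` to a directory
#'
#' Emits the ASV table (TSV, samples as rows), sequences (FASTA), taxonomy
#' (TSV), sample metadata (TSV), the riverscape rasters (Esri ASCII grid),
#' basin centroids (TSV) and the ground truth (JSON).
#'
#' @param dataset an `edna_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(dataset$reads$counts, file.path(dir, "asv_table.tsv"))
  write_fasta(dataset$sequences, file.path(dir, "asvs.fasta"))
  write_tsv(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tsv(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_tsv(dataset$riverscape$basins, file.path(dir, "basins.tsv"))
  for (g in c("dem", "rivers", "sea")) {
    write_ascii_grid(dataset$riverscape[[g]], file.path(dir, paste0(g, ".asc")))
  }
  jsonlite::write_json(dataset$ground_truth,
                       file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
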