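#' Simulate a random in-frame coding sequence
#'
#' Emulates a cytochrome b amplicon: an arbitrary 5' overhang of
#' `frame_offset` bases followed by sense codons of the vertebrate
#' mitochondrial code, so the sequence is stop-free when translated after
#' trimming the overhang.
#'
#' @param length total sequence length in bp (default 420, a typical cytb
#'   metabarcoding fragment).
#' @param frame_offset length of the 5' overhang before the first codon.
#' @return a single DNA string.
#' @export
random_coding_sequence <- function(length = 420, frame_offset = 15) {
  stopifnot(length > frame_offset + 3)
  head_part <- paste(sample(c("A", "C", "G", "T"), frame_offset, TRUE),
                     collapse = "")
  n_codon <- ceiling((length - frame_offset) / 3)
  body <- paste(sample(.sense_codons, n_codon, TRUE), collapse = "")
  substr(paste0(head_part, body), 1, length)
}

#' Define a species for the synthetic dataset
#'
#' @param species_name binomial name.
#' @param ancestral_sequence DNA string over A/C/G/T (default: random
#'   in-frame coding sequence of 420 bp).
#' @param per_step_mutations Poisson mean number of substitutions applied
#'   along each edge of the basin stepping-stone graph (the isolation by
#'   distance dial; 0 means every basin shares the ancestral haplotype).
#' @param occupancy character vector of occupied basin ids (resolved by the
#'   synthesiser if `NULL`).
#' @param reads_mean,reads_dispersion negative-binomial read-count
#'   parameters per occupied sample.
#' @param taxon_path named character vector with ranks class, order, family,
#'   genus, species.
#' @return object of class `species_model`.
#' @export
species_model <- function(species_name, ancestral_sequence = NULL,
                          per_step_mutations = 2, occupancy = NULL,
                          reads_mean = 5000, reads_dispersion = 2,
                          taxon_path = NULL) {
  if (!is.null(ancestral_sequence)) {
    stopifnot(grepl("^[ACGT]+$", ancestral_sequence))
  }
  stopifnot(per_step_mutations >= 0, is.finite(per_step_mutations))
  if (is.null(taxon_path)) {
    genus <- strsplit(species_name, " ")[[1]][1]
    taxon_path <- c(class = "Actinopterygii", order = "Cypriniformes",
                    family = "Cyprinidae", genus = genus,
                    species = species_name)
  }
  structure(list(species_name = species_name,
                 ancestral_sequence = ancestral_sequence,
                 per_step_mutations = per_step_mutations,
                 occupancy = occupancy, reads_mean = reads_mean,
                 reads_dispersion = reads_dispersion,
                 taxon_path = taxon_path),
            class = "species_model")
}

# apply k random substitutions to a sequence; when frame_offset is given,
# substitutions that would create an in-frame stop codon (vertebrate mito
# code) are resampled — a minimal model of purifying selection on a
# protein-coding marker
.mutate_sequence <- function(seq, k, frame_offset = NULL) {
  if (k == 0) return(seq)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  for (i in seq_len(k)) {
    for (try in 1:50) {
      pos <- sample.int(length(chars), 1)
      new <- sample(setdiff(bases, chars[pos]), 1)
      cand <- chars
      cand[pos] <- new
      if (is.null(frame_offset) ||
          !has_stop_codon(paste(cand, collapse = ""), frame_offset)) {
        chars <- cand
        break
      }
    }
  }
  paste(chars, collapse = "")
}

#' Evolve haplotypes over a basin stepping-stone graph
#'
#' The root basin carries the ancestral sequence; each edge of the graph
#' applies Poisson(lambda) substitutions at uniformly chosen positions, so
#' expected pairwise mismatch grows with graph distance — a constructed
#' isolation-by-distance signal.
#'
#' @param model a [species_model()].
#' @param basin_graph two-column character matrix (or data frame) of edges
#'   over the occupied basins; must be connected.
#' @param seed integer seed.
#' @param frame_offset if non-`NULL`, substitutions creating in-frame stop
#'   codons are resampled (see [random_coding_sequence()]).
#' @return named list: basin id -> character vector of haplotype sequences.
#' @export
evolve_haplotypes <- function(model, basin_graph, seed = 1,
                              frame_offset = NULL) {
  stopifnot(inherits(model, "species_model"))
  anc <- model$ancestral_sequence
  if (is.null(anc)) stop("model has no ancestral sequence")
  edges <- as.matrix(basin_graph)[, 1:2, drop = FALSE]
  basins <- unique(c(edges))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (!igraph::is_connected(g)) stop("basin graph must be connected")

  set.seed(stage_seed(seed, "haplotypes"))
  lambda <- model$per_step_mutations
  haps <- setNames(vector("list", length(basins)), basins)
  root <- basins[1]
  haps[[root]] <- anc
  # BFS from the root over a spanning tree of the graph
  bfs <- igraph::bfs(g, root = root, father = TRUE)
  order_v <- names(bfs$order)
  vnames <- names(igraph::V(g))
  father <- setNames(vnames[as.integer(bfs$father)], vnames)
  for (v in order_v[-1]) {
    parent_seq <- haps[[father[[v]]]][1]
    k <- rpois(1, lambda)
    haps[[v]] <- .mutate_sequence(parent_seq, k, frame_offset)
  }
  haps
}

#' Alongshore stepping-stone graph for a basin table
#'
#' Chains the basins of each side in alongshore (row) order and optionally
#' adds cross-divide edges between the first `cross_divide_pairs` opposite
#' basin pairs, emulating cross-divide faunal exchange near the coast.
#'
#' @param basins basin table from [generate_riverscape()].
#' @param cross_divide_pairs number of opposite-basin pairs to connect
#'   across the divide.
#' @return two-column character matrix of edges.
#' @export
basin_stepping_stone_graph <- function(basins, cross_divide_pairs = 0) {
  edge_list <- list()
  for (side in unique(basins$side)) {
    ids <- basins$basin_id[basins$side == side][order(basins$row[basins$side == side])]
    if (length(ids) > 1) {
      edge_list[[side]] <- cbind(ids[-length(ids)], ids[-1])
    }
  }
  if (cross_divide_pairs > 0) {
    lig <- basins$basin_id[basins$side == "ligurian"]
    adr <- basins$basin_id[basins$side == "adriatic"]
    k <- min(cross_divide_pairs, length(lig), length(adr))
    edge_list[["cross"]] <- cbind(lig[seq_len(k)], adr[seq_len(k)])
  }
  do.call(rbind, edge_list)
}
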