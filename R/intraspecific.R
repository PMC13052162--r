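#' Species with usable coverage for intraspecific analyses
#'
#' Returns the species (species-level assignments only) whose ASVs occur in
#' at least two basins, the minimum for pairwise between-basin comparisons.
#'
#' @param community a `community_matrix` from [pool_to_basins()].
#' @param taxonomy taxonomy data frame covering the community's ASVs.
#' @param min_basins coverage threshold (default 2).
#' @return character vector of species names.
#' @export
select_species <- function(community, taxonomy, min_basins = 2) {
  ranks <- .split_taxa(taxonomy$taxon_path)
  sp <- setNames(ranks[, "species"], taxonomy$asv_id)
  asvs <- colnames(community$presence)
  sp <- sp[asvs]
  sp[is.na(sp) | sp == ""] <- NA
  out <- character(0)
  for (s in unique(stats::na.omit(sp))) {
    cols <- asvs[!is.na(sp) & sp == s]
    n_basins <- sum(rowSums(community$presence[, cols, drop = FALSE]) > 0)
    if (n_basins >= min_basins) out <- c(out, s)
  }
  sort(out)
}

#' Pairwise genetic distances from an alignment
#'
#' Counts, for every sequence pair, the aligned columns where both rows
#' carry unambiguous bases (pairwise deletion of gaps and ambiguity codes)
#' and the bases differ. Raw mismatch counts and proportions per comparable
#' site are both returned.
#'
#' @param alignment a `species_alignment` from [align_species()].
#' @return object of class `genetic_distance`: list with `D` (symmetric
#'   integer mismatch matrix), `comparable_sites`, `proportion` (`NaN` where
#'   a pair has zero comparable sites; such pairs are excluded downstream).
#' @export
pairwise_distances <- function(alignment) {
  stopifnot(inherits(alignment, "species_alignment"))
  prof <- .encode_profile(alignment$aligned)
  both <- .cpp_mismatch_pairs(prof)
  n <- nrow(both)
  mm <- both * lower.tri(both); mm <- mm + t(mm)
  comp <- both * upper.tri(both); comp <- comp + t(comp)
  diag(comp) <- nchar(alignment$aligned[1])
  ids <- alignment$asv_ids
  dimnames(mm) <- dimnames(comp) <- list(ids, ids)
  prop <- mm / comp   # NaN where comparable_sites == 0
  if (any(comp == 0 & upper.tri(comp))) {
    warning("pairs with zero comparable sites: distance undefined")
  }
  structure(list(D = mm, comparable_sites = comp, proportion = prop),
            class = "genetic_distance")
}

#' Between-basin mean pairwise genetic distance (betaMPD)
#'
#' For each basin pair, the mean of the genetic distances over all cross
#' pairs of ASVs, one drawn from each basin (presence/absence weighting).
#' Two basins each holding only the same single haplotype score 0.
#'
#' @param community a `community_matrix`.
#' @param asv_ids the species' ASV ids (columns of the community and of
#'   `D`).
#' @param D symmetric genetic distance matrix over (at least) `asv_ids`.
#' @return symmetric basins x basins matrix with zero diagonal; `NA` for a
#'   pair where a basin holds no ASV of the species, with attribute
#'   `metric = "betaMPD"`.
#' @export
beta_mpd <- function(community, asv_ids, D) {
  stopifnot(inherits(community, "community_matrix"))
  asv_ids <- intersect(asv_ids, colnames(community$presence))
  stopifnot(all(asv_ids %in% rownames(D)))
  pres <- community$presence[, asv_ids, drop = FALSE]
  basins <- rownames(pres)
  out <- matrix(NA_real_, length(basins), length(basins),
                dimnames = list(basins, basins))
  diag(out) <- 0
  sets <- lapply(basins, function(b) asv_ids[pres[b, ]])
  for (i in seq_along(basins)) for (j in seq_len(i - 1)) {
    a <- sets[[i]]; b <- sets[[j]]
    if (length(a) && length(b)) {
      out[i, j] <- out[j, i] <- mean(D[a, b, drop = FALSE])
    }
  }
  attr(out, "metric") <- "betaMPD"
  out
}

#' Whole-community betaMPD
#'
#' betaMPD over the union of species-level ASVs of all species. Genetic
#' distances are only defined within species; cross-species ASV pairs
#' receive a capped distance equal to the global maximum observed
#' intraspecific distance (`cross_species = "cap"`), or are excluded from
#' the cross-pair mean (`"exclude"`).
#'
#' @param community a `community_matrix`.
#' @param species_asvs named list: species -> ASV ids.
#' @param D_list named list: species -> intraspecific distance matrix.
#' @param cross_species `"cap"` or `"exclude"`.
#' @return symmetric basins x basins betaMPD matrix.
#' @export
community_beta_mpd <- function(community, species_asvs, D_list,
                               cross_species = c("cap", "exclude")) {
  cross_species <- match.arg(cross_species)
  all_ids <- unlist(species_asvs, use.names = FALSE)
  stopifnot(!anyDuplicated(all_ids))
  cap <- max(0, vapply(D_list, function(d) max(d, na.rm = TRUE), 0))
  fill <- if (cross_species == "cap") cap else NA_real_
  Dall <- matrix(fill, length(all_ids), length(all_ids),
                 dimnames = list(all_ids, all_ids))
  for (s in names(species_asvs)) {
    ids <- species_asvs[[s]]
    Dall[ids, ids] <- D_list[[s]][ids, ids]
  }
  diag(Dall) <- 0
  if (cross_species == "exclude") {
    # cross-pair mean over defined entries only
    pres <- community$presence[, intersect(all_ids, colnames(community$presence)),
                               drop = FALSE]
    basins <- rownames(pres)
    out <- matrix(NA_real_, length(basins), length(basins),
                  dimnames = list(basins, basins))
    diag(out) <- 0
    sets <- lapply(basins, function(b) colnames(pres)[pres[b, ]])
    for (i in seq_along(basins)) for (j in seq_len(i - 1)) {
      a <- sets[[i]]; b <- sets[[j]]
      if (length(a) && length(b)) {
        vals <- Dall[a, b, drop = FALSE]
        out[i, j] <- out[j, i] <- mean(vals[!is.na(vals)])
      }
    }
    attr(out, "metric") <- "betaMPD"
    return(out)
  }
  beta_mpd(community, all_ids, Dall)
}
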