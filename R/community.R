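#' Collapse a community matrix to its highest assigned taxa
#'
#' Presence/absence of the deepest assigned taxon per ASV (species, else
#' genus, else family); ASVs with no assignment at family rank or deeper
#' are dropped.
#'
#' @param community a `community_matrix`.
#' @param taxonomy taxonomy data frame.
#' @return a `community_matrix` whose columns are taxa.
#' @export
collapse_to_taxa <- function(community, taxonomy) {
  ranks <- .split_taxa(taxonomy$taxon_path)
  label <- ifelse(ranks[, "species"] != "", ranks[, "species"],
                  ifelse(ranks[, "genus"] != "", ranks[, "genus"],
                         ranks[, "family"]))
  label[ranks[, "family"] == ""] <- NA
  label <- setNames(label, taxonomy$asv_id)[colnames(community$presence)]
  keep <- !is.na(label)
  pres <- community$presence[, keep, drop = FALSE]
  taxa <- unique(label[keep])
  out <- vapply(taxa, function(tx) {
    rowSums(pres[, label[keep] == tx, drop = FALSE]) > 0
  }, logical(nrow(pres)))
  structure(list(presence = out, side_of_divide = community$side_of_divide),
            class = "community_matrix")
}

#' Jaccard dissimilarity between basins
#'
#' `1 - |intersection| / |union|` on presence/absence sets, at ASV level or
#' collapsed to the highest assigned taxon (at least family).
#'
#' @param community a `community_matrix`.
#' @param level `"asv"` or `"taxon"`.
#' @param taxonomy required for `level = "taxon"`.
#' @return symmetric dissimilarity matrix in `[0, 1]` with attribute
#'   `metric = "jaccard"`; a pair of empty basins scores 0 with a warning.
#' @export
jaccard_dissimilarity <- function(community, level = c("asv", "taxon"),
                                  taxonomy = NULL) {
  level <- match.arg(level)
  if (level == "taxon") {
    stopifnot(!is.null(taxonomy))
    community <- collapse_to_taxa(community, taxonomy)
  }
  pres <- community$presence * 1
  inter <- tcrossprod(pres)
  size <- rowSums(pres)
  uni <- outer(size, size, "+") - inter
  D <- 1 - inter / uni
  if (any(uni == 0)) {
    warning("basin pair(s) with no occurrences: Jaccard defined as 0")
    D[uni == 0] <- 0
  }
  diag(D) <- 0
  attr(D, "metric") <- "jaccard"
  D
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres `-D^2/2`, eigendecomposes, and returns the axes with
#' positive eigenvalues, scaled by the square root of the eigenvalue. Axis
#' signs are fixed by making each axis's largest-magnitude loading
#' positive. Negative eigenvalues are dropped (magnitudes retained in the
#' `negative_eigenvalues` attribute).
#'
#' @param D symmetric dissimilarity matrix with labels.
#' @return object of class `pcoa_result`: list with `coordinates` (labels x
#'   axes) and `eigenvalues`.
#' @export
pcoa <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (all(D == 0)) {
    return(structure(list(coordinates = matrix(0, n, 0,
                                               dimnames = list(rownames(D), NULL)),
                          eigenvalues = numeric(0)),
                     class = "pcoa_result"))
  }
  # cmdscale warns when fewer than k axes have positive eigenvalues; the
  # positive set is selected explicitly below
  mds <- suppressWarnings(cmdscale(stats::as.dist(D), k = n - 1, eig = TRUE))
  eig <- mds$eig
  tol <- max(abs(eig)) * sqrt(.Machine$double.eps)
  pos <- which(eig > tol)
  coords <- mds$points[, pos, drop = FALSE]
  for (ax in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, ax])), ax] < 0) {
      coords[, ax] <- -coords[, ax]
    }
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = eig[pos],
                 negative_eigenvalues = abs(eig[eig < -tol])),
            class = "pcoa_result")
}

# lower-triangle pair indices of an n x n matrix
.pair_index <- function(n) {
  ij <- which(lower.tri(diag(n)), arr.ind = TRUE)
  list(i = ij[, 1], j = ij[, 2])
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of between- versus within-group
#' dissimilarities. All off-diagonal pairs are ranked with midranks;
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` with
#' `M = n(n-1)/2`. The permutation null shuffles group labels; the p-value
#' follows the `(1 + k) / (1 + N)` convention and the observed labelling is
#' never counted as a draw.
#'
#' @param D symmetric dissimilarity matrix.
#' @param groups group label per row of `D` (>= 2 groups of >= 2).
#' @param n_permutations number of label permutations.
#' @param seed integer seed for the permutations.
#' @return object of class `permutation_test`: list with `statistic`,
#'   `p_value`, `n_permutations`, `null_quantiles`, `method`.
#' @export
anosim_test <- function(D, groups, n_permutations = 999, seed = 1) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 members each")
  }
  px <- .pair_index(n)
  r <- rank(D[cbind(px$i, px$j)])  # midranks
  M <- length(r)
  stat_for <- function(g) {
    within <- g[px$i] == g[px$j]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  obs <- stat_for(groups)
  set.seed(stage_seed(seed, "permutation"))
  null <- vapply(seq_len(n_permutations), function(k) {
    stat_for(groups[sample.int(n)])
  }, 0)
  structure(list(statistic = obs,
                 p_value = (1 + sum(null >= obs)) / (1 + n_permutations),
                 n_permutations = n_permutations,
                 null_quantiles = quantile(null, c(0.5, 0.9, 0.95, 0.99)),
                 method = "ANOSIM"),
            class = "permutation_test")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle vectors; the null
#' permutes rows and columns of the second matrix simultaneously. One-sided
#' (greater) p-value with the `(1 + k) / (1 + N)` convention.
#'
#' @param D1,D2 symmetric matrices with matching labels (n >= 4).
#' @param n_permutations number of permutations.
#' @param seed integer seed.
#' @return a `permutation_test` object (statistic = Pearson r).
#' @export
mantel_test <- function(D1, D2, n_permutations = 999, seed = 1) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  stopifnot(nrow(D1) >= 4, all(dim(D1) == dim(D2)))
  if (!is.null(rownames(D1)) && !is.null(rownames(D2))) {
    stopifnot(identical(rownames(D1), rownames(D2)))
  }
  n <- nrow(D1)
  px <- .pair_index(n)
  v1 <- D1[cbind(px$i, px$j)]
  if (sd(v1) == 0) stop("zero-variance lower triangle in D1: r undefined")
  v1s <- (v1 - mean(v1)) / sd(v1)
  take <- function(perm) D2[cbind(perm[px$i], perm[px$j])]
  corr <- function(v2) {
    if (sd(v2) == 0) return(NA_real_)
    mean(v1s * (v2 - mean(v2)) / sd(v2)) * length(v1) / (length(v1) - 1)
  }
  obs <- corr(take(seq_len(n)))
  if (is.na(obs)) stop("zero-variance lower triangle in D2: r undefined")
  set.seed(stage_seed(seed, "permutation"))
  null <- vapply(seq_len(n_permutations), function(k) {
    corr(take(sample.int(n)))
  }, 0)
  structure(list(statistic = obs,
                 p_value = (1 + sum(null >= obs, na.rm = TRUE)) /
                   (1 + n_permutations),
                 n_permutations = n_permutations,
                 null_quantiles = quantile(null, c(0.5, 0.9, 0.95, 0.99),
                                           na.rm = TRUE),
                 method = "Mantel"),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(x$method, "statistic:", round(x$statistic, 4),
      " p =", x$p_value, "(", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' Richness per basin and comparison between the two sides of the divide
#'
#' Per-basin richness (ASV or highest-taxon level), per-side mean, SD and
#' side-total richness, and a two-sided Wilcoxon rank-sum test between the
#' sides (exact for small tie-free samples, normal approximation with
#' continuity correction otherwise).
#'
#' @param community a `community_matrix` with side labels.
#' @param level `"asv"` or `"taxon"`.
#' @param taxonomy required for `level = "taxon"`.
#' @return list with `per_basin` (data frame), `per_side` (data frame:
#'   side, n_basins, mean, sd, side_total), `wilcoxon` (htest).
#' @export
richness_by_side <- function(community, level = c("asv", "taxon"),
                             taxonomy = NULL) {
  level <- match.arg(level)
  if (level == "taxon") {
    stopifnot(!is.null(taxonomy))
    community <- collapse_to_taxa(community, taxonomy)
  }
  side <- community$side_of_divide
  if (length(unique(side)) < 2) stop("need basins on both sides")
  rich <- rowSums(community$presence)
  per_basin <- data.frame(basin_id = names(rich), side = side[names(rich)],
                          richness = as.integer(rich),
                          stringsAsFactors = FALSE)
  per_side <- do.call(rbind, lapply(sort(unique(side)), function(s) {
    b <- names(side)[side == s]
    data.frame(side = s, n_basins = length(b), mean = mean(rich[b]),
               sd = sd(rich[b]),
               side_total = sum(colSums(community$presence[b, , drop = FALSE]) > 0),
               stringsAsFactors = FALSE)
  }))
  sides <- sort(unique(side))
  w <- suppressWarnings(
    wilcox.test(rich[names(side)[side == sides[1]]],
                rich[names(side)[side == sides[2]]],
                alternative = "two.sided", correct = TRUE))
  list(per_basin = per_basin, per_side = per_side, wilcoxon = w)
}
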