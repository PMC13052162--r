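# DNA <-> integer encoding shared with the C++ aligner:
# A=0 C=1 G=2 T=3 gap=4 other/ambiguous=5
.encode_seq <- function(s) {
  chars <- strsplit(toupper(s), "")[[1]]
  code <- match(chars, c("A", "C", "G", "T", "-"))
  code[is.na(code)] <- 6L
  code - 1L
}

.encode_profile <- function(sequences) {
  rows <- lapply(sequences, .encode_seq)
  len <- unique(lengths(rows))
  stopifnot(length(len) == 1)
  matrix(unlist(rows), nrow = length(rows), byrow = TRUE)
}

.decode_profile <- function(prof, originals = NULL) {
  alpha <- c("A", "C", "G", "T", "-", "N")
  apply(prof, 1, function(r) paste(alpha[r + 1L], collapse = ""))
}

# global pairwise alignment of two single sequences; returns the C++
# traceback (idxA/idxB: source positions, 0 = gap)
.pairwise_align <- function(a, b) {
  .cpp_profile_align(matrix(.encode_seq(a), nrow = 1),
                     matrix(.encode_seq(b), nrow = 1))
}

# merge two encoded profiles along an alignment traceback
.merge_profiles <- function(pa, pb, aln) {
  L <- length(aln$idxA)
  out <- matrix(4L, nrow = nrow(pa) + nrow(pb), ncol = L)
  ka <- aln$idxA > 0
  out[seq_len(nrow(pa)), ka] <- pa[, aln$idxA[ka], drop = FALSE]
  kb <- aln$idxB > 0
  out[nrow(pa) + seq_len(nrow(pb)), kb] <- pb[, aln$idxB[kb], drop = FALSE]
  out
}

#' Progressive multiple alignment of a species' ASV sequences
#'
#' Pairwise mismatch distances feed a neighbour-joining guide tree; profiles
#' are then merged post-order with an affine-gap profile aligner (match +1,
#' mismatch -1, gap open -5, gap extend -1). Equal-length inputs differing
#' only by substitutions return the gap-free identity alignment.
#'
#' @param sequences named character vector of DNA sequences (>= 1; a single
#'   sequence returns itself with a warning).
#' @param species_name label carried on the result.
#' @return object of class `species_alignment`: list with `species_name`,
#'   `asv_ids`, `aligned` (named, equal-length rows over A/C/G/T/-/N).
#' @export
align_species <- function(sequences, species_name = NA_character_) {
  n <- length(sequences)
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  if (n == 1) {
    warning("single sequence: identity alignment returned")
    return(structure(list(species_name = species_name, asv_ids = ids,
                          aligned = setNames(unname(sequences), ids)),
                     class = "species_alignment"))
  }

  # guide distances: Hamming for equal lengths, else pairwise alignment
  lens <- nchar(sequences)
  if (length(unique(lens)) == 1) {
    prof <- .encode_profile(sequences)
    mm <- .cpp_mismatch_pairs(prof)
    D <- mm * lower.tri(mm)
    D <- D + t(D)
  } else {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      aln <- .pairwise_align(sequences[[i]], sequences[[j]])
      merged <- .merge_profiles(matrix(.encode_seq(sequences[[i]]), 1),
                                matrix(.encode_seq(sequences[[j]]), 1), aln)
      D[i, j] <- D[j, i] <- .cpp_mismatch_pairs(merged)[2, 1]
    }
  }
  dimnames(D) <- list(ids, ids)

  merge_order <- .guide_merge_order(D)

  profiles <- lapply(sequences, function(s) matrix(.encode_seq(s), nrow = 1))
  members <- as.list(seq_len(n))
  for (pair in merge_order) {
    a <- pair[1]; b <- pair[2]
    aln <- .cpp_profile_align(profiles[[a]], profiles[[b]])
    profiles[[a]] <- .merge_profiles(profiles[[a]], profiles[[b]], aln)
    members[[a]] <- c(members[[a]], members[[b]])
    profiles[b] <- list(NULL)   # keep slot so live indices stay stable
    members[b] <- list(NULL)
  }
  live <- which(!vapply(profiles, is.null, TRUE))[1]
  ord <- order(members[[live]])
  aligned <- .decode_profile(profiles[[live]][ord, , drop = FALSE])
  structure(list(species_name = species_name, asv_ids = ids,
                 aligned = setNames(aligned, ids)),
            class = "species_alignment")
}

# merge schedule from a neighbour-joining guide tree (fallback to
# agglomerative average linkage when NJ is not applicable, n < 4)
.guide_merge_order <- function(D) {
  n <- nrow(D)
  if (n == 2) return(list(c(1L, 2L)))
  tree <- NULL
  if (n >= 4) {
    tree <- tryCatch(ape::nj(stats::as.dist(D)), error = function(e) NULL)
  }
  if (is.null(tree)) {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    ord <- list()
    rep_of <- seq_len(n)   # cluster -> representative live profile index
    for (step in seq_len(n - 1)) {
      m <- hc$merge[step, ]
      left <- if (m[1] < 0) -m[1] else rep_of[n + m[1]]
      right <- if (m[2] < 0) -m[2] else rep_of[n + m[2]]
      ord[[step]] <- c(left, right)
      rep_of[n + step] <- left
    }
    return(ord)
  }
  # post-order walk of the rooted NJ tree, merging children sequentially
  tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  tip_idx <- match(tree$tip.label, rownames(D))
  edge <- tree$edge
  children <- split(edge[, 2], edge[, 1])
  ord <- list()
  rep_of <- integer(max(edge))
  rep_of[seq_len(n)] <- tip_idx
  walk <- function(node) {
    if (node <= n) return(rep_of[node])
    reps <- vapply(children[[as.character(node)]], walk, 0L)
    acc <- reps[1]
    for (r in reps[-1]) {
      ord[[length(ord) + 1L]] <<- c(acc, r)
    }
    rep_of[node] <<- acc
    acc
  }
  walk(n + 1L)
  ord
}
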