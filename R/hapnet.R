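#' Build a haplotype network (minimum spanning tree, infinite sites)
#'
#' Collapses identical sequences into haplotypes with frequencies and
#' side-of-divide composition, connects them by pairwise mismatch counts
#' (mutational steps), and extracts a minimum spanning tree with Kruskal's
#' algorithm (ties broken lexicographically on haplotype ids, so networks
#' are reproducible). Non-tree edges that could replace a tree edge at
#' equal cost — their weight equals the maximum edge weight on the tree
#' path between their endpoints — are recorded as alternative
#' configurations.
#'
#' When external reference haplotypes are supplied, all sequences are
#' aligned and trimmed to the fully overlapping region (columns where every
#' sequence has a base) before collapsing, mirroring the common practice of
#' trimming ASVs to the overlap with published haplotypes.
#'
#' @param sequences named character vector of DNA sequences.
#' @param side named character vector: sequence name -> side label (used
#'   for the per-haplotype composition counts; optional).
#' @param external_haplotypes optional named character vector of reference
#'   haplotypes to incorporate.
#' @param trim_to_overlap trim the alignment to complete columns; must be
#'   `TRUE` whenever external haplotypes are supplied.
#' @return object of class `haplotype_network`: list with `haplotypes`
#'   (data frame: hap_id, sequence, frequency, per-side counts, members) and
#'   `edges` (data frame: from, to, steps, is_alternative).
#' @export
build_haplotype_network <- function(sequences, side = NULL,
                                    external_haplotypes = NULL,
                                    trim_to_overlap = !is.null(external_haplotypes)) {
  if (!is.null(external_haplotypes) && !trim_to_overlap) {
    stop("external haplotypes require trim_to_overlap = TRUE")
  }
  all_seq <- c(sequences, external_haplotypes)
  if (is.null(names(all_seq))) names(all_seq) <- paste0("seq", seq_along(all_seq))

  if (length(unique(nchar(all_seq))) > 1 || trim_to_overlap) {
    aln <- align_species(all_seq)$aligned
    if (trim_to_overlap) {
      cols <- do.call(rbind, strsplit(aln, ""))
      keep <- colSums(cols == "-" | cols == "N") == 0
      if (!any(keep)) stop("zero-length overlap between sequences")
      aln <- apply(cols[, keep, drop = FALSE], 1, paste, collapse = "")
      names(aln) <- names(all_seq)
    }
    all_seq <- aln
  }

  # collapse identical sequences into haplotypes
  uniq <- unique(unname(all_seq))
  hap_ids <- sprintf("H%02d", seq_along(uniq))
  member_of <- hap_ids[match(all_seq, uniq)]
  haps <- data.frame(hap_id = hap_ids, sequence = uniq,
                     frequency = as.integer(table(member_of)[hap_ids]),
                     stringsAsFactors = FALSE)
  haps$members <- vapply(hap_ids, function(h) {
    paste(names(all_seq)[member_of == h], collapse = ",")
  }, "")
  if (!is.null(side)) {
    for (s in sort(unique(stats::na.omit(side)))) {
      haps[[paste0("n_", s)]] <- vapply(hap_ids, function(h) {
        sum(side[names(all_seq)[member_of == h]] == s, na.rm = TRUE)
      }, 0L)
    }
  }

  n <- length(uniq)
  if (n == 1) {
    return(structure(list(haplotypes = haps,
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             steps = numeric(0),
                                             is_alternative = logical(0))),
                     class = "haplotype_network"))
  }
  prof <- .encode_profile(setNames(uniq, hap_ids))
  mmu <- .cpp_mismatch_pairs(prof)
  steps <- mmu * lower.tri(mmu); steps <- steps + t(steps)
  dimnames(steps) <- list(hap_ids, hap_ids)

  # Kruskal MST, ties broken lexicographically on (from, to)
  pairs <- which(lower.tri(steps), arr.ind = TRUE)
  cand <- data.frame(from = hap_ids[pairs[, 2]], to = hap_ids[pairs[, 1]],
                     steps = steps[pairs], stringsAsFactors = FALSE)
  cand <- cand[order(cand$steps, cand$from, cand$to), ]
  parent <- seq_len(n); names(parent) <- hap_ids
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  in_tree <- logical(nrow(cand))
  for (e in seq_len(nrow(cand))) {
    ra <- find(match(cand$from[e], hap_ids))
    rb <- find(match(cand$to[e], hap_ids))
    if (ra != rb) { parent[ra] <- rb; in_tree[e] <- TRUE }
  }
  tree <- cand[in_tree, , drop = FALSE]

  # alternative edges: weight equals the bottleneck (max edge) on the tree
  # path between the endpoints
  g <- igraph::graph_from_data_frame(tree[, c("from", "to")], directed = FALSE,
                                     vertices = hap_ids)
  igraph::E(g)$steps <- tree$steps
  alt <- cand[!in_tree, , drop = FALSE]
  if (nrow(alt)) {
    is_alt <- vapply(seq_len(nrow(alt)), function(e) {
      p <- igraph::shortest_paths(g, alt$from[e], alt$to[e],
                                  output = "epath")$epath[[1]]
      alt$steps[e] <= max(igraph::E(g)$steps[as.integer(p)])
    }, TRUE)
    alt <- alt[is_alt, , drop = FALSE]
  }
  edges <- rbind(cbind(tree, is_alternative = FALSE),
                 if (nrow(alt)) cbind(alt, is_alternative = TRUE))
  rownames(edges) <- NULL
  structure(list(haplotypes = haps, edges = edges),
            class = "haplotype_network")
}
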