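# Independent reference implementations used as oracles. These deliberately
# use naive loops / third-party code paths distinct from the package's own.

# betaMPD by explicit double loop over cross pairs
oracle_betampd <- function(presence, D) {
  basins <- rownames(presence)
  out <- matrix(NA_real_, length(basins), length(basins),
                dimnames = list(basins, basins))
  diag(out) <- 0
  for (i in seq_along(basins)) for (j in seq_along(basins)) {
    if (i == j) next
    a <- colnames(presence)[presence[i, ]]
    b <- colnames(presence)[presence[j, ]]
    if (!length(a) || !length(b)) next
    tot <- 0; k <- 0
    for (x in a) for (y in b) { tot <- tot + D[x, y]; k <- k + 1 }
    out[i, j] <- tot / k
  }
  out
}

# textbook Dijkstra over an 8-neighbour conductance raster
oracle_cost_matrix <- function(cond, cell_km, src) {
  nr <- nrow(cond); nc <- ncol(cond); n <- nr * nc
  nbr <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
              c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  out <- matrix(0, length(src), length(src))
  for (s in seq_along(src)) {
    dist <- rep(Inf, n); dist[src[s]] <- 0
    done <- rep(FALSE, n)
    for (iter in seq_len(n)) {
      cand <- ifelse(done, Inf, dist)
      u <- which.min(cand)
      if (!is.finite(cand[u])) break
      done[u] <- TRUE
      ur <- (u - 1) %% nr + 1; uc <- (u - 1) %/% nr + 1
      for (d in nbr) {
        vr <- ur + d[1]; vc <- uc + d[2]
        if (vr >= 1 && vr <= nr && vc >= 1 && vc <= nc) {
          v <- (vc - 1) * nr + vr
          if (!done[v]) {
            w <- cell_km * (if (d[1] != 0 && d[2] != 0) sqrt(2) else 1) /
              ((cond[u] + cond[v]) / 2)
            if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
          }
        }
      }
    }
    out[s, ] <- dist[src]
  }
  out
}

# Hamming distance between equal-length strings
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# total MST weight via igraph on the complete mismatch graph
oracle_mst_weight <- function(seqs) {
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- oracle_hamming(seqs[i], seqs[j])
  }
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # make zero-weight edges representable (igraph drops 0 entries)
  g2 <- igraph::graph_from_adjacency_matrix(D + 1, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  sum(igraph::E(igraph::mst(g2))$weight) - (n - 1)
}

# random dissimilarity matrix with labels
random_dist_matrix <- function(n, labels = sprintf("b%02d", seq_len(n))) {
  pts <- matrix(rnorm(n * 3), n)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(labels, labels)
  m
}

# small community matrix built directly
make_community <- function(presence, side = NULL) {
  if (is.null(side)) {
    side <- setNames(rep(c("ligurian", "adriatic"),
                         length.out = nrow(presence)), rownames(presence))
  }
  structure(list(presence = presence, side_of_divide = side),
            class = "community_matrix")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  }, "")
}
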