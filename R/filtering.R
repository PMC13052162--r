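#' Construct a read matrix
#'
#' The raw input to filtering: samples x ASVs non-negative integer read
#' counts with per-sample negative-control flags.
#'
#' @param counts integer matrix, samples as rows, ASVs as columns, with
#'   dimnames.
#' @param is_control named logical vector over the samples.
#' @return object of class `read_matrix`.
#' @export
read_matrix <- function(counts, is_control) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            !is.null(rownames(counts)),
            ncol(counts) == 0 || !is.null(colnames(counts)),
            !anyDuplicated(rownames(counts)), !anyDuplicated(colnames(counts)))
  is_control <- is_control[rownames(counts)]
  stopifnot(!any(is.na(is_control)), any(!is_control))
  structure(list(counts = counts, is_control = is_control),
            class = "read_matrix")
}

#' @export
print.read_matrix <- function(x, ...) {
  cat("read_matrix:", nrow(x$counts), "samples (",
      sum(x$is_control), "controls ) x", ncol(x$counts), "ASVs\n")
  invisible(x)
}

#' Subtract negative-control reads per ASV
#'
#' For each ASV, the total read count observed across negative controls is
#' subtracted from that ASV's count in every other sample (per-ASV, not
#' globally); negative results clip to zero. Control rows are dropped from
#' the output.
#'
#' @param matrix a [read_matrix()] with at least one control sample.
#' @return a [read_matrix()] without control samples.
#' @export
subtract_control_reads <- function(matrix) {
  stopifnot(inherits(matrix, "read_matrix"))
  if (!any(matrix$is_control)) stop("no control samples present")
  ctrl_total <- colSums(matrix$counts[matrix$is_control, , drop = FALSE])
  out <- matrix$counts[!matrix$is_control, , drop = FALSE]
  out <- pmax(sweep(out, 2, ctrl_total, "-"), 0)
  read_matrix(out, matrix$is_control[!matrix$is_control])
}

#' Drop ASVs failing occurrence and total-read thresholds
#'
#' Removes ASVs detected in fewer than `min_samples` samples or carrying
#' fewer than `min_total_reads` reads overall. Applied after contamination
#' subtraction, so occurrence reflects cleaned counts.
#'
#' @param matrix a [read_matrix()] (controls already removed or retained —
#'   controls are ignored for both criteria).
#' @param min_samples minimum number of samples with nonzero count.
#' @param min_total_reads minimum summed reads.
#' @return filtered [read_matrix()], column order preserved.
#' @export
filter_occurrence_and_reads <- function(matrix, min_samples = 2,
                                        min_total_reads = 10) {
  stopifnot(inherits(matrix, "read_matrix"))
  cnt <- matrix$counts[!matrix$is_control, , drop = FALSE]
  keep <- colSums(cnt > 0) >= min_samples & colSums(cnt) >= min_total_reads
  if (!any(keep)) warning("no ASVs survive the occurrence/read filters")
  read_matrix(matrix$counts[, keep, drop = FALSE], matrix$is_control)
}

#' Screen an ASV sequence for NUMT-diagnostic stop codons
#'
#' Translates the sequence with the vertebrate mitochondrial genetic code
#' and flags it as a putative NUMT (nuclear mitochondrial pseudogene) if any
#' in-frame stop codon appears. Two framing modes: `"fixed-trim-15"`
#' removes the first 15 bases of the 5' end and translates the remainder
#' (truncating a trailing partial codon); `"alignment-frame"` determines the
#' codon phase from a global alignment to an in-frame reference CDS.
#' Codons containing IUPAC ambiguity codes are left untranslated and never
#' count as stops.
#'
#' @param sequences character vector of ASV DNA sequences (named by ASV id).
#' @param reference_cds in-frame protein-coding reference sequence
#'   (required for `"alignment-frame"`).
#' @param mode framing mode.
#' @return logical vector `numt` (TRUE = stop codon found); sequences
#'   shorter than 18 bases are `NA` (unscreenable, treated as removed).
#' @export
screen_numts <- function(sequences, reference_cds = NULL,
                         mode = c("alignment-frame", "fixed-trim-15")) {
  mode <- match.arg(mode)
  if (mode == "alignment-frame" && is.null(reference_cds)) {
    stop("alignment-frame mode requires a reference CDS")
  }
  vapply(sequences, function(s) {
    if (nchar(s) < 18) return(NA)
    if (mode == "fixed-trim-15") {
      offset <- 15L
    } else {
      aln <- .pairwise_align(reference_cds, s)
      # reference position aligned to the ASV's first base -> codon phase
      first <- which(aln$idxB > 0 & aln$idxA > 0)[1]
      if (is.na(first)) return(NA)
      ref_pos <- aln$idxA[first]
      asv_pos <- aln$idxB[first]
      phase <- (ref_pos - 1L) %% 3L
      offset <- (asv_pos - 1L) + ((3L - phase) %% 3L)
    }
    has_stop_codon(s, offset)
  }, TRUE)
}

# split "Class;Order;Family;Genus;Species" rank paths into a matrix
.split_taxa <- function(taxon_path) {
  parts <- strsplit(taxon_path, ";", fixed = TRUE)
  out <- t(vapply(parts, function(p) { length(p) <- 5L; p }, character(5)))
  colnames(out) <- c("class", "order", "family", "genus", "species")
  out[is.na(out)] <- ""
  out
}

#' Taxonomic retention filter
#'
#' Keeps ray-finned fishes (`keep_class`), drops the marine families of the
#' exclusion list (case-insensitive exact match on the family rank), and —
#' for taxon-level analyses — optionally drops records without an
#' assignment at family rank or deeper.
#'
#' @param taxonomy data frame with columns `asv_id`, `taxon_path`
#'   (`Class;Order;Family;Genus;Species`), `confidence`.
#' @param keep_class class to retain.
#' @param excluded_families family-level exclusion list.
#' @param require_at_least `"family"` to drop records with no family-level
#'   assignment, or `NA` to keep them.
#' @return the taxonomy rows retained, with logical columns `marine` and
#'   `below_family` added.
#' @export
filter_taxa <- function(taxonomy, keep_class = "Actinopterygii",
                        excluded_families = marine_families,
                        require_at_least = NA) {
  ranks <- .split_taxa(taxonomy$taxon_path)
  taxonomy$marine <- tolower(ranks[, "family"]) %in% tolower(excluded_families)
  taxonomy$below_family <- ranks[, "family"] == ""
  keep <- ranks[, "class"] == keep_class & !taxonomy$marine
  if (identical(require_at_least, "family")) keep <- keep & !taxonomy$below_family
  unknown <- ranks[, "class"] == ""
  if (any(unknown & keep)) {
    warning(sum(unknown & keep), " records with unknown class passed through")
  }
  taxonomy[keep, , drop = FALSE]
}

#' Pool sample-level occurrences to basin presence/absence
#'
#' An ASV is present in a basin iff any sample of that basin carries a
#' nonzero count; read counts are not propagated (all downstream analyses
#' are occurrence-based). All-zero ASV columns are dropped.
#'
#' @param matrix a [read_matrix()] (controls ignored).
#' @param metadata data frame mapping `sample_id` to `basin_id` and `side`.
#' @return object of class `community_matrix`: list with logical `presence`
#'   (basins x ASVs) and named character `side_of_divide`.
#' @export
pool_to_basins <- function(matrix, metadata) {
  stopifnot(inherits(matrix, "read_matrix"))
  cnt <- matrix$counts[!matrix$is_control, , drop = FALSE]
  m <- metadata[match(rownames(cnt), metadata$sample_id), ]
  if (any(is.na(m$basin_id))) {
    stop("samples with unknown basin: ",
         paste(rownames(cnt)[is.na(m$basin_id)], collapse = ", "))
  }
  basins <- unique(m$basin_id)
  pres <- t(vapply(basins, function(b) {
    colSums(cnt[m$basin_id == b, , drop = FALSE] > 0) > 0
  }, logical(ncol(cnt))))
  dimnames(pres) <- list(basins, colnames(cnt))
  pres <- pres[, colSums(pres) > 0, drop = FALSE]
  side <- setNames(m$side[match(basins, m$basin_id)], basins)
  structure(list(presence = pres, side_of_divide = side),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community_matrix:", nrow(x$presence), "basins x", ncol(x$presence),
      "ASVs\n")
  invisible(x)
}

#' Run the full post-denoising filter chain
#'
#' Applies, in order: taxonomic retention (class + marine exclusion),
#' negative-control contamination subtraction, the occurrence (>= 2
#' samples) and total-read (>= 10) thresholds, the stop-codon NUMT screen,
#' and basin pooling. The chain is idempotent.
#'
#' @param reads a [read_matrix()].
#' @param sequences named character vector of ASV sequences.
#' @param taxonomy taxonomy data frame (see [filter_taxa()]).
#' @param metadata sample metadata (see [pool_to_basins()]).
#' @param reference_cds in-frame reference for `"alignment-frame"` NUMT
#'   screening; when `NULL` the fixed 15-bp trim is used.
#' @param min_samples,min_total_reads occurrence/read thresholds.
#' @param numt_mode framing mode passed to [screen_numts()].
#' @return list with `community` ([pool_to_basins()] result), `reads`
#'   (filtered [read_matrix()]), `survivors` (ASV ids), and `report` (data
#'   frame: asv_id, step_removed, reason).
#' @export
filter_asvs <- function(reads, sequences, taxonomy, metadata,
                        reference_cds = NULL, min_samples = 2,
                        min_total_reads = 10,
                        numt_mode = c("alignment-frame", "fixed-trim-15")) {
  numt_mode <- match.arg(numt_mode)
  if (is.null(reference_cds)) numt_mode <- "fixed-trim-15"
  report <- list()
  note <- function(ids, step, reason) {
    if (length(ids)) {
      report[[length(report) + 1L]] <<- data.frame(
        asv_id = ids, step_removed = step, reason = reason,
        stringsAsFactors = FALSE)
    }
  }

  # 1. taxonomic retention + marine exclusion
  tax_kept <- filter_taxa(taxonomy)
  removed <- setdiff(colnames(reads$counts), tax_kept$asv_id)
  ranks <- .split_taxa(taxonomy$taxon_path)
  is_marine <- setNames(tolower(ranks[, "family"]) %in% tolower(marine_families),
                        taxonomy$asv_id)
  note(removed[is_marine[removed]], "taxa", "marine family")
  note(removed[!is_marine[removed]], "taxa", "not Actinopterygii")
  m <- read_matrix(reads$counts[, intersect(colnames(reads$counts),
                                            tax_kept$asv_id), drop = FALSE],
                   reads$is_control)

  # 2. contamination subtraction (controls dropped afterwards)
  m <- if (any(m$is_control)) subtract_control_reads(m) else m

  # 3. occurrence / total-read thresholds
  before <- colnames(m$counts)
  m <- suppressWarnings(
    filter_occurrence_and_reads(m, min_samples, min_total_reads))
  note(setdiff(before, colnames(m$counts)), "occurrence_reads",
       sprintf("<%d samples or <%d reads", min_samples, min_total_reads))

  # 4. stop-codon (NUMT) screen
  numt <- screen_numts(sequences[colnames(m$counts)], reference_cds, numt_mode)
  note(colnames(m$counts)[is.na(numt)], "numt", "unscreenable (<18 bp)")
  note(colnames(m$counts)[!is.na(numt) & numt], "numt", "in-frame stop codon")
  keep <- !is.na(numt) & !numt
  m <- read_matrix(m$counts[, keep, drop = FALSE], m$is_control)

  community <- pool_to_basins(m, metadata)
  report <- if (length(report)) {
    do.call(rbind, report)
  } else {
    data.frame(asv_id = character(0), step_removed = character(0),
               reason = character(0))
  }
  list(community = community, reads = m, survivors = colnames(m$counts),
       report = report)
}
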