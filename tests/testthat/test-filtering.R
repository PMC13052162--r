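mk_reads <- function(counts, controls) {
  read_matrix(counts, setNames(rownames(counts) %in% controls,
                               rownames(counts)))
}

test_that("control subtraction is per-ASV with clipping at zero", {
  cnt <- rbind(s1 = c(a = 12L, b = 7L, c = 0L),
               s2 = c(a = 3L, b = 1L, c = 5L),
               neg = c(a = 5L, b = 0L, c = 2L))
  out <- subtract_control_reads(mk_reads(cnt, "neg"))
  expect_equal(out$counts["s1", ], c(a = 7, b = 7, c = 0))   # b untouched: c=0
  expect_equal(out$counts["s2", ], c(a = 0, b = 1, c = 3))   # a clips to 0
  expect_false("neg" %in% rownames(out$counts))
})

test_that("subtraction over multiple controls equals a brute-force loop", {
  set.seed(31)
  for (rep in 1:5) {
    cnt <- matrix(rpois(20 * 30, 4), 20, 30,
                  dimnames = list(sprintf("s%02d", 1:20),
                                  sprintf("a%02d", 1:30)))
    controls <- sprintf("s%02d", 1:3)
    out <- subtract_control_reads(mk_reads(cnt, controls))
    expected <- cnt[-(1:3), ]
    for (i in seq_len(nrow(expected))) for (j in seq_len(ncol(expected))) {
      expected[i, j] <- max(0, cnt[i + 3, j] - sum(cnt[1:3, j]))
    }
    expect_equal(out$counts, expected)
  }
})

test_that("occurrence and total-read rules drop the right ASVs", {
  cnt <- rbind(s1 = c(single = 1000L, low = 4L, ok = 6L),
               s2 = c(single = 0L, low = 3L, ok = 6L),
               s3 = c(single = 0L, low = 2L, ok = 0L))
  out <- filter_occurrence_and_reads(mk_reads(cnt, character(0)))
  expect_equal(colnames(out$counts), "ok")  # 1000 reads in 1 sample dropped,
                                            # 9 reads over 3 samples dropped
  expect_warning(
    empty <- filter_occurrence_and_reads(mk_reads(cnt[, "single", drop = FALSE],
                                                  character(0))),
    "no ASVs survive")
  expect_equal(ncol(empty$counts), 0)
})

test_that("stop-codon screen flags NUMTs in both framing modes", {
  keep <- paste0(strrep("C", 15), "ATGTTTAAACGACTG")
  numt <- paste0(strrep("C", 15), "ATGTAGTTTCGACTG")
  expect_false(screen_numts(keep, mode = "fixed-trim-15"))
  expect_true(screen_numts(numt, mode = "fixed-trim-15"))
  expect_true(is.na(screen_numts("ACGTACGTACGT", mode = "fixed-trim-15")))
  # alignment-frame mode recovers the phase from an in-frame reference even
  # when the ASV starts mid-codon
  ref <- random_coding_sequence(300, 0)
  asv_inframe <- substr(ref, 31, 150)
  asv_shift <- substr(ref, 32, 150)   # starts at codon phase 1
  expect_false(screen_numts(asv_inframe, ref, mode = "alignment-frame"))
  expect_false(screen_numts(asv_shift, ref, mode = "alignment-frame"))
  broken <- asv_shift
  substr(broken, 12, 14) <- "TAA"     # in-frame stop given the phase
  expect_true(screen_numts(broken, ref, mode = "alignment-frame"))
})

test_that("taxon filter applies class, marine and family-level rules", {
  tax <- data.frame(
    asv_id = c("a", "b", "c", "d"),
    taxon_path = c("Mammalia;Rodentia;Muridae;Mus;Mus musculus",
                   "Actinopterygii;Mugiliformes;Mugilidae;;",
                   "Actinopterygii;Cypriniformes;Leuciscidae;Telestes;T. muticellus",
                   "Actinopterygii;;;;"),
    confidence = 90)
  kept <- filter_taxa(tax)
  expect_setequal(kept$asv_id, c("c", "d"))
  kept_fam <- filter_taxa(tax, require_at_least = "family")
  expect_equal(kept_fam$asv_id, "c")
  # case-insensitive family match
  tax$taxon_path[2] <- "Actinopterygii;Mugiliformes;MUGILIDAE;;"
  expect_false("b" %in% filter_taxa(tax)$asv_id)
})

test_that("basin pooling uses any-nonzero presence and drops empty columns", {
  cnt <- rbind(s1 = c(a = 0L, b = 2L, c = 0L),
               s2 = c(a = 7L, b = 0L, c = 0L),
               s3 = c(a = 0L, b = 0L, c = 0L))
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     basin_id = c("B1", "B1", "B2"),
                     side = c("ligurian", "ligurian", "adriatic"))
  comm <- pool_to_basins(mk_reads(cnt, character(0)), meta)
  expect_true(comm$presence["B1", "a"])   # (0, 7) -> present
  expect_false("c" %in% colnames(comm$presence))
  meta$basin_id[3] <- NA
  expect_error(pool_to_basins(mk_reads(cnt, character(0)), meta),
               "unknown basin")
})

test_that("the filter chain is idempotent and monotone", {
  ds <- synthesize_dataset(riverscape_scenario(n_basins_per_side = 3, seed = 6),
                           seed = 6)
  f1 <- filter_asvs(ds$reads, ds$sequences, ds$taxonomy, ds$metadata)
  f2 <- filter_asvs(f1$reads, ds$sequences, ds$taxonomy, ds$metadata)
  expect_identical(f1$survivors, f2$survivors)
  expect_identical(f1$community$presence, f2$community$presence)

  # adding reads to a surviving ASV never removes it
  boosted <- ds$reads$counts
  surv <- f1$survivors[1]
  boosted[which(!ds$reads$is_control)[1], surv] <-
    boosted[which(!ds$reads$is_control)[1], surv] + 1000L
  f3 <- filter_asvs(read_matrix(boosted, ds$reads$is_control),
                    ds$sequences, ds$taxonomy, ds$metadata)
  expect_true(surv %in% f3$survivors)

  # removing a control never removes an ASV
  keep_rows <- rownames(ds$reads$counts) != names(which(ds$reads$is_control))[1]
  f4 <- filter_asvs(read_matrix(ds$reads$counts[keep_rows, ],
                                ds$reads$is_control[keep_rows]),
                    ds$sequences, ds$taxonomy, ds$metadata)
  expect_true(all(f1$survivors %in% f4$survivors))
})
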