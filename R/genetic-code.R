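#' Vertebrate mitochondrial genetic code
#'
#' Translation utilities used by the stop-codon (NUMT) screen and by the
#' coding-sequence simulator. Under the vertebrate mitochondrial code the
#' stop codons are TAA, TAG, AGA and AGG; TGA encodes tryptophan and ATA
#' methionine (both stops/isoleucine in the standard code).
#'
#' @name vertebrate-mito-code
NULL

.vert_mito_stops <- c("TAA", "TAG", "AGA", "AGG")

.vert_mito_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16),
                   rep(bases, each = 4, times = 4),
                   rep(bases, times = 16))
  # standard code over (first, second, third) in TCAG order, third fastest
  aa <- unlist(strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", ""))
  tab <- setNames(aa, codons)
  tab["TGA"] <- "W"; tab["ATA"] <- "M"   # mito reassignments
  tab["AGA"] <- "*"; tab["AGG"] <- "*"
  tab
})

#' Translate DNA under the vertebrate mitochondrial code
#'
#' @param seq a single DNA string (characters beyond A/C/G/T are treated as
#'   ambiguous).
#' @param offset number of 5' bases to skip before the first codon.
#' @return character vector of amino acids, one per complete codon; codons
#'   containing an ambiguity code yield `"X"` (never a stop); a trailing
#'   partial codon is dropped.
#' @export
translate_vertmito <- function(seq, offset = 0) {
  stopifnot(length(seq) == 1, offset >= 0)
  s <- toupper(seq)
  s <- substr(s, offset + 1, nchar(s))
  n_codons <- nchar(s) %/% 3
  if (n_codons == 0) return(character(0))
  starts <- seq(1, by = 3, length.out = n_codons)
  codons <- substring(s, starts, starts + 2)
  aa <- .vert_mito_table[codons]
  aa[is.na(aa)] <- "X"   # ambiguity codes leave the codon untranslated
  unname(aa)
}

#' Does a reading frame contain a stop codon?
#'
#' @inheritParams translate_vertmito
#' @return `TRUE` if at least one in-frame stop codon (vertebrate
#'   mitochondrial code) occurs.
#' @export
has_stop_codon <- function(seq, offset = 0) {
  any(translate_vertmito(seq, offset) == "*")
}

# all sense (non-stop) codons of the vertebrate mito code
.sense_codons <- names(.vert_mito_table)[.vert_mito_table != "*"]
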