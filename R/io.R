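#' File input/output helpers
#'
#' Tab-separated tables, FASTA (via seqinr) and Esri ASCII grid rasters.
#' Rasters are stored as plain numeric matrices with attributes
#' `cellsize_km`, `xllcorner`, `yllcorner` so that all grids derived from
#' one riverscape stay co-registered.
#'
#' @name ednadivide-io
NULL

#' @rdname ednadivide-io
#' @param x data frame or matrix to write.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  if (is.matrix(x)) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = TRUE,
                col.names = NA)
  } else {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname ednadivide-io
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname ednadivide-io
#' @param sequences named character vector of DNA strings.
#' @export
write_fasta <- function(sequences, path) {
  seqinr::write.fasta(as.list(unname(sequences)), names = names(sequences),
                      file.out = path, nbchar = 80)
  invisible(path)
}

#' @rdname ednadivide-io
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  setNames(toupper(vapply(recs, as.character, "")), names(recs))
}

#' Write a raster as an Esri ASCII grid
#'
#' No installed package handles this plain-text format, so the six-line
#' header + row-major body is emitted directly.
#'
#' @param grid numeric matrix (row 1 = northernmost row).
#' @param path output file.
#' @param cellsize cell edge length (same units as the corner coordinates).
#' @param xll,yll lower-left corner coordinates.
#' @param nodata NODATA sentinel.
#' @export
write_ascii_grid <- function(grid, path, cellsize = attr(grid, "cellsize_km"),
                             xll = 0, yll = 0, nodata = -9999) {
  if (is.null(cellsize)) cellsize <- 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(grid)),
               paste("nrows", nrow(grid)),
               paste("xllcorner", xll),
               paste("yllcorner", yll),
               paste("cellsize", cellsize),
               paste("NODATA_value", nodata)), con)
  g <- grid
  g[is.na(g)] <- nodata
  write.table(format(g, trim = TRUE, scientific = FALSE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path file path.
#' @return numeric matrix with attributes `cellsize_km`, `xllcorner`,
#'   `yllcorner`; NODATA cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  hdr_lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr_lines), "\\s+")
  hdr <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                  tolower(vapply(kv, `[`, "", 1)))
  body <- scan(path, skip = 6, quiet = TRUE)
  g <- matrix(body, nrow = hdr[["nrows"]], ncol = hdr[["ncols"]], byrow = TRUE)
  if ("nodata_value" %in% names(hdr)) g[g == hdr[["nodata_value"]]] <- NA
  attr(g, "cellsize_km") <- hdr[["cellsize"]]
  attr(g, "xllcorner") <- hdr[["xllcorner"]]
  attr(g, "yllcorner") <- hdr[["yllcorner"]]
  g
}
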