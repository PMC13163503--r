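# Minimal ENVI-convention cube I/O: a flat binary file plus a text header
# (samples/lines/bands, band-sequential interleave, double precision,
# little endian, wavelength list). Enough to exchange cubes with the usual
# hyperspectral toolchains; no compression, no BIL/BIP.

#' Write a hypercube in ENVI convention
#'
#' Produces `<path>.img` (band-sequential doubles, little endian) and
#' `<path>.hdr`.
#'
#' @param cube A [hypercube].
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("kind = %s", cube$kind),
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, trim = TRUE), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".img"), "wb")
  on.exit(close(con))
  for (b in seq_len(d[3])) {
    # BSQ: within a band, samples vary fastest within each line
    writeBin(as.vector(t(cube$values[, , b])), con, size = 8L,
             endian = "little")
  }
  invisible(path)
}

#' Read an ENVI-convention hypercube
#'
#' Supports the subset written by [write_envi]: band-sequential doubles
#' (data type 5), byte order 0.
#'
#' @param path Path without extension (expects `.hdr` and `.img`).
#' @return A [hypercube].
#' @export
read_envi <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  get_field <- function(name) {
    ln <- grep(sprintf("^%s\\s*=", name), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  samples <- as.integer(get_field("samples"))
  lines <- as.integer(get_field("lines"))
  bands <- as.integer(get_field("bands"))
  if (get_field("interleave") != "bsq" || get_field("data type") != "5") {
    stop("only bsq interleave with data type 5 (double) is supported")
  }
  wl_raw <- paste(hdr[grep("wavelength", hdr)[1]:length(hdr)], collapse = " ")
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}.*", "", wl_raw), ",")[[1]])
  kind <- get_field("kind") %||% "intensity"
  con <- file(paste0(path, ".img"), "rb")
  on.exit(close(con))
  vals <- array(0, c(lines, samples, bands))
  for (b in seq_len(bands)) {
    slab <- readBin(con, "double", n = samples * lines, size = 8L,
                    endian = "little")
    vals[, , b] <- matrix(slab, lines, samples, byrow = TRUE)
  }
  hypercube(vals, wl, kind = kind)
}

#' Write a matrix (mask, map, height) as CSV
#'
#' Plain-text raster export: one row per image row, no headers. Logical
#' matrices are written as 0/1.
#'
#' @param m Matrix (numeric or logical).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  storage.mode(m) <- if (is.logical(m)) "integer" else "double"
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}
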