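#' Read and write BART-style CFL datasets
#'
#' A CFL dataset is a pair of files `<basename>.hdr` (ASCII: a
#' `# Dimensions` line followed by 16 space-separated sizes) and
#' `<basename>.cfl` (little-endian interleaved 32-bit float real/imaginary
#' pairs in column-major dimension order). Write-then-read round-trips are
#' bit-exact at single precision.
#'
#' @param basename Path without extension.
#' @param x Complex array (any shape up to 16 dimensions) or vector.
#' @return `readCfl()` returns a complex array with the trailing singleton
#'   dimensions dropped (minimum 1 dimension); `writeCfl()` returns
#'   `basename` invisibly.
#' @export
writeCfl <- function(basename, x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (length(d) > 16L) stop("CFL supports at most 16 dimensions")
  dims <- c(d, rep(1L, 16L - length(d)))
  writeLines(c("# Dimensions", paste(dims, collapse = " ")),
             paste0(basename, ".hdr"))
  v <- as.complex(as.vector(x))
  buf <- as.single(rbind(Re(v), Im(v)))
  con <- file(paste0(basename, ".cfl"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(buf), con, size = 4L, endian = "little")
  invisible(basename)
}

#' @rdname writeCfl
#' @export
readCfl <- function(basename) {
  hdr <- paste0(basename, ".hdr")
  raw <- paste0(basename, ".cfl")
  if (!file.exists(hdr) || !file.exists(raw))
    stop(errorCondition(sprintf("CFL pair '%s' not found", basename),
                        class = c("enlivr_io_error", "error", "condition")))
  lines <- readLines(hdr, warn = FALSE)
  dimLine <- lines[which(grepl("^# Dimensions", lines)) + 1L]
  if (length(dimLine) != 1L || is.na(dimLine))
    stop(errorCondition(sprintf("malformed CFL header '%s'", hdr),
                        class = c("enlivr_format_error", "error", "condition")))
  dims <- as.integer(strsplit(trimws(dimLine), "\\s+")[[1]])
  n <- prod(dims)
  expected <- 8 * n
  if (file.info(raw)$size != expected)
    stop(errorCondition(sprintf(
      "CFL size mismatch: header implies %d bytes, file has %d",
      expected, file.info(raw)$size),
      class = c("enlivr_format_error", "error", "condition")))
  con <- file(raw, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = 2L * n, size = 4L, endian = "little")
  z <- complex(real = v[c(TRUE, FALSE)], imaginary = v[c(FALSE, TRUE)])
  keep <- max(c(1L, which(dims > 1L)))
  array(z, dim = dims[seq_len(max(keep, 1L))])
}

#' Export a magnitude image as NIfTI or PNG
#'
#' Thin convenience wrappers over the RNifti and png packages (Suggests).
#' PNG output is display-scaled to the image maximum.
#'
#' @param img Real 2D/3D array (e.g. a slot of [CombinedImage-class]).
#' @param file Output path.
#' @export
writeMagnitudeNifti <- function(img, file) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI export")
  arr <- array(as.numeric(img), dim = dim(img))
  RNifti::writeNifti(RNifti::asNifti(arr), file)
  invisible(file)
}

#' @rdname writeMagnitudeNifti
#' @export
writeMagnitudePng <- function(img, file) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for PNG export")
  m <- as.matrix(array(img, dim = dim(img)[1:2]))
  mx <- max(m)
  if (mx > 0) m <- m / mx
  png::writePNG(t(m)[rev(seq_len(ncol(m))), , drop = FALSE], file)
  invisible(file)
}
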