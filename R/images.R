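# Image containers and raster I/O.
#
# Images are plain numeric arrays on a nominal 0-255 scale: RGB images are
# H x W x 3 arrays, grayscale images H x W matrices. PNG and TIFF go through
# the png/tiff packages; PPM/PGM (the STARE container) has a built-in
# reader/writer supporting both ASCII (P2/P3) and binary (P5/P6) variants.

validate_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort_input("expected an H x W x 3 RGB array")
  }
  if (!all(is.finite(image))) abort_input("RGB image contains non-finite values")
  if (any(image < 0)) abort_input("RGB image contains negative intensities")
  invisible(image)
}

validate_gray <- function(image) {
  if (!is.matrix(image)) abort_input("expected an H x W grayscale matrix")
  if (!all(is.finite(image))) abort_input("grayscale image contains non-finite values")
  invisible(image)
}

#' Read a raster image as a 0-255 numeric array
#'
#' Supports PNG, TIFF and PPM/PGM. Grayscale files are returned as H x W
#' matrices, colour files as H x W x 3 arrays; any alpha channel is dropped.
#'
#' @param path Path to the image file.
#' @return Numeric matrix or array with intensities on the 0-255 scale.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort_io(paste0("no such image file: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path) * 255,
    ppm = ,
    pgm = read_pnm(path),
    abort_io(paste0("unsupported image format '.", ext,
                    "' (supported: png, tif/tiff, ppm/pgm): ", path))
  )
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 1) img <- img[, , 1]
    else if (dim(img)[3] > 3) img <- img[, , 1:3]
  }
  img
}

#' Write a 0-255 image to disk
#'
#' The format is chosen from the file extension (png, tif/tiff, ppm/pgm).
#'
#' @param image H x W matrix or H x W x 3 array on the 0-255 scale.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  scaled <- pmin(pmax(image / 255, 0), 1)
  switch(ext,
    png = png::writePNG(scaled, path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8),
    ppm = ,
    pgm = write_pnm(image, path),
    abort_io(paste0("unsupported output format: .", ext))
  )
  invisible(path)
}

# minimal netpbm reader (P2/P3 ASCII, P5/P6 binary, 8-bit)
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    abort_io(paste0("not an 8-bit PGM/PPM file: ", path))
  }
  vals <- integer(0)
  # read header tokens (width, height, maxval), skipping comments
  tokens <- character(0)
  buf <- character(0)
  while (length(tokens) < 3) {
    ch <- rawToChar(readBin(con, "raw", 1))
    if (length(ch) == 0 || ch == "") abort_io("truncated PNM header")
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1))
        if (ch %in% c("\n", "\r", "")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else {
      buf <- c(buf, ch)
    }
  }
  w <- as.integer(tokens[1])
  h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P2", "P3")) {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    as.integer(readBin(con, "raw", n))
  }
  if (length(vals) != n) abort_io(paste0("truncated PNM payload: ", path))
  vals <- vals * (255 / maxval)
  if (nch == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    # interleaved RGB triples, row-major
    a <- array(0, c(h, w, 3))
    m <- matrix(vals, nrow = 3)
    for (c in 1:3) a[, , c] <- matrix(m[c, ], nrow = h, ncol = w, byrow = TRUE)
    a
  }
}

write_pnm <- function(image, path) {
  img <- round(pmin(pmax(image, 0), 255))
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.matrix(img)) {
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
    write(t(img), con, ncolumns = 16)
  } else {
    writeLines(c("P3", paste(dim(img)[2], dim(img)[1]), "255"), con)
    inter <- rbind(as.vector(t(img[, , 1])), as.vector(t(img[, , 2])),
                   as.vector(t(img[, , 3])))
    write(inter, con, ncolumns = 15)
  }
  invisible(path)
}
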