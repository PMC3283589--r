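#' Read a 2D grayscale image
#'
#' Reads PNG (via the png package) or PGM (plain `P2` or binary `P5`).
#' The result is a numeric matrix indexed `[y + 1, x + 1]` with x = column,
#' y = row, both 0-based and pixel-centered in all package coordinates.
#' PNG intensities are rescaled from [0, 1] to [0, 255]; multi-channel PNGs
#' are averaged over their color channels. PGM values are kept as stored.
#'
#' @param path image file path; format chosen by extension (.png/.pgm).
#' @return Numeric matrix of intensities.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3L, dim(img)[3L]), drop = FALSE],
                                             c(1L, 2L), mean)
    return(img * 255)
  }
  if (ext == "pgm") return(read_pgm(path))
  stop("unsupported image format: .", ext, " (use .png or .pgm)", call. = FALSE)
}

#' Write a 2D grayscale image
#'
#' Writes PNG (values clamped to [0, 255] and stored as 8-bit) or plain-text
#' PGM (`P2`, values rounded and clamped to [0, maxval]).
#'
#' @param pixels numeric intensity matrix (row = y, column = x).
#' @param path output path (.png or .pgm).
#' @param maxval maximum gray value recorded in PGM headers.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(pixels, path, maxval = 255L) {
  ext <- tolower(tools::file_ext(path))
  m <- pmin(pmax(round(pixels), 0), maxval)
  if (ext == "png") {
    png::writePNG(m / maxval, path)
  } else if (ext == "pgm") {
    write_pgm(m, path, maxval)
  } else {
    stop("unsupported image format: .", ext, " (use .png or .pgm)", call. = FALSE)
  }
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  tokens <- character(0)
  # header: width, height, maxval; '#' starts a comment to end of line
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || ch == "") stop("truncated PGM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (ch == "\n" || ch == "") break
      }
    } else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!grepl("[0-9]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  w <- as.integer(tokens[1L]); h <- as.integer(tokens[2L]); mx <- as.integer(tokens[3L])
  if (magic == "P5") {
    bytes <- if (mx < 256L) 1L else 2L
    vals <- readBin(con, "integer", n = w * h, size = bytes, signed = FALSE,
                    endian = "big")
  } else {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE,
                 comment.char = "#")
  }
  if (length(vals) != w * h) stop("truncated PGM pixel data", call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(pixels, path, maxval = 255L) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(pixels), nrow(pixels)), as.character(maxval)), con)
  apply(pixels, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Read and write binary masks
#'
#' Masks are 0/1 integer matrices. On disk they are 8-bit grayscale images
#' with 0 = background and 255 = object; any non-zero pixel reads back as 1.
#'
#' @param path image file path (.png or .pgm).
#' @return `read_mask()`: a 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  m <- read_gray_image(path)
  (m > 127) * 1L
}

#' @rdname read_mask
#' @param mask 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  write_gray_image(ifelse(mask > 0, 255, 0), path)
}

#' Read and write contours as text
#'
#' One "x y" pair per line (0-based pixel coordinates), `#` comments allowed.
#'
#' @param path text file path.
#' @return `read_contour()`: tibble with columns `x`, `y`.
#' @export
read_contour <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("x", "y"), colClasses = "numeric")
  tibble::as_tibble(tab)
}

#' @rdname read_contour
#' @param contour data frame with columns `x`, `y`.
#' @export
write_contour <- function(contour, path) {
  writeLines(c("# contour points: x y (0-based pixel coordinates)",
               sprintf("%.6f %.6f", contour$x, contour$y)), path)
  invisible(path)
}

#' Extract one slice of a NIfTI volume as a grayscale matrix
#'
#' Convenience extractor for real data: pulls a single 2D slice out of a
#' NIfTI volume so it can be fed to [segment_image()]. Requires the RNifti
#' package.
#'
#' @param path NIfTI file.
#' @param axis which voxel axis to slice across (1, 2 or 3).
#' @param index 1-based slice index along that axis.
#' @return Numeric intensity matrix (row = y, column = x).
#' @export
nifti_slice <- function(path, axis = 3L, index = 1L) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("nifti_slice() requires the RNifti package", call. = FALSE)
  }
  vol <- RNifti::readNifti(path)
  arr <- as.array(vol)
  if (length(dim(arr)) < 3L) arr <- array(arr, c(dim(arr), 1L))
  sl <- switch(as.character(axis),
               "1" = arr[index, , ],
               "2" = arr[, index, ],
               "3" = arr[, , index],
               stop("`axis` must be 1, 2 or 3", call. = FALSE))
  t(as.matrix(sl))
}
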