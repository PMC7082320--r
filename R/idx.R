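#' Read and write the IDX array container
#'
#' Minimal reader/writer for the IDX binary container used to distribute
#' classic image benchmarks (magic number `0 0 <type> <ndim>`, big-endian
#' dimension sizes, then the data in row-major order). Only the unsigned
#' byte element type (code `0x08`) is supported, which covers the standard
#' image and label files. No download is ever performed: the user supplies
#' the files.
#'
#' @param path Path to an IDX file.
#' @return `read_idx()` returns an array: dimension order is preserved, so a
#'   stack of images is indexed `[image, row, col]` and labels are a plain
#'   vector.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (length(magic) < 4L || magic[1] != 0L || magic[2] != 0L) {
    stop("not an IDX file: bad magic number", call. = FALSE)
  }
  if (magic[3] != 0x08) {
    stop("unsupported IDX element type 0x",
         format(as.hexmode(magic[3])), " (only unsigned byte is supported)",
         call. = FALSE)
  }
  ndim <- magic[4]
  if (ndim < 1L) stop("not an IDX file: zero dimensions", call. = FALSE)
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  if (length(dims) < ndim || any(dims < 0L)) {
    stop("truncated or corrupt IDX header", call. = FALSE)
  }
  n <- prod(dims)
  data <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
  if (length(data) < n) stop("truncated IDX file: expected ", n,
                             " bytes of data, got ", length(data),
                             call. = FALSE)
  if (ndim == 1L) return(data)
  # IDX is row-major with the first dimension slowest; R arrays are
  # column-major, so fill in reversed order and transpose back.
  aperm(array(data, dim = rev(dims)), rev(seq_len(ndim)))
}

#' @rdname read_idx
#' @param x Vector or array of integers in `0..255`.
#' @export
write_idx <- function(x, path) {
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  vals <- as.integer(if (is.null(dim(x))) x else aperm(x, rev(seq_along(dims))))
  if (any(vals < 0L | vals > 255L)) {
    stop("write_idx() supports unsigned byte data only (0..255)",
         call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0L, 0L, 0x08, length(dims))), con)
  writeBin(as.integer(dims), con, size = 4L, endian = "big")
  writeBin(as.raw(vals), con)
  invisible(path)
}

#' Load an image/label pair of IDX files
#'
#' Convenience wrapper reading a 3-dimensional image file and its matching
#' 1-dimensional label file, checking that the counts agree.
#'
#' @param image_path,label_path Paths to the image and label IDX files.
#' @return List with `images` (array `[n, H, W]`) and `labels` (integer
#'   vector of length `n`).
#' @export
load_idx_images <- function(image_path, label_path) {
  images <- read_idx(image_path)
  labels <- read_idx(label_path)
  if (length(dim(images)) != 3L) {
    stop("image file must hold a 3-dimensional array", call. = FALSE)
  }
  if (!is.null(dim(labels))) {
    stop("label file must hold a 1-dimensional array", call. = FALSE)
  }
  if (dim(images)[1] != length(labels)) {
    stop("image/label count mismatch: ", dim(images)[1], " images vs ",
         length(labels), " labels", call. = FALSE)
  }
  list(images = images, labels = as.integer(labels))
}
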