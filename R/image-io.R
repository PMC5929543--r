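#' 8-bit RGB raster image
#'
#' The unit of analysis: three integer intensity planes (red, green, blue) of
#' identical shape, each value in \[0, 255\]. Pixel coordinates are 1-based
#' (row, column), row-major, as usual for R matrices; areas are pixel counts.
#'
#' @param red,green,blue Integer matrices of identical dimensions with values
#'   in \[0, 255\]. A single matrix may be passed as `red` to build a grayscale
#'   image (replicated to all three channels).
#' @return An object of class `rgb_image`: a list with elements `red`,
#'   `green`, `blue` (integer matrices) and attributes for `height`/`width`.
#' @examples
#' img <- rgb_image(matrix(255L, 2, 2), matrix(0L, 2, 2), matrix(0L, 2, 2))
#' dim(img)
#' @export
rgb_image <- function(red, green = NULL, blue = NULL) {
  if (is.null(green) && is.null(blue)) {
    green <- red
    blue <- red
  }
  planes <- list(red = red, green = green, blue = blue)
  for (nm in names(planes)) {
    p <- planes[[nm]]
    if (!is.matrix(p)) stop("channel '", nm, "' must be a matrix")
    if (!identical(dim(p), dim(red)))
      stop("channel planes differ in shape: '", nm, "' is ",
           paste(dim(p), collapse = "x"), ", expected ",
           paste(dim(red), collapse = "x"))
    if (anyNA(p) || any(p < 0) || any(p > 255) || any(p != trunc(p)))
      stop("channel '", nm, "' must contain integers in [0, 255]")
    storage.mode(p) <- "integer"
    planes[[nm]] <- p
  }
  structure(planes, class = "rgb_image")
}

#' @export
dim.rgb_image <- function(x) dim(x$red)

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels (8-bit per channel)\n", d[1], d[2]))
  for (ch in c("red", "green", "blue"))
    cat(sprintf("  %-5s range [%d, %d], mean %.1f\n", ch,
                min(x[[ch]]), max(x[[ch]]), mean(x[[ch]])))
  invisible(x)
}

#' Display an RGB image
#'
#' @param x An [rgb_image()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rgb_image <- function(x, ...) {
  d <- dim(x)
  arr <- array(0, c(d[1], d[2], 3))
  arr[, , 1] <- x$red / 255
  arr[, , 2] <- x$green / 255
  arr[, , 3] <- x$blue / 255
  graphics::plot(c(0, d[2]), c(0, d[1]), type = "n", asp = 1,
                 xlab = "column", ylab = "row", ...)
  graphics::rasterImage(arr, 0, 0, d[2], d[1])
  invisible(x)
}

#' Ordered Z-stack of RGB images
#'
#' A confocal Z-stack is carried as an ordered list of [rgb_image()] slices
#' sharing one shape; analysis is slice-wise 2D.
#'
#' @param slices List of `rgb_image` objects with identical dimensions.
#' @param source_id Text label for the stack.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(slices, source_id = "stack") {
  if (length(slices) < 1L) stop("an image_stack needs at least 1 slice")
  d1 <- dim(slices[[1]])
  for (i in seq_along(slices)) {
    if (!inherits(slices[[i]], "rgb_image"))
      stop("slice ", i, " is not an rgb_image")
    if (!identical(dim(slices[[i]]), d1))
      stop("slice ", i, " has shape ", paste(dim(slices[[i]]), collapse = "x"),
           " but slice 1 has ", paste(d1, collapse = "x"))
  }
  structure(list(slices = slices, source_id = source_id),
            class = "image_stack")
}

#' @export
length.image_stack <- function(x) length(x$slices)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<image_stack> '%s': %d slice(s) of %d x %d pixels\n",
              x$source_id, length(x$slices), d[1], d[2]))
  invisible(x)
}

# numeric [h,w,ch] array in [0,1] (png/jpeg readers) -> rgb_image
.array_to_rgb <- function(arr, bit_depth = 8L) {
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  scale <- if (bit_depth == 16L) 65535 else 255
  q <- round(arr * scale)
  if (bit_depth == 16L) q <- q %/% 257      # full-range 16 -> 8 bit
  nch <- dim(q)[3]
  if (nch == 1L) {
    rgb_image(q[, , 1, drop = TRUE])
  } else if (nch == 2L) {                    # gray + alpha: alpha dropped
    rgb_image(q[, , 1, drop = TRUE])
  } else {                                   # RGB or RGBA: alpha dropped
    rgb_image(q[, , 1], q[, , 2], q[, , 3])
  }
}

#' Read a micrograph into an 8-bit RGB image
#'
#' Accepts PNG, TIFF (uncompressed baseline, single or multi-page; the first
#' page is returned) and JPEG. 16-bit inputs are rescaled to 8 bits by integer
#' division by 257 so that full scale maps to full scale; grayscale inputs are
#' replicated to three identical channels; an alpha channel is dropped. A
#' warning is issued for JPEG input, whose lossy artifacts can perturb
#' threshold-based detection.
#'
#' @param path Path to a PNG/TIFF/JPEG file.
#' @return An [rgb_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    .array_to_rgb(arr, bit_depth = as.integer(bits))
  } else if (ext %in% c("tif", "tiff")) {
    pages <- read_tiff(path)
    pages[[1]]
  } else if (ext %in% c("jpg", "jpeg")) {
    warning("JPEG is lossy; compression artifacts may perturb thresholding: ",
            path)
    .array_to_rgb(jpeg::readJPEG(path), bit_depth = 8L)
  } else {
    stop("unsupported image format '", ext, "' for ", path,
         " (expected PNG, TIFF or JPEG)")
  }
}

#' Read a confocal Z-stack
#'
#' Either a multi-page TIFF (pages in file order) or a directory of single
#' images read in lexicographic filename order.
#'
#' @param path Path to a multi-page TIFF or a directory of images.
#' @param source_id Label for the stack; defaults to the file/directory name.
#' @return An [image_stack()].
#' @export
load_stack <- function(path, source_id = basename(path)) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[order(basename(files))]
    if (length(files) == 0L) stop("no images found in directory: ", path)
    slices <- lapply(files, load_image)
  } else {
    if (!file.exists(path)) stop("no such stack: ", path)
    slices <- read_tiff(path)
  }
  d1 <- dim(slices[[1]])
  bad <- which(!vapply(slices, function(s) identical(dim(s), d1), logical(1)))
  if (length(bad))
    stop("stack slices have mixed shapes; offending slice index(es): ",
         paste(bad, collapse = ", "))
  image_stack(slices, source_id = source_id)
}

#' Write an RGB image to PNG or TIFF
#'
#' Lossless round trip: `load_image(write_image(img, path))` is pixel-exact.
#'
#' @param image An [rgb_image()].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    d <- dim(image)
    arr <- array(0, c(d[1], d[2], 3))
    arr[, , 1] <- image$red / 255
    arr[, , 2] <- image$green / 255
    arr[, , 3] <- image$blue / 255
    png::writePNG(arr, path)
  } else if (ext %in% c("tif", "tiff")) {
    write_tiff(list(image), path)
  } else {
    stop("unsupported output format '", ext, "' (use PNG or TIFF)")
  }
  invisible(path)
}

#' Write a Z-stack as a multi-page TIFF
#'
#' @param stack An [image_stack()].
#' @param path Output path ending in `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  write_tiff(stack$slices, path)
  invisible(path)
}

#' Write tabular results as CSV
#'
#' UTF-8, '.' decimal separator, header row; one data row per record.
#'
#' @param rows A data frame, or a list of same-schema records (named lists).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  if (!is.data.frame(rows)) {
    if (length(rows) == 0L) stop("cannot infer a schema from an empty list; ",
                                 "pass a data.frame for a header-only file")
    nms <- names(rows[[1]])
    for (i in seq_along(rows))
      if (!identical(names(rows[[i]]), nms))
        stop("record ", i, " does not share the schema of record 1")
    rows <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  }
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
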