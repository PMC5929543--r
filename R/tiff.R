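# Minimal baseline TIFF codec.
#
# No TIFF reader is available in the installed R library, so the package
# carries its own reader/writer for the subset the analysis needs:
# uncompressed baseline TIFF, little- or big-endian, 8- or 16-bit samples,
# grayscale / RGB / RGBA, chunky planar configuration, single- or multi-page.
# 16-bit samples are rescaled to 8 bits by integer division by 257
# (full scale maps to full scale); alpha is dropped.

.u16 <- function(raw, off, endian) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2, signed = FALSE,
          endian = endian)
}

.u32 <- function(raw, off, endian) {
  v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
  if (v < 0) v <- v + 2^32
  v
}

# read `count` values of a given TIFF field type starting at byte offset `off`
.read_values <- function(raw, off, type, count, endian) {
  if (type == 1L) {                                        # BYTE
    as.integer(raw[(off + 1):(off + count)])
  } else if (type == 3L) {                                 # SHORT
    vapply(seq_len(count) - 1L,
           function(i) .u16(raw, off + 2L * i, endian), numeric(1))
  } else if (type == 4L) {                                 # LONG
    vapply(seq_len(count) - 1L,
           function(i) .u32(raw, off + 4L * i, endian), numeric(1))
  } else {
    stop("unsupported TIFF field type ", type)
  }
}

.type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)

# parse one IFD; returns list(tags = named list, next_ifd = offset)
.read_ifd <- function(raw, off, endian) {
  n <- .u16(raw, off, endian)
  tags <- list()
  for (i in seq_len(n)) {
    e <- off + 2L + 12L * (i - 1L)
    tag <- .u16(raw, e, endian)
    type <- .u16(raw, e + 2L, endian)
    count <- .u32(raw, e + 4L, endian)
    sz <- .type_size[as.character(type)]
    if (is.na(sz)) next                     # skip rationals etc.
    nbytes <- sz * count
    voff <- if (nbytes <= 4) e + 8L else .u32(raw, e + 8L, endian)
    tags[[as.character(tag)]] <- .read_values(raw, voff, type, count, endian)
  }
  list(tags = tags, next_ifd = .u32(raw, off + 2L + 12L * n, endian))
}

.tag <- function(tags, id, default = NULL) {
  v <- tags[[as.character(id)]]
  if (is.null(v)) default else v
}

# Read all pages of a TIFF file as a list of rgb_image objects.
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file (too short): ", path)
  bom <- rawToChar(raw[1:2])
  endian <- if (bom == "II") "little" else if (bom == "MM") "big" else
    stop("not a TIFF file (bad byte-order mark): ", path)
  if (.u16(raw, 2L, endian) != 42L) stop("not a TIFF file: ", path)
  off <- .u32(raw, 4L, endian)
  pages <- list()
  while (off != 0) {
    ifd <- .read_ifd(raw, off, endian)
    pages[[length(pages) + 1L]] <- .decode_page(raw, ifd$tags, endian, path)
    off <- ifd$next_ifd
  }
  if (length(pages) == 0L) stop("TIFF file contains no images: ", path)
  pages
}

.decode_page <- function(raw, tags, endian, path) {
  width <- .tag(tags, 256); height <- .tag(tags, 257)
  if (is.null(width) || is.null(height))
    stop("TIFF page lacks dimensions: ", path)
  comp <- .tag(tags, 259, 1)
  if (comp != 1)
    stop("unsupported TIFF compression scheme ", comp, " in ", path,
         " (only uncompressed baseline TIFF is supported)")
  spp <- .tag(tags, 277, 1)
  bits <- .tag(tags, 258, 8)[1]
  if (!bits %in% c(8, 16))
    stop("unsupported TIFF bit depth ", bits, " in ", path)
  planar <- .tag(tags, 284, 1)
  if (planar != 1 && spp > 1)
    stop("unsupported planar TIFF layout in ", path)
  offs <- .tag(tags, 273); cnts <- .tag(tags, 279)
  if (is.null(offs)) stop("TIFF page lacks strip offsets: ", path)
  if (is.null(cnts)) cnts <- rep(width * height * spp * bits / 8, length(offs))
  data <- raw(0)
  for (i in seq_along(offs))
    data <- c(data, raw[(offs[i] + 1):(offs[i] + cnts[i])])
  npx <- width * height
  if (bits == 8L) {
    v <- as.integer(data[seq_len(npx * spp)])
  } else {
    v <- readBin(data, "integer", n = npx * spp, size = 2, signed = FALSE,
                 endian = endian)
    v <- v %/% 257L
  }
  plane <- function(s) {
    # chunky layout, row-major: sample s of pixel (r, c) at ((r-1)w + c-1)spp + s
    m <- matrix(v[seq(s, by = spp, length.out = npx)],
                nrow = width, ncol = height)
    t(m)
  }
  if (spp == 1L) rgb_image(plane(1L))
  else rgb_image(plane(1L), plane(2L), plane(3L))   # alpha (spp = 4) dropped
}

# ---- writer ----------------------------------------------------------------

.w16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.w32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.ifd_entry <- function(tag, type, count, value_field) {
  c(.w16(tag), .w16(type), .w32(count), value_field)
}

.inline_short <- function(x) c(.w16(x), .w16(0L))

# Write a list of rgb_image objects as an uncompressed little-endian
# multi-page RGB TIFF (8 bits per sample, one strip per page).
write_tiff <- function(images, path) {
  stopifnot(length(images) >= 1)
  chunks <- list(c(charToRaw("II"), .w16(42L), .w32(0L)))  # header; IFD offset patched
  pos <- 8L
  ifd_offset_patch <- 4L        # byte position of the pointer to the next IFD
  out <- vector("list", 0)
  body <- raw(0)
  for (k in seq_along(images)) {
    img <- images[[k]]
    stopifnot(inherits(img, "rgb_image"))
    h <- dim(img)[1]; w <- dim(img)[2]
    # interleave RGB row-major
    px <- integer(h * w * 3L)
    ord <- as.vector(t(matrix(seq_len(h * w), h, w)))  # row-major pixel order
    px[seq(1, by = 3, length.out = h * w)] <- as.vector(img$red)[ord]
    px[seq(2, by = 3, length.out = h * w)] <- as.vector(img$green)[ord]
    px[seq(3, by = 3, length.out = h * w)] <- as.vector(img$blue)[ord]
    data <- as.raw(px)
    data_off <- pos
    bps_off <- pos + length(data)
    ifd_off <- bps_off + 6L
    entries <- list(
      .ifd_entry(256L, 4L, 1L, .w32(w)),                 # ImageWidth
      .ifd_entry(257L, 4L, 1L, .w32(h)),                 # ImageLength
      .ifd_entry(258L, 3L, 3L, .w32(bps_off)),           # BitsPerSample -> [8,8,8]
      .ifd_entry(259L, 3L, 1L, .inline_short(1L)),       # Compression = none
      .ifd_entry(262L, 3L, 1L, .inline_short(2L)),       # Photometric = RGB
      .ifd_entry(273L, 4L, 1L, .w32(data_off)),          # StripOffsets
      .ifd_entry(277L, 3L, 1L, .inline_short(3L)),       # SamplesPerPixel
      .ifd_entry(278L, 4L, 1L, .w32(h)),                 # RowsPerStrip
      .ifd_entry(279L, 4L, 1L, .w32(length(data))),      # StripByteCounts
      .ifd_entry(284L, 3L, 1L, .inline_short(1L))        # PlanarConfig = chunky
    )
    ifd <- c(.w16(length(entries)), do.call(c, entries), .w32(0L))
    # patch the previous next-IFD pointer to point here
    ptr <- .w32(ifd_off)
    if (ifd_offset_patch <= 8L) {
      chunks[[1]][5:8] <- ptr
    } else {
      rel <- ifd_offset_patch - 8L
      body[(rel + 1):(rel + 4)] <- ptr
    }
    page <- c(data, c(.w16(8L), .w16(8L), .w16(8L)), ifd)
    # next-IFD pointer sits in the last 4 bytes of this page's IFD
    ifd_offset_patch <- ifd_off + length(ifd) - 4L
    body <- c(body, page)
    pos <- pos + length(page)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(chunks[[1]], body), con)
  invisible(path)
}
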