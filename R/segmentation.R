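#' Single-cell size window
#'
#' Objects whose pixel area lies in `[s_min, s_max]` (inclusive at both ends)
#' are taken as isolated single cells; their mean area calibrates the
#' effective count.
#'
#' @param s_min,s_max Pixel-count bounds, `1 <= s_min <= s_max`.
#' @return An object of class `size_range`.
#' @examples
#' size_range(301, 600)
#' @export
size_range <- function(s_min, s_max) {
  if (s_min < 1 || s_min > s_max || s_min != trunc(s_min) ||
      (is.finite(s_max) && s_max != trunc(s_max)))
    stop("size range must satisfy 1 <= s_min <= s_max (integer pixel counts)")
  structure(list(s_min = as.numeric(s_min), s_max = as.numeric(s_max)),
            class = "size_range")
}

#' @export
print.size_range <- function(x, ...) {
  cat(sprintf("<size_range> [%g, %g] pixels\n", x$s_min, x$s_max))
  invisible(x)
}

#' Label 8-connected components of a binary mask
#'
#' Pixels that are horizontal, vertical or diagonal neighbours and both
#' selected belong to the same object. Labels are consecutive `1..K`, ordered
#' by the raster-scan (row-major) position of each object's first pixel, so a
#' given mask always labels identically.
#'
#' Implemented as run-length union-find: horizontal runs of selected pixels
#' are extracted per row and runs in consecutive rows are merged when their
#' column intervals touch or overlap within one column (the 8-connectivity
#' criterion).
#'
#' @param mask Logical matrix from [apply_threshold()].
#' @return An object of class `labeled_objects`: a list with `label_map`
#'   (integer matrix, 0 = background) and `objects` (data frame with columns
#'   `id`, `area`, `row_min`, `col_min`, `row_max`, `col_max`,
#'   `centroid_row`, `centroid_col`; 1-based pixel coordinates).
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  label_map <- matrix(0L, h, w)
  empty <- data.frame(id = integer(0), area = numeric(0),
                      row_min = integer(0), col_min = integer(0),
                      row_max = integer(0), col_max = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
  if (!any(mask))
    return(structure(list(label_map = label_map, objects = empty),
                     class = "labeled_objects"))

  # horizontal runs in row-major order
  v <- as.vector(t(mask))
  n <- length(v)
  idx <- seq_len(n)
  prev <- c(FALSE, v[-n])
  nxt <- c(v[-1], FALSE)
  at_row_start <- ((idx - 1L) %% w) == 0L
  at_row_end <- (idx %% w) == 0L
  s_idx <- which(v & (!prev | at_row_start))
  e_idx <- which(v & (!nxt | at_row_end))
  run_row <- (s_idx - 1L) %/% w + 1L
  run_s <- (s_idx - 1L) %% w + 1L
  run_e <- (e_idx - 1L) %% w + 1L
  nrun <- length(s_idx)

  parent <- seq_len(nrun)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  by_row <- split(seq_len(nrun), run_row)
  rows_present <- as.integer(names(by_row))
  for (k in seq_along(rows_present)[-1]) {
    if (rows_present[k] - rows_present[k - 1] != 1L) next
    above <- by_row[[k - 1]]
    below <- by_row[[k]]
    j <- 1L
    nab <- length(above)
    for (b in below) {
      while (j <= nab && run_e[above[j]] < run_s[b] - 1L) j <- j + 1L
      kk <- j
      while (kk <= nab && run_s[above[kk]] <= run_e[b] + 1L) {
        ra <- find(above[kk]); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        kk <- kk + 1L
      }
    }
  }
  roots <- vapply(seq_len(nrun), find, integer(1))
  labels <- match(roots, unique(roots))  # raster order of first pixel

  len <- run_e - run_s + 1L
  lin <- rep(run_row, len) + (sequence(len, from = run_s) - 1L) * h
  label_map[lin] <- rep(labels, len)

  area <- as.vector(rowsum(as.numeric(len), labels))
  row_min <- as.integer(tapply(run_row, labels, min))
  row_max <- as.integer(tapply(run_row, labels, max))
  col_min <- as.integer(tapply(run_s, labels, min))
  col_max <- as.integer(tapply(run_e, labels, max))
  centroid_row <- as.vector(rowsum(run_row * as.numeric(len), labels)) / area
  centroid_col <- as.vector(rowsum(len * (run_s + run_e) / 2, labels)) / area
  objects <- data.frame(id = seq_along(area), area = area,
                        row_min = row_min, col_min = col_min,
                        row_max = row_max, col_max = col_max,
                        centroid_row = centroid_row,
                        centroid_col = centroid_col)
  structure(list(label_map = label_map, objects = objects),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("<labeled_objects> %d object(s), total area %g px\n",
              nrow(x$objects), sum(x$objects$area)))
  if (nrow(x$objects) > 0)
    cat(sprintf("  area range [%g, %g] px\n", min(x$objects$area),
                max(x$objects$area)))
  invisible(x)
}

#' Select single-cell candidates by area
#'
#' @param objects A [label_components()] result.
#' @param range A [size_range()]; bounds are inclusive at both ends.
#' @return Integer vector of selected object ids (possibly empty).
#' @export
select_by_size <- function(objects, range) {
  stopifnot(inherits(objects, "labeled_objects"), inherits(range, "size_range"))
  ob <- objects$objects
  ob$id[ob$area >= range$s_min & ob$area <= range$s_max]
}

#' Remove manually excluded objects from a selection
#'
#' Replaces the GUI gesture of double-clicking anomalous segments: ids listed
#' in a run configuration are dropped from the single-cell selection.
#' Exclusion affects only the mean single-cell area — never the total stained
#' area.
#'
#' @param objects A [label_components()] result (defines the valid ids).
#' @param selection Integer vector of selected ids.
#' @param excluded Integer vector of ids to drop; every id must exist in the
#'   labeling.
#' @return `setdiff(selection, excluded)`.
#' @export
exclude_objects <- function(objects, selection, excluded) {
  stopifnot(inherits(objects, "labeled_objects"))
  unknown <- setdiff(excluded, objects$objects$id)
  if (length(unknown))
    stop("cannot exclude unknown object id(s): ",
         paste(unknown, collapse = ", "))
  setdiff(selection, excluded)
}

#' Object-size bins for histogram sweeps
#'
#' Bins partition `[1, Inf)`: `[1, b1], [b1+1, b2], ..., [b_m + 1, Inf)`.
#' The defaults are the bins used throughout the balance analysis:
#' 1–300, 301–600, 601–1000, 1001–2000, >2000 pixels.
#'
#' @param upper Strictly increasing positive integer inner upper bounds.
#' @return A data frame of class `size_bins` with columns `lo`, `hi`
#'   (`hi = Inf` for the open last bin).
#' @examples
#' size_bins()           # the default bins
#' size_bins(c(100, 500))
#' @export
size_bins <- function(upper = c(300, 600, 1000, 2000)) {
  if (length(upper) < 1L || any(upper < 1) || any(upper != trunc(upper)) ||
      any(diff(upper) <= 0))
    stop("bin bounds must be strictly increasing positive integers")
  b <- data.frame(lo = c(1, upper + 1), hi = c(upper, Inf))
  class(b) <- c("size_bins", "data.frame")
  b
}

# validate a bins argument: size_bins object or lo/hi data.frame partitioning [1, Inf)
.check_bins <- function(bins) {
  if (!is.data.frame(bins) || !all(c("lo", "hi") %in% names(bins)))
    stop("bins must be a size_bins() object or a data.frame with lo/hi")
  if (bins$lo[1] != 1 || !is.infinite(bins$hi[nrow(bins)]) ||
      (nrow(bins) > 1 && any(bins$lo[-1] != bins$hi[-nrow(bins)] + 1)) ||
      any(bins$hi < bins$lo))
    stop("bins must be contiguous, non-overlapping, start at 1 and end open")
  bins
}

#' Empirical histogram of object sizes
#'
#' Per-bin object count and total area; membership by inclusive lower and
#' upper bound (the last bin is open-ended).
#'
#' @param objects A [label_components()] result.
#' @param bins A [size_bins()] object (or equivalent lo/hi data frame).
#' @return Data frame with columns `bin_lo`, `bin_hi`, `count`, `total_area`.
#'   Totals over bins equal the global object count and mask area.
#' @export
object_size_histogram <- function(objects, bins = size_bins()) {
  stopifnot(inherits(objects, "labeled_objects"))
  bins <- .check_bins(bins)
  a <- objects$objects$area
  k <- findInterval(a, bins$lo)
  data.frame(bin_lo = bins$lo, bin_hi = bins$hi,
             count = tabulate(k, nbins = nrow(bins)),
             total_area = vapply(seq_len(nrow(bins)),
                                 function(i) sum(a[k == i]), numeric(1)))
}
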