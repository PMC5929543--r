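#' Multi-threshold object-size histogram sweep
#'
#' The objective criterion for balancing the detection threshold `T` against
#' the single-cell size window: for every `T` on a grid the image is
#' thresholded, labeled, and the isolated objects are binned by size. The
#' total thresholded area is non-increasing in `T` and, at every `T`, equals
#' the summed per-bin area (the "black curve is the sum of the coloured
#' curves" conservation).
#'
#' @param image An [rgb_image()].
#' @param channel Primary channel, `"red"`, `"green"` or `"blue"`.
#' @param rule_mode `"single_channel"` (default), `"differential"` or
#'   `"intensity"`.
#' @param T_grid Strictly increasing integer thresholds; default a 5-step
#'   grid 5..250.
#' @param bins A [size_bins()] object.
#' @return Object of class `threshold_sweep`: `channel`, `rule_mode`,
#'   `T_grid`, `bins`, `total_area` (per T), `counts` and `areas`
#'   (length(T_grid) x nrow(bins) matrices).
#' @export
threshold_sweep <- function(image, channel = "red",
                            rule_mode = "single_channel",
                            T_grid = seq(5L, 250L, by = 5L),
                            bins = size_bins()) {
  stopifnot(inherits(image, "rgb_image"))
  if (length(T_grid) < 1L || any(diff(T_grid) <= 0))
    stop("T_grid must be strictly increasing")
  bins <- .check_bins(bins)
  nT <- length(T_grid); nb <- nrow(bins)
  total_area <- numeric(nT)
  counts <- matrix(0, nT, nb)
  areas <- matrix(0, nT, nb)
  for (i in seq_len(nT)) {
    rule <- threshold_rule(rule_mode, channel, T_grid[i])
    mask <- apply_threshold(image, rule)
    total_area[i] <- mask_area(mask)
    hist <- object_size_histogram(label_components(mask), bins)
    counts[i, ] <- hist$count
    areas[i, ] <- hist$total_area
  }
  structure(list(channel = channel, rule_mode = rule_mode,
                 T_grid = as.integer(T_grid), bins = bins,
                 total_area = total_area, counts = counts, areas = areas),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> %s channel (%s), %d thresholds in [%d, %d]\n",
              x$channel, x$rule_mode, length(x$T_grid), min(x$T_grid),
              max(x$T_grid)))
  cat(sprintf("  total area: %g px at T = %d down to %g px at T = %d\n",
              x$total_area[1], x$T_grid[1],
              x$total_area[length(x$T_grid)], max(x$T_grid)))
  invisible(x)
}

#' Plot a threshold sweep
#'
#' Draws the total thresholded area (black) over the per-size-bin area or
#' count curves (coloured), one curve per size bin.
#'
#' @param x A [threshold_sweep()] result.
#' @param what `"area"` or `"count"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.threshold_sweep <- function(x, what = c("area", "count"), ...) {
  what <- match.arg(what)
  m <- if (what == "area") x$areas else x$counts
  tot <- if (what == "area") x$total_area else rowSums(x$counts)
  cols <- grDevices::hcl.colors(ncol(m), "Dark 3")
  graphics::matplot(x$T_grid, m, type = "l", lty = 1, col = cols,
                    xlab = "threshold T",
                    ylab = if (what == "area") "object area [px]"
                           else "object count", ...)
  graphics::lines(x$T_grid, tot, lwd = 2, col = "black")
  labs <- sprintf("%g-%g", x$bins$lo, x$bins$hi)
  labs[length(labs)] <- sprintf(">%g", x$bins$lo[length(labs)] - 1)
  graphics::legend("topright", legend = c("total", labs), lwd = c(2, rep(1,
    ncol(m))), col = c("black", cols), bty = "n", cex = 0.8)
  invisible(x)
}

#' Suggest a detection threshold from a sweep
#'
#' Formalizes the visual rule of reading the threshold off the histogram
#' maximum: `T*` is the grid value maximizing the isolated-object count in
#' the target size bin, ties broken toward the smallest `T`. The full count
#' curve is returned so multi-modal histograms (for instance a bin whose
#' counts peak at two separate thresholds, betraying cell clusters rather
#' than single cells) can be inspected instead of silently auto-resolved.
#'
#' @param sweep A [threshold_sweep()] result.
#' @param target_bin Index into `sweep$bins` of the single-cell size bin.
#' @return Object of class `threshold_suggestion`: `T_star`, `target_bin`,
#'   `T_grid`, `counts` (the target bin's count curve).
#' @export
suggest_threshold <- function(sweep, target_bin) {
  stopifnot(inherits(sweep, "threshold_sweep"))
  if (target_bin < 1 || target_bin > nrow(sweep$bins))
    stop("target_bin must index a bin of the sweep (1..", nrow(sweep$bins),
         ")")
  curve <- sweep$counts[, target_bin]
  if (all(curve == 0))
    stop("no objects in this size range at any threshold; choose another ",
         "bin or extend the threshold grid")
  T_star <- sweep$T_grid[which.max(curve)]  # which.max takes the first tie
  structure(list(T_star = T_star, target_bin = target_bin,
                 T_grid = sweep$T_grid, counts = curve),
            class = "threshold_suggestion")
}

#' @export
print.threshold_suggestion <- function(x, ...) {
  cat(sprintf("<threshold_suggestion> T* = %d (max count %g in bin %d)\n",
              x$T_star, max(x$counts), x$target_bin))
  n_modes <- sum(diff(sign(diff(c(-Inf, x$counts, -Inf)))) == -2)
  if (n_modes > 1)
    cat(sprintf("  note: count curve has %d local maxima; inspect $counts\n",
                n_modes))
  invisible(x)
}

#' Red/green area-ratio stability across thresholds
#'
#' When the red and green total-area curves decay with `T` by the same
#' functional form, their ratio is constant over a threshold band and any `T`
#' in the band yields the same sub-population fractions. This function
#' computes the per-threshold area ratio and its relative spread
#' `(max - min) / mean` over a requested band.
#'
#' @param sweep_red,sweep_green [threshold_sweep()] results on an identical
#'   `T_grid`.
#' @param band Optional length-2 numeric `c(T_lo, T_hi)` restricting the
#'   spread computation; default the whole grid.
#' @return Object of class `ratio_stability`: `T`, `ratio` (red/green total
#'   area, `NA` where the green area is zero), `spread`, `excluded_T`
#'   (thresholds dropped for a zero denominator or numerator).
#' @export
ratio_stability <- function(sweep_red, sweep_green, band = NULL) {
  stopifnot(inherits(sweep_red, "threshold_sweep"),
            inherits(sweep_green, "threshold_sweep"))
  if (!identical(sweep_red$T_grid, sweep_green$T_grid))
    stop("the two sweeps must share an identical T_grid")
  Tg <- sweep_red$T_grid
  ok <- sweep_red$total_area > 0 & sweep_green$total_area > 0
  ratio <- ifelse(ok, sweep_red$total_area / sweep_green$total_area, NA_real_)
  if (is.null(band)) band <- range(Tg)
  in_band <- ok & Tg >= band[1] & Tg <= band[2]
  if (!any(in_band))
    stop("no threshold in the band has positive area in both channels")
  r <- ratio[in_band]
  spread <- if (length(r) == 1L) 0 else (max(r) - min(r)) / mean(r)
  structure(list(T = Tg, ratio = ratio, band = band, spread = spread,
                 excluded_T = Tg[!ok]),
            class = "ratio_stability")
}

#' @export
print.ratio_stability <- function(x, ...) {
  cat(sprintf(
    "<ratio_stability> red/green area ratio over T in [%g, %g]\n",
    x$band[1], x$band[2]))
  cat(sprintf("  relative spread (max-min)/mean: %.4f\n", x$spread))
  if (length(x$excluded_T))
    cat(sprintf("  %d threshold(s) excluded (zero area in a channel)\n",
                length(x$excluded_T)))
  invisible(x)
}
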