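#' Per-channel analysis parameters
#'
#' Bundles the threshold rule, single-cell size window and manual exclusion
#' list for one staining channel. Thresholds and size windows are adjusted
#' per channel because sub-populations can differ in typical cell size (dead
#' eukaryotic cells, for instance, are commonly smaller than viable ones).
#'
#' @param rule A [threshold_rule()].
#' @param range A [size_range()].
#' @param exclusions Integer ids of objects to drop from the single-cell
#'   selection (see [exclude_objects()]).
#' @return An object of class `channel_params`.
#' @examples
#' channel_params(threshold_rule("single_channel", "red", 30),
#'                size_range(301, 600))
#' @export
channel_params <- function(rule, range, exclusions = integer(0)) {
  stopifnot(inherits(rule, "threshold_rule"), inherits(range, "size_range"))
  structure(list(rule = rule, range = range,
                 exclusions = as.integer(exclusions)),
            class = "channel_params")
}

#' Mean area of the selected single cells
#'
#' @param objects A [label_components()] result.
#' @param ids Non-empty integer vector of selected object ids.
#' @return Arithmetic mean of the selected object areas, in pixels.
#' @export
mean_single_cell_area <- function(objects, ids) {
  stopifnot(inherits(objects, "labeled_objects"))
  if (length(ids) == 0L)
    stop("no single cells selected: adjust the threshold T or the size ",
         "range [s_min, s_max] so that isolated cells fall inside the window")
  mean(objects$objects$area[match(ids, objects$objects$id)])
}

#' Effective cell count by area normalization
#'
#' The core statistic: total stained area divided by the mean single-cell
#' area, `N_eff = S / S_bar`. Clumps of adherent cells thus contribute in
#' proportion to their area instead of being miscounted as one object.
#'
#' @param total_area Total thresholded area S, in pixels (>= 0).
#' @param mean_area Mean single-cell area S_bar, in pixels (> 0).
#' @return `total_area / mean_area`, unrounded.
#' @examples
#' effective_count(1000, 100)  # 10 cells
#' @export
effective_count <- function(total_area, mean_area) {
  if (total_area < 0) stop("total_area must be >= 0")
  if (total_area == 0) return(0)
  if (!is.finite(mean_area) || mean_area <= 0)
    stop("mean single-cell area must be positive")
  total_area / mean_area
}

#' Quantify one staining channel of a micrograph
#'
#' Runs the full two-step per-channel pipeline: threshold, 8-connected
#' labeling, size-window selection, manual exclusions, mean single-cell area,
#' effective count. All intermediates are kept on the returned object.
#'
#' A channel with zero thresholded area yields `effective_count = 0` (and an
#' undefined mean area); a channel with stained area but no objects in the
#' size window raises the "no single cells selected" error.
#'
#' @param image An [rgb_image()].
#' @param params A [channel_params()] (or pass `rule`, `range`, `exclusions`
#'   directly through `...` as named arguments of [channel_params()]).
#' @return Object of class `channel_quant` with fields `channel`, `rule`,
#'   `range`, `total_area`, `objects`, `single_cell_ids`,
#'   `mean_single_cell_area`, `effective_count`.
#' @export
quantify_channel <- function(image, params) {
  stopifnot(inherits(image, "rgb_image"), inherits(params, "channel_params"))
  mask <- apply_threshold(image, params$rule)
  total_area <- mask_area(mask)
  objects <- label_components(mask)
  ids <- select_by_size(objects, params$range)
  ids <- exclude_objects(objects, ids, params$exclusions)
  if (total_area == 0) {
    mean_area <- NA_real_
    n_eff <- 0
  } else {
    mean_area <- mean_single_cell_area(objects, ids)
    n_eff <- effective_count(total_area, mean_area)
  }
  structure(list(channel = params$rule$channel, rule = params$rule,
                 range = params$range, total_area = total_area,
                 objects = objects, single_cell_ids = ids,
                 mean_single_cell_area = mean_area,
                 effective_count = n_eff),
            class = "channel_quant")
}

#' @export
print.channel_quant <- function(x, ...) {
  cat(sprintf("<channel_quant> %s channel, T = %d, size window [%g, %g]\n",
              x$channel, x$rule$T, x$range$s_min, x$range$s_max))
  cat(sprintf("  total stained area S  : %g px\n", x$total_area))
  n_single <- if (!is.null(x$single_cell_ids)) length(x$single_cell_ids)
              else x$n_single_cells
  cat(sprintf("  single cells selected : %d\n", n_single))
  cat(sprintf("  mean single-cell area : %s px\n",
              formatC(x$mean_single_cell_area, digits = 6)))
  cat(sprintf("  effective count N_eff : %s (~ %s cells)\n",
              formatC(x$effective_count, digits = 6),
              format(round(x$effective_count))))
  invisible(x)
}

.fraction_red <- function(n_red, n_green) {
  if (n_red + n_green <= 0) NA_real_ else n_red / (n_red + n_green)
}

#' Quantify red and green sub-populations of one micrograph
#'
#' Both channels are analysed independently on the same pixels (their own
#' threshold rule and size window) and the red — conventionally non-viable —
#' fraction is computed from the *effective counts*, not raw areas, so that
#' channel-specific cell sizes are respected.
#'
#' @param image An [rgb_image()].
#' @param red_params,green_params [channel_params()] for each channel.
#' @param image_id Text label carried into results.
#' @return Object of class `subpop_result` with fields `image_id`, `red`,
#'   `green` (both `channel_quant`) and `fraction_red` (`NA` when both
#'   effective counts are zero — the fraction is then undefined, not 0).
#' @export
quantify_image <- function(image, red_params, green_params,
                           image_id = "image") {
  red <- quantify_channel(image, red_params)
  green <- quantify_channel(image, green_params)
  structure(list(image_id = image_id, red = red, green = green,
                 fraction_red = .fraction_red(red$effective_count,
                                              green$effective_count)),
            class = "subpop_result")
}

#' @export
print.subpop_result <- function(x, ...) {
  cat(sprintf("<subpop_result> '%s'\n", x$image_id))
  cat(sprintf("  N_Reff = %.2f, N_Geff = %.2f\n",
              x$red$effective_count, x$green$effective_count))
  if (is.na(x$fraction_red)) {
    cat("  fraction red: undefined (no stained cells in either channel)\n")
  } else {
    cat(sprintf("  fraction red (non-viable): %.3f (%.1f%%)\n",
                x$fraction_red, 100 * x$fraction_red))
  }
  invisible(x)
}

#' Quantify a confocal Z-stack slice-wise with pooled statistics
#'
#' Each slice is analysed as an independent 2D image with shared parameters;
#' per-slice stained areas are summed and the single-cell selections of all
#' slices are pooled before taking the mean, so
#' `N_eff = sum_z S_z / mean(pooled single-cell areas)`. A cell spanning
#' several slices is counted once per slice — the documented consequence of
#' strictly 2D analysis.
#'
#' @param stack An [image_stack()].
#' @param red_params,green_params Shared [channel_params()].
#' @return A `subpop_result`; its `red`/`green` components additionally carry
#'   `per_slice_area` and `n_slices`.
#' @export
quantify_stack <- function(stack, red_params, green_params) {
  stopifnot(inherits(stack, "image_stack"))
  pool <- function(params) {
    areas <- numeric(length(stack$slices))
    single_areas <- numeric(0)
    for (z in seq_along(stack$slices)) {
      mask <- apply_threshold(stack$slices[[z]], params$rule)
      areas[z] <- mask_area(mask)
      objects <- label_components(mask)
      ids <- select_by_size(objects, params$range)
      ids <- exclude_objects(objects, ids, params$exclusions)
      single_areas <- c(single_areas,
                        objects$objects$area[match(ids, objects$objects$id)])
    }
    total <- sum(areas)
    if (total == 0) {
      mean_area <- NA_real_; n_eff <- 0
    } else {
      if (length(single_areas) == 0L)
        stop("no single cells selected in any slice: adjust the threshold T ",
             "or the size range [s_min, s_max]")
      mean_area <- mean(single_areas)
      n_eff <- effective_count(total, mean_area)
    }
    structure(list(channel = params$rule$channel, rule = params$rule,
                   range = params$range, total_area = total,
                   per_slice_area = areas, n_slices = length(areas),
                   single_cell_ids = NULL,
                   n_single_cells = length(single_areas),
                   mean_single_cell_area = mean_area,
                   effective_count = n_eff),
              class = "channel_quant")
  }
  red <- pool(red_params)
  green <- pool(green_params)
  structure(list(image_id = stack$source_id, red = red, green = green,
                 fraction_red = .fraction_red(red$effective_count,
                                              green$effective_count)),
            class = "subpop_result")
}

#' Batch analysis of an image series with fixed parameters
#'
#' The unattended second step of the workflow: once parameters are fixed on
#' representative images, a whole series of similar fields of view is
#' analysed with no further adjustment. Unreadable or failing images are
#' recorded and skipped; the rest of the series still completes. No cap on
#' the series length is enforced.
#'
#' @param images List of [rgb_image()] objects and/or file paths.
#' @param red_params,green_params Shared [channel_params()].
#' @param image_ids Labels; defaults to file names or `image_<i>`.
#' @return List of class `batch_result`: `results` (one `subpop_result` per
#'   successful image, in input order) and `failures` (named character vector
#'   of error messages keyed by image id).
#' @export
batch_quantify <- function(images, red_params, green_params,
                           image_ids = NULL) {
  if (is.null(image_ids))
    image_ids <- vapply(seq_along(images), function(i) {
      if (is.character(images[[i]])) basename(images[[i]])
      else sprintf("image_%03d", i)
    }, character(1))
  results <- list()
  failures <- character(0)
  for (i in seq_along(images)) {
    res <- tryCatch({
      img <- images[[i]]
      if (is.character(img)) img <- load_image(img)
      quantify_image(img, red_params, green_params, image_id = image_ids[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[image_ids[i]] <- conditionMessage(res)
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  structure(list(results = results, failures = failures),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> %d image(s) analysed, %d failure(s)\n",
              length(x$results), length(x$failures)))
  for (nm in names(x$failures))
    cat(sprintf("  FAILED %s: %s\n", nm, x$failures[[nm]]))
  invisible(x)
}

#' Flatten quantification results into a report table
#'
#' One row per (image, channel). Effective counts are kept fractional;
#' a rounded integer companion column is provided for reporting.
#'
#' @param results A `subpop_result`, a list of them, or a `batch_result`.
#' @return Data frame with columns `image_id`, `channel`, `T`, `s_min`,
#'   `s_max`, `total_area`, `n_single_cells`, `mean_cell_area`,
#'   `effective_count`, `effective_count_rounded`, `fraction_red`.
#' @export
results_table <- function(results) {
  if (inherits(results, "subpop_result")) results <- list(results)
  if (inherits(results, "batch_result")) results <- results$results
  rows <- lapply(results, function(r) {
    do.call(rbind, lapply(list(r$red, r$green), function(q) {
      n_single <- if (!is.null(q$single_cell_ids))
        length(q$single_cell_ids) else q$n_single_cells
      data.frame(image_id = r$image_id, channel = q$channel, T = q$rule$T,
                 s_min = q$range$s_min, s_max = q$range$s_max,
                 total_area = q$total_area, n_single_cells = n_single,
                 mean_cell_area = q$mean_single_cell_area,
                 effective_count = q$effective_count,
                 effective_count_rounded = round(q$effective_count),
                 fraction_red = r$fraction_red)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
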