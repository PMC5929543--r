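#' Specification of a synthetic two-channel stained micrograph
#'
#' The generator emulates live/dead-stained micrographs: viable cells
#' fluoresce green, membrane-compromised cells red. Cells are drawn as
#' filled disks (coccal morphology), capsules with random orientation (rods)
#' or ellipses (eukaryotic cells), with centre-bright radial intensity
#' falloff (`peak * (1 - r)^falloff`) so that the detection threshold
#' genuinely interacts with apparent object size — the coupling the
#' threshold/size-balance procedure exists to resolve. Additive Gaussian
#' background noise and optional Gaussian blur complete the image.
#'
#' Default geometries: coccus mean area 450 px (single-cell bin 301–600),
#' rod 1400 px and eukaryote 1500 px (bin 1001–2000).
#'
#' @param height,width Image size in pixels.
#' @param morphology `"coccus"`, `"rod"` or `"eukaryote"`.
#' @param n_cells Number of cells to place.
#' @param dead_fraction Probability that a cell is non-viable (red).
#' @param mean_area Nominal mean cell area in pixels; default by morphology
#'   (450 / 1400 / 1500).
#' @param area_rel_sd Relative standard deviation of cell area; default 0.15.
#' @param overlap Fraction of cells placed adjacent to an existing cell so
#'   their supports overlap; the rest are placed disjoint.
#' @param peak_intensity Centre intensity (<= 255); default 220.
#' @param falloff Radial falloff exponent; default 0.5.
#' @param noise_sd Additive Gaussian noise standard deviation in intensity
#'   units; default 5.
#' @param blur_sigma Optional Gaussian blur sigma in pixels (`NULL` = none).
#' @param seed Integer RNG seed; generation is deterministic given the spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(height = 512, width = 512,
                           morphology = c("coccus", "rod", "eukaryote"),
                           n_cells = 60, dead_fraction = 0.3,
                           mean_area = NULL, area_rel_sd = 0.15,
                           overlap = 0.2, peak_intensity = 220,
                           falloff = 0.5, noise_sd = 5, blur_sigma = NULL,
                           seed = 1L) {
  morphology <- match.arg(morphology)
  if (is.null(mean_area))
    mean_area <- switch(morphology, coccus = 450, rod = 1400,
                        eukaryote = 1500)
  stopifnot(n_cells >= 0, dead_fraction >= 0, dead_fraction <= 1,
            overlap >= 0, overlap <= 1, peak_intensity <= 255,
            peak_intensity > 0, noise_sd >= 0, mean_area > 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 morphology = morphology, n_cells = as.integer(n_cells),
                 dead_fraction = dead_fraction, mean_area = mean_area,
                 area_rel_sd = area_rel_sd, overlap = overlap,
                 peak_intensity = peak_intensity, falloff = falloff,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %dx%d px, %d %s cell(s), dead fraction %.2f\n",
    x$height, x$width, x$n_cells, x$morphology, x$dead_fraction))
  cat(sprintf(
    "  mean area %g px (rel sd %.2f), overlap %.2f, peak %g, noise sd %g\n",
    x$mean_area, x$area_rel_sd, x$overlap, x$peak_intensity, x$noise_sd))
  invisible(x)
}

# normalized distance field (0 at centre, 1 at boundary) on a local grid
.shape_distance <- function(morphology, area, theta, rows, cols, cy, cx) {
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  if (morphology == "coccus") {
    R <- sqrt(area / pi)
    sqrt(dy^2 + dx^2) / R
  } else if (morphology == "rod") {
    # capsule, total length = 4 x width: area = 3w^2 + pi (w/2)^2
    w0 <- sqrt(area / (3 + pi / 4))
    r <- w0 / 2
    half <- 1.5 * w0                       # rectangle half-length
    ux <- cos(theta); uy <- sin(theta)
    t <- pmin(pmax(dy * uy + dx * ux, -half), half)
    px <- t * ux; py <- t * uy
    sqrt((dy - py)^2 + (dx - px)^2) / r
  } else {                                 # eukaryote: 1.5:1 ellipse
    ar <- 1.5
    a <- sqrt(area * ar / pi)
    b <- sqrt(area / (ar * pi))
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    sqrt((u / a)^2 + (v / b)^2)
  }
}

# bounding radius of the shape, for placement margins
.shape_radius <- function(morphology, area) {
  if (morphology == "coccus") sqrt(area / pi)
  else if (morphology == "rod") {
    w0 <- sqrt(area / (3 + pi / 4))
    1.5 * w0 + w0 / 2
  } else sqrt(area * 1.5 / pi)
}

# render the noiseless cell population; RNG state is the caller's
.render_population <- function(spec) {
  h <- spec$height; w <- spec$width
  red <- matrix(0, h, w); green <- matrix(0, h, w)
  occupied <- matrix(FALSE, h, w)
  n <- spec$n_cells
  is_red <- if (n > 0) stats::rbinom(n, 1, spec$dead_fraction) == 1 else
    logical(0)
  areas <- pmax(stats::rnorm(n, spec$mean_area,
                             spec$area_rel_sd * spec$mean_area), 20)
  cells <- vector("list", n)
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    theta <- stats::runif(1, 0, pi)
    rb <- ceiling(.shape_radius(spec$morphology, areas[i])) + 1L
    if (2 * rb + 2 >= min(h, w))
      stop("cell larger than the image; enlarge height/width")
    place_touching <- i > 1 && stats::runif(1) < spec$overlap
    placed <- FALSE
    for (attempt in seq_len(1000L)) {
      if (place_touching) {
        j <- sample.int(i - 1L, 1L)
        rbj <- .shape_radius(spec$morphology, areas[j])
        d <- stats::runif(1, 0.5, 0.9) * (rb + rbj)
        phi <- stats::runif(1, 0, 2 * pi)
        cy <- round(centers[j, 1] + d * sin(phi))
        cx <- round(centers[j, 2] + d * cos(phi))
        if (cy < rb + 1 || cy > h - rb || cx < rb + 1 || cx > w - rb) next
      } else {
        cy <- sample.int(h - 2L * rb, 1L) + rb
        cx <- sample.int(w - 2L * rb, 1L) + rb
      }
      rows <- (cy - rb):(cy + rb)
      cols <- (cx - rb):(cx + rb)
      dn <- .shape_distance(spec$morphology, areas[i], theta, rows, cols,
                            cy, cx)
      intensity <- round(spec$peak_intensity * pmax(1 - dn, 0)^spec$falloff)
      foot <- intensity >= 1
      if (!any(foot)) next
      if (!place_touching) {
        # require 1-pixel clearance so disjoint cells never become 8-adjacent
        dil <- foot
        for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                        c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
          sr <- sh[1]; sc <- sh[2]
          shifted <- matrix(FALSE, nrow(foot), ncol(foot))
          rs <- max(1, 1 + sr):min(nrow(foot), nrow(foot) + sr)
          cs <- max(1, 1 + sc):min(ncol(foot), ncol(foot) + sc)
          shifted[rs, cs] <- foot[rs - sr, cs - sc]
          dil <- dil | shifted
        }
        if (any(occupied[rows, cols] & dil)) next
      }
      plane <- if (is_red[i]) red else green
      plane[rows, cols] <- pmax(plane[rows, cols], intensity * foot)
      if (is_red[i]) red <- plane else green <- plane
      occupied[rows, cols] <- occupied[rows, cols] | foot
      lin <- which(foot)
      cells[[i]] <- list(
        channel = if (is_red[i]) "red" else "green",
        center = c(row = cy, col = cx),
        area = length(lin),
        pixels = (rows[((lin - 1) %% length(rows)) + 1]) +
          (cols[((lin - 1) %/% length(rows)) + 1] - 1) * h)
      centers[i, ] <- c(cy, cx)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place cell ", i, " within 1000 attempts; ",
           "reduce n_cells or enlarge the image")
  }
  list(red = red, green = green, cells = cells,
       true_n_red = sum(is_red), true_n_green = sum(!is_red))
}

.finish_image <- function(spec, red, green) {
  h <- spec$height; w <- spec$width
  noisy <- function(m) {
    if (spec$noise_sd > 0)
      m <- m + stats::rnorm(h * w, 0, spec$noise_sd)
    matrix(pmin(pmax(round(m), 0), 255), h, w)
  }
  img <- rgb_image(noisy(red), noisy(green), noisy(matrix(0, h, w)))
  if (!is.null(spec$blur_sigma)) img <- gaussian_filter(img, spec$blur_sigma)
  img
}

.truth_of <- function(pop) {
  cells <- pop$cells
  per_cell <- data.frame(
    channel = vapply(cells, `[[`, character(1), "channel"),
    center_row = vapply(cells, function(c) c$center[["row"]], numeric(1)),
    center_col = vapply(cells, function(c) c$center[["col"]], numeric(1)),
    area = vapply(cells, `[[`, numeric(1), "area"))
  structure(list(true_n_red = pop$true_n_red,
                 true_n_green = pop$true_n_green,
                 per_cell = per_cell,
                 footprints = lapply(cells, `[[`, "pixels")),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d red + %d green cell(s)\n",
              x$true_n_red, x$true_n_green))
  invisible(x)
}

#' Generate a synthetic stained micrograph with ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `image` (an [rgb_image()]) and `truth`
#'   (class `ground_truth`: `true_n_red`, `true_n_green`, `per_cell` data
#'   frame, and per-cell `footprints` as linear pixel indices into the
#'   noiseless support).
#' @examples
#' out <- generate_micrograph(synthetic_spec(n_cells = 10, seed = 7,
#'                                           height = 128, width = 128))
#' out$truth
#' @export
generate_micrograph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  pop <- .render_population(spec)
  list(image = .finish_image(spec, pop$red, pop$green),
       truth = .truth_of(pop))
}

#' Generate a synthetic confocal Z-stack
#'
#' The same cell population is rendered on every slice with per-slice
#' multiplicative intensity jitter and fresh noise, emulating defocus
#' aberration across optical sections. With `slice_jitter = 0` all slices
#' are identical (one rendering, replicated). Truth counts are per slice.
#'
#' @param spec A [synthetic_spec()]; `blur_sigma` applies per slice.
#' @param n_slices Number of Z slices (>= 1).
#' @param slice_jitter Relative sd of the per-slice intensity scale.
#' @return List with `stack` (an [image_stack()]) and `truth`.
#' @export
generate_stack <- function(spec, n_slices = 12, slice_jitter = 0.1) {
  stopifnot(inherits(spec, "synthetic_spec"), n_slices >= 1)
  set.seed(spec$seed)
  pop <- .render_population(spec)
  if (slice_jitter == 0) {
    slice <- .finish_image(spec, pop$red, pop$green)
    slices <- rep(list(slice), n_slices)
  } else {
    slices <- lapply(seq_len(n_slices), function(z) {
      scale <- min(max(1 + stats::rnorm(1, 0, slice_jitter), 0.5), 1.5)
      .finish_image(spec, pop$red * scale, pop$green * scale)
    })
  }
  list(stack = image_stack(slices,
                           source_id = sprintf("synthetic_stack_seed%d",
                                               spec$seed)),
       truth = .truth_of(pop))
}

#' Generate a reproducible benchmark suite of synthetic micrographs
#'
#' Images spanning a set of target dead fractions, each generated with its
#' own seed derived deterministically from the master seed, so the suite is
#' reproducible piecewise (regenerating image i alone gives the same image).
#'
#' @param spec_template A [synthetic_spec()]; its `dead_fraction` and `seed`
#'   are overridden per image.
#' @param dead_fractions Target dead fractions, recycled to `n_images`.
#' @param n_images Number of images; default `length(dead_fractions)`.
#' @param seed Master seed.
#' @return List of class `benchmark_suite`; each element has `image`,
#'   `truth` and `spec`.
#' @export
benchmark_suite <- function(spec_template = synthetic_spec(),
                            dead_fractions = seq(0.1, 0.9, length.out = 20),
                            n_images = length(dead_fractions),
                            seed = 1L) {
  stopifnot(inherits(spec_template, "synthetic_spec"), n_images >= 1)
  fracs <- rep_len(dead_fractions, n_images)
  out <- lapply(seq_len(n_images), function(i) {
    sp <- spec_template
    sp$dead_fraction <- fracs[i]
    sp$seed <- as.integer((as.numeric(seed) * 1009 + 7919 * i) %% 2147483647)
    c(generate_micrograph(sp), list(spec = sp))
  })
  class(out) <- "benchmark_suite"
  out
}
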