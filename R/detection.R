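#' Threshold rule for stained-pixel detection
#'
#' Detection marks a pixel as "stained" when a per-pixel statistic strictly
#' exceeds an integer threshold `T`. Three rule families are supported:
#' \describe{
#'   \item{`single_channel`}{statistic = the primary channel intensity.}
#'   \item{`differential`}{statistic = primary minus counterpart channel,
#'     signed (not clipped at zero). The counterpart of red is green and vice
#'     versa — the two staining channels. A differential rule with blue
#'     primary subtracts the maximum of red and green; this is a documented
#'     extension, not used by default.}
#'   \item{`intensity`}{statistic = mean of (R, G, B), rounded half-up, so the
#'     statistic stays integral.}
#' }
#'
#' @param mode One of `"single_channel"`, `"differential"`, `"intensity"`.
#' @param channel Primary channel, one of `"red"`, `"green"`, `"blue"`.
#'   Ignored for `mode = "intensity"`.
#' @param T Integer threshold in \[0, 255\]; pixels with statistic equal to
#'   `T` are *not* selected (strict inequality).
#' @return An object of class `threshold_rule`.
#' @examples
#' threshold_rule("differential", "red", T = 30)
#' @export
threshold_rule <- function(mode = c("single_channel", "differential",
                                    "intensity"),
                           channel = c("red", "green", "blue"), T = 30L) {
  mode <- match.arg(mode)
  channel <- match.arg(channel)
  if (length(T) != 1L || is.na(T) || T < 0 || T > 255 || T != trunc(T))
    stop("threshold T must be a single integer in [0, 255]")
  structure(list(mode = mode, channel = channel, T = as.integer(T)),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  desc <- switch(x$mode,
    single_channel = sprintf("I_%s > %d", toupper(substr(x$channel, 1, 1)),
                             x$T),
    differential = {
      other <- switch(x$channel, red = "G", green = "R", blue = "max(R,G)")
      sprintf("I_%s - I_%s > %d", toupper(substr(x$channel, 1, 1)), other,
              x$T)
    },
    intensity = sprintf("mean(R,G,B) > %d", x$T))
  cat(sprintf("<threshold_rule> %s (%s)\n", desc, x$mode))
  invisible(x)
}

# per-pixel rule statistic as an integer matrix (may be negative for
# differential rules)
rule_statistic <- function(image, rule) {
  switch(rule$mode,
    single_channel = image[[rule$channel]],
    differential = {
      counterpart <- switch(rule$channel,
        red = image$green,
        green = image$red,
        blue = pmax(image$red, image$green))
      image[[rule$channel]] - counterpart
    },
    intensity = {
      s <- image$red + image$green + image$blue
      # mean rounded half-up: floor(x + 1/2) = (2s + 3) %/% 6
      (2L * s + 3L) %/% 6L
    })
}

#' Threshold an image into a binary mask of stained pixels
#'
#' @param image An [rgb_image()].
#' @param rule A [threshold_rule()].
#' @return A logical matrix of the image's shape; `TRUE` marks pixels whose
#'   rule statistic strictly exceeds the threshold.
#' @examples
#' img <- rgb_image(matrix(100L, 1, 1), matrix(50L, 1, 1), matrix(0L, 1, 1))
#' apply_threshold(img, threshold_rule("differential", "red", 30))
#' @export
apply_threshold <- function(image, rule) {
  stopifnot(inherits(image, "rgb_image"), inherits(rule, "threshold_rule"))
  rule_statistic(image, rule) > rule$T
}

#' Total stained area of a mask, in pixels
#'
#' @param mask Logical matrix from [apply_threshold()].
#' @return Number of selected pixels (the S_R / S_G numerators of the
#'   effective count).
#' @export
mask_area <- function(mask) {
  stopifnot(is.logical(mask))
  sum(mask)
}
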