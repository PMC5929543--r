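test_that("mean single-cell area is the arithmetic mean of selected areas", {
  fake <- structure(list(objects = data.frame(id = 1:2, area = c(500, 600))),
                    class = "labeled_objects")
  expect_equal(mean_single_cell_area(fake, 1:2), 550)
  one <- structure(list(objects = data.frame(id = 1L, area = 317)),
                   class = "labeled_objects")
  expect_equal(mean_single_cell_area(one, 1L), 317)
  set.seed(8)
  areas <- sample(50:2000, 50)
  many <- structure(list(objects = data.frame(id = 1:50, area = areas)),
                    class = "labeled_objects")
  ids <- sample(1:50, 20)
  expect_equal(mean_single_cell_area(many, ids), sum(areas[ids]) / 20)
})

test_that("effective count divides total area by mean single-cell area", {
  expect_equal(effective_count(1000, 100), 10)
  expect_equal(effective_count(0, 100), 0)
  expect_equal(effective_count(0, NA), 0)        # empty channel needs no mean
  # 12 disjoint 317-px cells plus a 3-cell clump of union area 850
  expect_equal(effective_count(12 * 317 + 850, 317), 14.68, tolerance = 0.01 / 14.68)
  expect_error(effective_count(100, 0), "positive")
  expect_error(effective_count(-1, 10), ">= 0")
})

test_that("quantify_channel is exact on identical disjoint single cells", {
  set.seed(2)
  centers <- as.matrix(expand.grid(seq(15, 105, by = 30), seq(15, 135, by = 30)))
  centers <- centers[1:10, ]
  img <- disk_image(120, 150, centers, radius = 11, value = 200L)
  lab <- label_components(apply_threshold(
    img, threshold_rule("single_channel", "red", 100)))
  A <- lab$objects$area[1]                       # identical pixelated disks
  expect_true(all(lab$objects$area == A))
  q <- quantify_channel(img, params_single("red", 100, A - 50, A + 50))
  expect_identical(q$effective_count, 10)
  expect_equal(q$total_area, 10 * A)
  # a window excluding every object fails loudly
  expect_error(quantify_channel(img, params_single("red", 100, A + 1, A + 100)),
               "no single cells")
})

test_that("an overlapped pair contributes clump_area / mean_area cells", {
  centers <- as.matrix(expand.grid(seq(15, 105, by = 30), seq(15, 105, by = 30)))
  centers <- centers[1:8, ]
  img8 <- disk_image(160, 120, centers, radius = 11)
  lab8 <- label_components(apply_threshold(
    img8, threshold_rule("single_channel", "red", 100)))
  A <- lab8$objects$area[1]
  # measure the union area of the overlapping pair independently
  pair <- disk_image(160, 120, rbind(c(140, 40), c(148, 48)), radius = 11)
  union_area <- mask_area(apply_threshold(
    pair, threshold_rule("single_channel", "red", 100)))
  expect_true(union_area > A && union_area < 2 * A)
  both <- rgb_image(pmax(img8$red, pair$red), img8$green, img8$blue)
  q <- quantify_channel(both, params_single("red", 100, A, A))
  expect_equal(q$effective_count, 8 + union_area / A, tolerance = 1e-12)
})

test_that("quantify_image combines channels into the red fraction", {
  set.seed(4)
  red_part <- disk_image(100, 200, cbind(c(25, 25), c(30, 90)), radius = 11,
                         channel = "red")
  green_part <- disk_image(100, 200, rbind(c(70, 40), c(70, 100), c(70, 160)),
                           radius = 11, channel = "green")
  img <- rgb_image(red_part$red, green_part$green, red_part$blue)
  lab <- label_components(apply_threshold(
    img, threshold_rule("single_channel", "red", 50)))
  A <- lab$objects$area[1]
  res <- quantify_image(img, params_single("red", 50, A, A),
                        params_single("green", 50, A, A), image_id = "mix")
  expect_equal(res$red$effective_count, 2)
  expect_equal(res$green$effective_count, 3)
  expect_equal(res$fraction_red, 0.4)
  # zero red cells -> fraction 0; both channels empty -> undefined, not 0
  dark <- rgb_image(matrix(0L, 20, 20))
  res0 <- quantify_image(
    rgb_image(matrix(0L, 100, 200), green_part$green, red_part$blue),
    params_single("red", 50, A, A), params_single("green", 50, A, A))
  expect_equal(res0$fraction_red, 0)
  resNA <- quantify_image(dark, params_single("red", 50, 1, 10),
                          params_single("green", 50, 1, 10))
  expect_true(is.na(resNA$fraction_red))
  expect_equal(resNA$red$effective_count, 0)
})

test_that("fraction_red follows effective counts (N_R=5, N_G=15 -> 0.25)", {
  expect_equal(effcount:::.fraction_red(5, 15), 0.25)
  expect_equal(effcount:::.fraction_red(0, 7), 0)
  expect_true(is.na(effcount:::.fraction_red(0, 0)))
})

test_that("duplicating an image side by side doubles the effective count", {
  out <- generate_micrograph(synthetic_spec(height = 128, width = 128,
                                            n_cells = 8, overlap = 0,
                                            noise_sd = 0, seed = 21))
  img <- out$image
  wide <- rgb_image(cbind(img$red, img$red), cbind(img$green, img$green),
                    cbind(img$blue, img$blue))
  p <- params_single("green", 30, 200, 600)
  q1 <- quantify_channel(img, p)
  q2 <- quantify_channel(wide, p)
  expect_equal(q2$total_area, 2 * q1$total_area)
  expect_equal(q2$mean_single_cell_area, q1$mean_single_cell_area)
  expect_equal(q2$effective_count, 2 * q1$effective_count)
})

test_that("stack quantification pools areas and single-cell statistics", {
  out <- generate_micrograph(synthetic_spec(height = 128, width = 128,
                                            n_cells = 10, dead_fraction = 0.4,
                                            overlap = 0, noise_sd = 0,
                                            seed = 33))
  p_red <- params_single("red", 30, 200, 600)
  p_green <- params_single("green", 30, 200, 600)
  single <- quantify_image(out$image, p_red, p_green)
  st <- image_stack(rep(list(out$image), 3), source_id = "tripled")
  pooled <- quantify_stack(st, p_red, p_green)
  expect_equal(pooled$red$total_area, 3 * single$red$total_area)
  expect_equal(pooled$green$total_area, 3 * single$green$total_area)
  expect_equal(pooled$fraction_red, single$fraction_red)
  expect_equal(pooled$red$effective_count, 3 * single$red$effective_count)
  # 1-slice stack is identical to single-image analysis
  one <- quantify_stack(image_stack(list(out$image)), p_red, p_green)
  expect_equal(one$red$effective_count, single$red$effective_count)
  expect_equal(one$fraction_red, single$fraction_red)
  # pooled S equals the sum of per-slice S on an inhomogeneous stack
  gen <- generate_stack(synthetic_spec(height = 96, width = 96, n_cells = 6,
                                       noise_sd = 3, seed = 5),
                        n_slices = 4, slice_jitter = 0.15)
  ps <- quantify_stack(gen$stack, params_single("red", 25, 100, 600),
                       params_single("green", 25, 100, 600))
  per_slice <- vapply(gen$stack$slices, function(s)
    mask_area(apply_threshold(s, threshold_rule("single_channel", "green", 25))),
    numeric(1))
  expect_equal(ps$green$total_area, sum(per_slice))
})

test_that("batch analysis isolates failures and is deterministic", {
  d <- tempfile(); dir.create(d)
  for (i in 1:3) {
    out <- generate_micrograph(synthetic_spec(height = 128, width = 128,
                                              n_cells = 10, seed = i,
                                              dead_fraction = 0.5))
    write_image(out$image, file.path(d, sprintf("img%d.png", i)))
  }
  bad <- file.path(d, "broken.png")
  writeLines("not a png", bad)
  files <- c(file.path(d, sprintf("img%d.png", 1:3)), bad)
  p_red <- params_single("red", 30, 200, 600)
  p_green <- params_single("green", 30, 200, 600)
  b <- batch_quantify(files, p_red, p_green)
  expect_length(b$results, 3)
  expect_length(b$failures, 1)
  expect_named(b$failures, "broken.png")
  expect_identical(vapply(b$results, `[[`, character(1), "image_id"),
                   sprintf("img%d.png", 1:3))
  # rerunning the identical series yields identical outputs
  b2 <- batch_quantify(files, p_red, p_green)
  expect_identical(results_table(b), results_table(b2))
  unlink(d, recursive = TRUE)
})

test_that("the results table carries one row per image and channel", {
  out <- generate_micrograph(synthetic_spec(height = 128, width = 128,
                                            n_cells = 10, dead_fraction = 0.5,
                                            seed = 2))
  res <- quantify_image(out$image, params_single("red", 30, 200, 600),
                        params_single("green", 30, 200, 600), "one")
  tab <- results_table(res)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$channel, c("red", "green"))
  expect_true(all(c("image_id", "T", "s_min", "s_max", "total_area",
                    "n_single_cells", "mean_cell_area", "effective_count",
                    "fraction_red") %in% names(tab)))
  expect_equal(tab$effective_count_rounded, round(tab$effective_count))
  # effective_count x mean area recovers the total area
  expect_equal(tab$effective_count * tab$mean_cell_area, tab$total_area,
               tolerance = 1e-9)
})
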