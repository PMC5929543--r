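test_that("labeling handles the degenerate and diagonal cases", {
  lab <- label_components(matrix(FALSE, 5, 5))
  expect_equal(nrow(lab$objects), 0)
  expect_true(all(lab$label_map == 0L))

  # two diagonal pixels are one object under 8-connectivity
  m <- matrix(FALSE, 3, 3)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE
  lab <- label_components(m)
  expect_equal(nrow(lab$objects), 1)
  expect_equal(lab$objects$area, 2)
  # and the same pixels under a one-column gap are two objects
  m2 <- matrix(FALSE, 3, 4)
  m2[1, 1] <- TRUE; m2[3, 3] <- TRUE
  expect_equal(nrow(label_components(m2)$objects), 2)
})

test_that("labeling agrees with the flood-fill oracle on random masks", {
  set.seed(99)
  for (i in 1:40) {
    density <- runif(1, 0.2, 0.7)
    mask <- matrix(runif(32 * 32) < density, 32, 32)
    lab <- label_components(mask)
    oracle <- flood_fill_labels(mask)
    expect_true(same_partition(lab$label_map, oracle))
    expect_equal(max(lab$label_map), nrow(lab$objects))
    # conservation: object areas sum to the mask area
    expect_equal(sum(lab$objects$area), mask_area(mask))
  }
})

test_that("labels are consecutive and ordered by raster-scan first pixel", {
  set.seed(5)
  mask <- matrix(runif(400) < 0.3, 20, 20)
  lab <- label_components(mask)
  K <- nrow(lab$objects)
  expect_identical(lab$objects$id, seq_len(K))
  # first pixel (row-major) of label k must precede that of label k+1
  first_px <- vapply(seq_len(K), function(k) {
    w <- which(t(lab$label_map) == k)  # row-major positions
    min(w)
  }, numeric(1))
  expect_true(all(diff(first_px) > 0))
})

test_that("object measurements are consistent with the label map", {
  set.seed(17)
  mask <- matrix(runif(900) < 0.35, 30, 30)
  lab <- label_components(mask)
  for (k in sample(lab$objects$id, min(5, nrow(lab$objects)))) {
    px <- which(lab$label_map == k, arr.ind = TRUE)
    ob <- lab$objects[k, ]
    expect_equal(ob$area, nrow(px))
    expect_equal(ob$row_min, min(px[, 1])); expect_equal(ob$row_max, max(px[, 1]))
    expect_equal(ob$col_min, min(px[, 2])); expect_equal(ob$col_max, max(px[, 2]))
    expect_equal(ob$centroid_row, mean(px[, 1]))
    expect_equal(ob$centroid_col, mean(px[, 2]))
  }
})

test_that("size selection is inclusive at both window ends", {
  img <- disk_image(40, 160, cbind(c(20, 20, 20), c(25, 75, 125)), radius = 9)
  lab <- label_components(apply_threshold(
    img, threshold_rule("single_channel", "red", 100)))
  areas <- sort(lab$objects$area)
  expect_equal(length(areas), 3)
  a <- areas[1]                                  # all three disks identical
  expect_setequal(select_by_size(lab, size_range(a, a)), lab$objects$id)
  expect_length(select_by_size(lab, size_range(a + 1, a + 10)), 0)
  expect_length(select_by_size(lab, size_range(1, a - 1)), 0)
  # synthetic areas framing the window: {499,500,1000,1001} vs [500,1000]
  fake <- structure(list(objects = data.frame(
    id = 1:4, area = c(499, 500, 1000, 1001))), class = "labeled_objects")
  expect_identical(select_by_size(fake, size_range(500, 1000)), 2:3)
  # identity selection
  expect_identical(select_by_size(fake, size_range(1, 1001)), 1:4)
})

test_that("manual exclusions behave as a validated set difference", {
  fake <- structure(list(objects = data.frame(id = 1:3, area = c(10, 20, 30))),
                    class = "labeled_objects")
  expect_identical(exclude_objects(fake, 1:3, 2L), c(1L, 3L))
  expect_identical(exclude_objects(fake, 1:3, integer(0)), 1:3)
  expect_length(exclude_objects(fake, 1:3, 1:3), 0)
  expect_error(exclude_objects(fake, 1:3, 7L), "unknown object id.*7")
  # excluding the whole selection makes the mean-size step fail loudly
  expect_error(mean_single_cell_area(fake, integer(0)), "no single cells")
})

test_that("object size histograms bin inclusively and conserve totals", {
  fake <- structure(list(objects = data.frame(
    id = 1:4, area = c(50, 350, 350, 5000))), class = "labeled_objects")
  h <- object_size_histogram(fake, size_bins())
  expect_equal(h$count, c(1, 2, 0, 0, 1))
  expect_equal(sum(h$total_area), sum(fake$objects$area))
  # bin-edge membership: inclusive lower and upper bounds
  edges <- structure(list(objects = data.frame(
    id = 1:4, area = c(300, 301, 600, 601))), class = "labeled_objects")
  expect_equal(object_size_histogram(edges)$count, c(1, 2, 1, 0, 0))
  # empty labeling -> all-zero histogram
  lab0 <- label_components(matrix(FALSE, 3, 3))
  h0 <- object_size_histogram(lab0)
  expect_true(all(h0$count == 0) && all(h0$total_area == 0))
  # random labeling: per-bin totals re-binned by brute force
  set.seed(31)
  mask <- matrix(runif(2500) < 0.45, 50, 50)
  lab <- label_components(mask)
  bins <- size_bins(c(2, 5, 20))
  h <- object_size_histogram(lab, bins)
  for (i in seq_len(nrow(bins))) {
    inb <- lab$objects$area >= bins$lo[i] & lab$objects$area <= bins$hi[i]
    expect_equal(h$count[i], sum(inb))
    expect_equal(h$total_area[i], sum(lab$objects$area[inb]))
  }
  expect_equal(sum(h$total_area), mask_area(mask))
})

test_that("invalid bins and size ranges are rejected", {
  expect_error(size_bins(c(300, 300)), "strictly increasing")
  expect_error(size_range(0, 10), "s_min")
  expect_error(size_range(10, 5), "s_min")
  fake <- structure(list(objects = data.frame(id = 1L, area = 10)),
                    class = "labeled_objects")
  bad <- data.frame(lo = c(1, 500), hi = c(300, Inf))  # gap 301..499
  expect_error(object_size_histogram(fake, bad), "contiguous")
})
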