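# Independent oracles and small fixture builders, kept deliberately naive.

# Recursive flood-fill connected-components oracle, 8-connectivity.
# Independent of the package's run-length union-find implementation.
flood_fill_labels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  next_label <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    next_label <- next_label + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- next_label
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- next_label
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# do two label maps define the same partition of the foreground?
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  fg <- a > 0
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# paint a uniform-intensity disk onto a matrix, returning the matrix
draw_disk <- function(m, cy, cx, radius, value) {
  h <- nrow(m); w <- ncol(m)
  for (r in max(1, cy - radius):min(h, cy + radius))
    for (c in max(1, cx - radius):min(w, cx + radius))
      if ((r - cy)^2 + (c - cx)^2 <= radius^2) m[r, c] <- value
  m
}

# image of uniform disks on black background in one channel
disk_image <- function(h, w, centers, radius, value = 200L,
                       channel = "red") {
  m <- matrix(0L, h, w)
  for (i in seq_len(nrow(centers)))
    m <- draw_disk(m, centers[i, 1], centers[i, 2], radius, value)
  z <- matrix(0L, h, w)
  if (channel == "red") rgb_image(m, z, z) else rgb_image(z, m, z)
}

random_image <- function(h, w, seed) {
  set.seed(seed)
  rgb_image(matrix(sample(0:255, h * w, TRUE), h, w),
            matrix(sample(0:255, h * w, TRUE), h, w),
            matrix(sample(0:255, h * w, TRUE), h, w))
}

# standard per-channel parameters used across tests
params_single <- function(channel, T, s_min, s_max) {
  channel_params(threshold_rule("single_channel", channel, T),
                 size_range(s_min, s_max))
}
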