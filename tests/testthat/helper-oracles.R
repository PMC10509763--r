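# Independent oracles used across the suite: deliberately naive
# implementations that define the expected behaviour.

# exhaustive Otsu: try every candidate level, compute the two-class
# between-class variance directly from the pixel values
brute_otsu <- function(pixels) {
  v <- as.integer(pixels)
  n <- length(v)
  best_t <- NA_integer_
  best <- -Inf
  for (t in 0:254) {
    c0 <- v[v <= t]
    c1 <- v[v > t]
    if (length(c0) == 0L || length(c1) == 0L) next
    w0 <- length(c0) / n
    w1 <- length(c1) / n
    s <- w0 * w1 * (mean(c0) - mean(c1))^2
    if (s > best) { # strict: first (lowest) maximizing level wins
      best <- s
      best_t <- t
    }
  }
  best_t
}

# O(|A| * |B|) Hausdorff distance in mm
brute_hausdorff <- function(A, B, ps = c(1, 1)) {
  pa <- which(A == 1, arr.ind = TRUE)
  pb <- which(B == 1, arr.ind = TRUE)
  D2 <- outer(pa[, 1], pb[, 1], function(a, b) ((a - b) * ps[1])^2) +
    outer(pa[, 2], pb[, 2], function(a, b) ((a - b) * ps[2])^2)
  h_ab <- max(apply(D2, 1, min)) # farthest A pixel from its nearest B pixel
  h_ba <- max(apply(D2, 2, min))
  sqrt(max(h_ab, h_ba))
}

rand_mask <- function(h, w, p = 0.3) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# empty columns strictly between the column extents of the two components
count_gap_columns <- function(mask) {
  regs <- label_regions(as_mask(mask), 8L)$regions
  stopifnot(nrow(regs) == 2L)
  r <- regs[order(regs$centroid_col), ]
  cols <- (r$col_max[1] + 1L):(r$col_min[2] - 1L)
  if (r$col_min[2] - r$col_max[1] <= 1L) return(0L)
  sum(vapply(cols, function(cc) all(mask[, cc + 1L] == 0L), TRUE))
}
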