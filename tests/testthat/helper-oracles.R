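# Independent brute-force oracles: plain element loops, deliberately
# sharing no code with the implementation they check.

oracle_stats <- function(m, mask) {
  vals <- c()
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    if (mask[i, j]) vals <- c(vals, m[i, j])
  mu <- sum(vals) / length(vals)
  va <- sum((vals - mu)^2) / length(vals)
  list(mean = mu, deviation = sqrt(va), variance = va, n = length(vals))
}

oracle_histogram <- function(m, mask, lo, hi) {
  counts <- setNames(rep(0L, hi - lo + 1L), lo:hi)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    v <- m[i, j]
    if (mask[i, j] && v >= lo && v <= hi)
      counts[as.character(v)] <- counts[as.character(v)] + 1L
  }
  unname(counts)
}

oracle_count <- function(pred, m) {
  n <- 0L
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    if (pred(m[i, j])) n <- n + 1L
  n
}

# Mean over the k-nearest stencil at (i, j), enumerating candidate offsets
# and sorting exactly as the contract states: squared distance, then row,
# then column; members outside the image or suppressed are dropped and the
# mean renormalized.
oracle_stencil_mean <- function(m, mask, i, j, k) {
  offs <- expand.grid(dr = -5:5, dc = -5:5)
  offs <- offs[order(offs$dr^2 + offs$dc^2, offs$dr, offs$dc), ][seq_len(k), ]
  vals <- c()
  for (t in seq_len(k)) {
    r <- i + offs$dr[t]; c <- j + offs$dc[t]
    if (r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) && mask[r, c])
      vals <- c(vals, m[r, c])
  }
  mean(vals)
}

# Small default phantom used across tests: lesion shifted fully outside
# the tissue display range.
tiny_phantom <- function(size = 64, seed = 7, lesion = TRUE) {
  les <- if (lesion) list(center = c(round(size * 0.56), round(size * 0.5)),
                          radius = max(2, round(size / 20)), level_shift = 25L)
         else NULL
  generate_phantom(phantom_spec(size = size, seed = seed, lesion = les,
                                skull_width = max(2, round(size / 16))))
}

expect_same_grid <- function(a, b) {
  expect_identical(unname(a), unname(b))
}
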