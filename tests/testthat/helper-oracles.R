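# Shared fixtures and independent oracles, built in code at test time.

# Small, fast simulation used across tests: 30 h at 10-min sampling (181
# samples per frequency).
small_sim_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, duration_hours = 30,
                    sample_interval_minutes = 10, ...)
}

# All interval partitions of the points along one axis: for each part count
# k = 2..kmax, every assignment (in original point order) obtained by
# cutting the sorted axis at value changes.
axis_partitions <- function(v, kmax) {
  ord <- order(v)
  gaps <- which(diff(v[ord]) != 0)       # allowed cut positions (after i)
  out <- vector("list", kmax)
  for (k in 2:kmax) {
    if (length(gaps) < k - 1) break
    combs <- utils::combn(gaps, k - 1, simplify = FALSE)
    out[[k]] <- lapply(combs, function(cuts) {
      bins_sorted <- findInterval(seq_along(v), cuts + 0.5) + 1L
      bins <- integer(length(v))
      bins[ord] <- bins_sorted
      bins
    })
  }
  out
}

grid_mi <- function(xb, yb, c, r) {
  n <- length(xb)
  counts <- tabulate((xb - 1L) * r + yb, c * r)
  p <- counts / n
  px <- tapply(p, rep(seq_len(c), each = r), sum)
  py <- tapply(p, rep(seq_len(r), times = c), sum)
  pe <- as.numeric(outer(py, px))       # matches (xb-1)*r + yb layout
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / pe[nz]))
}

# Exhaustive all-partitions MIC: every (c, r) grid with c, r >= 2 and
# c * r <= B, every interval partition on both axes.
brute_force_mic <- function(x, y, B = 16) {
  kmax <- floor(B / 2)
  px <- axis_partitions(x, kmax)
  py <- axis_partitions(y, kmax)
  best <- 0
  for (c in 2:kmax) {
    if (length(px) < c || is.null(px[[c]])) next
    for (r in 2:floor(B / c)) {
      if (length(py) < r || is.null(py[[r]])) next
      norm <- log2(min(c, r))
      for (xb in px[[c]]) {
        for (yb in py[[r]]) {
          v <- grid_mi(xb, yb, c, r) / norm
          if (v > best) best <- v
        }
      }
    }
  }
  best
}
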