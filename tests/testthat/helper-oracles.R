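# Independent oracles used across the suite.

# Naive O(N^2) time-averaged MSD: msd(k) = mean_i (x[i+k] - x[i])^2
naive_msd <- function(x, max_lag = length(x) - 1) {
  vapply(seq_len(max_lag), function(k) {
    i <- seq_len(length(x) - k)
    mean((x[i + k] - x[i])^2)
  }, numeric(1))
}

# Brute-force 2D binning: count points cell-by-cell on extended edges
brute_bin <- function(d_theta, d_chi, chi_edges, theta_edges) {
  ce <- c(-Inf, chi_edges, Inf)
  te <- c(0, theta_edges, Inf)
  counts <- matrix(0, nrow = length(te) - 1, ncol = length(ce) - 1)
  for (k in seq_along(d_chi)) {
    ti <- max(which(abs(d_theta[k]) >= te[-length(te)]))
    ci <- max(which(d_chi[k] >= ce[-length(ce)]))
    counts[ti, ci] <- counts[ti, ci] + 1
  }
  counts
}

# Direct sample skewness
direct_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

# A tiny trajectory tibble from explicit angle vectors
traj_tbl <- function(theta, chi, id = 1L, t0 = 0L) {
  tibble::tibble(track_id = id, frame = t0 + seq_along(theta) - 1L,
                 theta_mrad = theta, chi_mrad = chi)
}
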