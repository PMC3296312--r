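# shared fixture builders; everything is generated in code at test time

rand_stack <- function(K, dims, p = 0.5) {
  rater_set(lapply(seq_len(K), function(k) {
    array(stats::rbinom(prod(dims), 1L, p), dim = dims)
  }))
}

# brute-force per-element disagreement check, independent of the package path
brute_disputed <- function(rs) {
  E <- sapply(rs$raters, as.integer)
  apply(E, 1, function(v) length(unique(v)) > 1L)
}

# exact euclidean distance oracle by exhaustive pairwise search (2D)
brute_signed_distance <- function(m) {
  idx <- which(m == 1L | m == 0L, arr.ind = TRUE)
  fg <- which(m == 1L, arr.ind = TRUE)
  bg <- which(m == 0L, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (m[i, j] == 1L) {
      d <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
      out[i, j] <- -d
    } else {
      d <- sqrt(min((fg[, 1] - i)^2 + (fg[, 2] - j)^2))
      out[i, j] <- d
    }
  }
  out
}

# filled disk of radius r centered on (cx, cy) in an n x n grid
disk_label <- function(n, cx, cy, r) {
  ii <- matrix(seq_len(n), n, n)
  jj <- matrix(seq_len(n), n, n, byrow = TRUE)
  label_image(matrix(as.integer((ii - cx)^2 + (jj - cy)^2 <= r^2), n))
}

# small-grid 2D spec for fast unit tests (v_D is scale-free, so the
# calibration logic behaves identically at reduced resolution)
small_spec_2d <- function() shape_spec_2d(grid_n = 64L)

small_sigma_2d <- function() {
  calibrate_sigma("2d", n_pilot = 500L, seed = 7L, spec = small_spec_2d())
}
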