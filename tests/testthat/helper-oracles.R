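# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, closed forms, or a
# different library route.

# Benjamini-Hochberg step-up, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# closed-form fractional anisotropy from eigenvalues
fa_oracle <- function(l) {
  sqrt(0.5) * sqrt((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[1] - l[3])^2) /
    sqrt(sum(l^2))
}

# brute-force count of voxels whose center lies in a sphere, by explicit
# per-voxel loop through the affine
sphere_count_oracle <- function(center, radius, shape, affine) {
  count <- 0L
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) for (k in seq_len(shape[3])) {
    w <- affine %*% c(i - 1, j - 1, k - 1, 1)
    if (sum((w[1:3] - center)^2) <= radius^2) count <- count + 1L
  }
  count
}

# exhaustive Youden search over all midpoints, direction fixed
cutpoint_oracle <- function(scores, events, direction) {
  su <- sort(unique(scores))
  cand <- (su[-1] + su[-length(su)]) / 2
  best_j <- -Inf; best_cut <- NA; best_imb <- Inf
  for (cut in cand) {
    pred <- if (direction == "<=") scores <= cut else scores >= cut
    sens <- mean(pred[events == 1])
    spec <- mean(!pred[events == 0])
    J <- sens + spec - 1
    imb <- abs(sum(pred) - sum(!pred))
    if (J > best_j + 1e-12 ||
        (abs(J - best_j) <= 1e-12 &&
           (imb < best_imb || (imb == best_imb && cut < best_cut)))) {
      best_j <- J; best_cut <- cut; best_imb <- imb
    }
  }
  list(cutpoint = best_cut, youden = best_j)
}

# ICC(2,1) via the two-way ANOVA mean squares from stats::aov
icc_oracle <- function(a, b) {
  n <- length(a)
  d <- data.frame(y = c(a, b),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(aov(y ~ subj + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}

# grid affine centred on an ROI (odd cube side, voxel center on the ROI center)
scaled_affine_for_test <- function(voxel_size, roi, n = NULL) {
  n <- n %||% if (voxel_size == 1) 21L else 9L
  scaled_affine(voxel_size,
                origin = c(roi$x, roi$y, roi$z) - (n - 1) / 2 * voxel_size)
}

# small DWI phantom spec on a coarse grid, for fast tensor tests
tiny_phantom <- function(tensor, shape = c(5, 5, 5), n_dirs = 15, ...) {
  phantom_spec(shape = shape, voxel_size = 2.5,
               background_tensor = tensor,
               directions = default_gradient_set(n_dirs), ...)
}
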