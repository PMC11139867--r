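# Shared fixtures and independent oracles for the test suite.

# Trajectory from explicit coordinates (all in a generous frame).
make_traj <- function(x, y, visible = rep(TRUE, length(x)), fps = 30) {
  tip_trajectory(x = x, y = y, visible = visible, fps = fps,
                 frame_width = 10000, frame_height = 10000)
}

# Random valid trajectory for property tests (runs under the caller's seed).
random_traj <- function(n = 60, p_visible = 0.7, fps = 30) {
  make_traj(x = runif(n, 0, 5000), y = runif(n, 0, 5000),
            visible = runif(n) < p_visible, fps = fps)
}

# Brute-force travel distance: explicit frame-by-frame loop, counting only
# transitions between consecutive visible frames.
oracle_travel_distance <- function(traj) {
  tot <- 0
  for (i in seq_len(length(traj) - 1)) {
    if (traj$visible[i] && traj$visible[i + 1]) {
      tot <- tot + sqrt((traj$x[i + 1] - traj$x[i])^2 +
                          (traj$y[i + 1] - traj$y[i])^2)
    }
  }
  tot
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
oracle_mw_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    aa <- pooled[idx]; bb <- pooled[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  all_u <- apply(utils::combn(n1 + n2, n1), 2, u_of)
  u_obs <- u_of(seq_len(n1))
  p <- min(1, 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs)))
  list(u = u_obs, p = p)
}

# Pixel-by-pixel confusion counts with explicit loops.
oracle_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] && truth[i, j]) tp <- tp + 1
      else if (pred[i, j]) fp <- fp + 1
      else if (truth[i, j]) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}
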