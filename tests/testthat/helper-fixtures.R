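# Shared fixtures, memoised so expensive objects are built once per run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

small_pop <- function(n = 5, seed = 11, ...) {
  fixture(paste0("pop_", n, "_", seed),
          function() sample_population(population_config(n_subjects = n,
                                                         seed = seed, ...)))
}

quick_stride <- function(subject, footwear = "sport", stride_seed = 1,
                         rate = 120) {
  synth_grf_stride(subject, footwear, stride_seed = stride_seed,
                   sampling_rate_hz = rate)
}

# Brute-force DTW oracle: recursively enumerates every monotone warping
# path (steps (1,0), (0,1), (1,1)) and takes the minimal accumulated
# L1 cost.  Exponential; only for short series.
dtw_enum <- function(a, b) {
  rec <- function(i, j) {
    cost <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(cost)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    cost + best
  }
  rec(length(a), length(b))
}

# Tiny hand-built skeleton log: one or two sensors, constant height,
# all chain joints on a vertical line.  States can be overridden per
# joint name.
toy_skeleton <- function(height_cm = 165, n_frames = 3, sensors = 1:2,
                         offset = gaitid:::head_top_offset_default,
                         states = NULL) {
  joints <- gaitid:::skeleton_joints
  frac <- gaitid:::joint_span_fraction[names(joints)]
  span <- (height_cm - offset) / 100
  rows <- list()
  for (f in seq_len(n_frames)) {
    for (s in sensors) {
      st <- rep("fully_tracked", length(joints))
      names(st) <- names(joints)
      if (!is.null(states)) st[names(states)] <- states
      rows[[length(rows) + 1L]] <- data.frame(
        timestamp = (f - 1) / 30, sensor_id = s,
        joint_id = unname(joints), x = 0, y = unname(frac * span), z = 0,
        tracking_state = unname(st))
    }
  }
  log <- do.call(rbind, rows)
  class(log) <- c("skeleton_log", "data.frame")
  log
}
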