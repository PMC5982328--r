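# Skeleton joint ids (Kinect-v2-style numbering) used by the generator
# and the height estimator.  Only the joints on the height chain are
# emitted: trunk head->neck->spine_shoulder->spine_mid->spine_base and
# both leg chains hip->knee->ankle->foot.
skeleton_joints <- c(spine_base = 0L, spine_mid = 1L, neck = 2L, head = 3L,
                     hip_L = 12L, knee_L = 13L, ankle_L = 14L, foot_L = 15L,
                     hip_R = 16L, knee_R = 17L, ankle_R = 18L, foot_R = 19L,
                     spine_shoulder = 20L)

# Vertical position of each chain joint as a fraction of the chain span
# (instantaneous height minus the head-top offset).  Trunk segments sum
# to 0.52 of the span, each leg chain to 0.48; both legs are identical
# (symmetric skeleton), which makes the contralateral fallback exact.
joint_span_fraction <- c(spine_base = 0.48, spine_mid = 0.64, neck = 0.88,
                         head = 1.00, spine_shoulder = 0.82,
                         hip_L = 0.48, knee_L = 0.28, ankle_L = 0.09, foot_L = 0,
                         hip_R = 0.48, knee_R = 0.28, ankle_R = 0.09, foot_R = 0)

# Head joint centre to head top plus foot joint to ground, in cm.  The
# generator and the estimator share this constant so that the chain sum
# reproduces the instantaneous height exactly on fully tracked frames.
head_top_offset_default <- 12

#' Generate a two-sensor skeleton frame log
#'
#' Emulates two depth sensors tracking a walking subject.  The
#' instantaneous chain height at time t is
#' `true_height_sport + heel_delta * [footwear == "heels"]` plus a
#' sinusoidal within-cycle head-height oscillation (peak-to-trough equal
#' to the subject's `osc_amp_cm`, capped at 9.5 cm) plus independent
#' zero-mean per-sensor measurement noise.  Joint coordinates are laid
#' out so that the anthropometric chain sum of [estimate_body_height()]
#' reproduces that height exactly whenever all joints are fully
#' tracked.  Each joint observation is independently degraded to
#' `"inferred"` with the configured dropout probability.
#'
#' @param subject A `subject_params` object.
#' @param footwear `"sport"` or `"heels"`.
#' @param n_cycles Number of gait cycles to record (>= 1).
#' @param seed Integer seed for noise and dropout.
#' @param fps Frame rate; defaults to the subject's configured rate.
#' @return A `skeleton_log`: data frame with columns `timestamp`,
#'   `sensor_id`, `joint_id`, `x`, `y`, `z` (metres) and
#'   `tracking_state`.  The noise-free ground truth (per-frame height
#'   and oscillation component, cm) is attached as attribute `"truth"`.
#' @examples
#' s <- sample_population(population_config(n_subjects = 1, seed = 1))[[1]]
#' log <- synth_skeleton_stream(s, "sport", n_cycles = 2, seed = 1)
#' head(attr(log, "truth"))
#' @export
synth_skeleton_stream <- function(subject, footwear = c("sport", "heels"),
                                  n_cycles = 3L, seed = 1L, fps = NULL) {
  if (!inherits(subject, "subject_params"))
    stop("synth_skeleton_stream: 'subject' must be a subject_params")
  footwear <- match.arg(footwear)
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L)
    stop("synth_skeleton_stream: 'n_cycles' must be >= 1")
  if (is.null(fps)) fps <- subject$skeleton_fps

  base <- subject$true_height_sport_cm +
    if (footwear == "heels") subject$heel_delta_cm else 0
  cyc <- subject$timing$cycle_duration_s
  n_frames <- max(1L, floor(n_cycles * cyc * fps))
  t_s <- (seq_len(n_frames) - 1L) / fps
  osc <- (subject$osc_amp_cm / 2) * sin(2 * pi * t_s / cyc)

  jn <- names(skeleton_joints)
  nj <- length(jn)
  frac <- joint_span_fraction[jn]
  x_off <- ifelse(grepl("_L$", jn), -0.09, ifelse(grepl("_R$", jn), 0.09, 0))

  with_seed(mix_seed(seed, 3L), {
    rows <- vector("list", 2L)
    for (sensor in 1:2) {
      noise <- if (subject$noise$sensor_noise_sd > 0)
        rnorm(n_frames, 0, subject$noise$sensor_noise_sd) else 0
      span_m <- (base + osc + noise - head_top_offset_default) / 100
      y <- as.vector(outer(span_m, frac))            # frame-major blocks per joint
      state <- rep("fully_tracked", n_frames * nj)
      if (subject$noise$dropout_prob > 0)
        state[runif(n_frames * nj) < subject$noise$dropout_prob] <- "inferred"
      rows[[sensor]] <- data.frame(
        timestamp = rep(t_s, times = nj),
        sensor_id = sensor,
        joint_id = rep(unname(skeleton_joints[jn]), each = n_frames),
        x = rep(x_off, each = n_frames),
        y = y,
        z = rep(1.2 * t_s, times = nj),              # forward progression
        tracking_state = state)
    }
    log <- rbind(rows[[1]], rows[[2]])
    log <- log[order(log$timestamp, log$sensor_id, log$joint_id), ]
    rownames(log) <- NULL
    structure(log,
              truth = data.frame(time_s = t_s, height_cm = base + osc,
                                 osc_cm = osc),
              subject_id = subject$subject_id, footwear = footwear,
              cycle_s = cyc,
              class = c("skeleton_log", "data.frame"))
  })
}
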