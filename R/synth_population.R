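#' Configuration of the synthetic walking population
#'
#' Bundles every parameter of the synthetic-gait generator into one
#' validated list.  The defaults emulate a cohort of adult women walking
#' in their own sport shoes and 8--10 cm high heels: body weight
#' 61.9 +/- 11.07 kg, standing height 166.41 +/- 5.74 cm, a heel-induced
#' increase of the measured walking height of 4.988 +/- 0.7504 cm, and a
#' stance (support) phase occupying on average 60 % of the gait cycle.
#'
#' The GRF shape of each subject is a perturbed copy of a shared
#' control-point template (see [synth_grf_stride()]).  Identity
#' information lives in the *between*-subject perturbation of the control
#' points; stride-to-stride repeatability is governed by the smaller
#' *within*-subject perturbation.  The ratio of the two standard
#' deviations is the separability knob of the generator.
#'
#' @param n_subjects Number of subjects to generate (>= 1).
#' @param seed Integer root seed; all subject draws derive from it.
#' @param body_weight_mean_N,body_weight_sd_N Body weight distribution in
#'   newtons (default 61.90 kg and 11.07 kg at g = 9.81 m/s^2).
#' @param height_mean_cm,height_sd_cm Standing sport-shoe height (cm).
#' @param heel_delta_mean,heel_delta_sd Mean and SD (cm) of the increase
#'   in measured walking height caused by high heels.
#' @param between_subject_sd List with elements `amp` (relative SD of
#'   control-point amplitudes) and `time` (absolute SD of control-point
#'   timings, as a fraction of stance) describing between-subject GRF
#'   shape variation.
#' @param within_subject_sd Same structure; stride-to-stride variation of
#'   one subject.
#' @param stance_fraction_mean,stance_fraction_sd Stance duration as a
#'   fraction of the gait cycle (between-subject).
#' @param cycle_duration_mean,cycle_duration_sd Gait-cycle duration (s).
#' @param osc_amp_mean_cm,osc_amp_sd_cm Peak-to-trough amplitude (cm) of
#'   the within-cycle head-height oscillation; capped at
#'   `osc_amp_max_cm` (the largest head-height excursion reported for
#'   normal walking).
#' @param osc_amp_max_cm Hard cap on the oscillation amplitude (cm).
#' @param sensor_noise_sd Per-frame, per-sensor height measurement noise
#'   SD (cm) of the depth sensors.
#' @param dropout_prob Probability that a joint observation is degraded
#'   from `fully_tracked` to `inferred`, independently per joint, frame
#'   and sensor.
#' @param heels_amp_scale Multiplicative increase of GRF extreme
#'   amplitudes in high heels.
#' @param heels_stance_scale Multiplicative change of stance duration in
#'   high heels.
#' @param heels_time_shift Shift (fraction of stance, negative = earlier)
#'   of the weight-acceptance extremes in high heels: the reduced heel
#'   rocker makes loading more abrupt, so the first vertical maximum and
#'   the braking minimum arrive earlier in the stance.
#' @param sampling_rate_hz Force-plate sampling rate (Hz).
#' @param skeleton_fps Skeleton stream frame rate (frames/s).
#'
#' @return An object of class `population_config` (a named list).
#' @seealso [sample_population()], [synth_grf_stride()],
#'   [synth_skeleton_stream()]
#' @export
population_config <- function(n_subjects = 50L,
                              seed = 1L,
                              body_weight_mean_N = 607.2,
                              body_weight_sd_N = 108.6,
                              height_mean_cm = 166.41,
                              height_sd_cm = 5.74,
                              heel_delta_mean = 4.988,
                              heel_delta_sd = 0.7504,
                              between_subject_sd = list(amp = 0.05, time = 0.012),
                              within_subject_sd = list(amp = 0.012, time = 0.004),
                              stance_fraction_mean = 0.60,
                              stance_fraction_sd = 0.015,
                              cycle_duration_mean = 1.05,
                              cycle_duration_sd = 0.06,
                              osc_amp_mean_cm = 4,
                              osc_amp_sd_cm = 0.8,
                              osc_amp_max_cm = 9.5,
                              sensor_noise_sd = 1.0,
                              dropout_prob = 0.05,
                              heels_amp_scale = 1.10,
                              heels_stance_scale = 0.95,
                              heels_time_shift = -0.03,
                              sampling_rate_hz = 960,
                              skeleton_fps = 30) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L)
    stop("population_config: 'n_subjects' must be a positive integer")
  if (length(seed) != 1L || is.na(seed))
    stop("population_config: 'seed' must be a single integer")
  sds <- c(body_weight_sd_N, height_sd_cm, heel_delta_sd,
           between_subject_sd$amp, between_subject_sd$time,
           within_subject_sd$amp, within_subject_sd$time,
           stance_fraction_sd, cycle_duration_sd,
           osc_amp_sd_cm, sensor_noise_sd)
  if (any(sds < 0)) stop("population_config: standard deviations must be >= 0")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("population_config: 'dropout_prob' must be in [0, 1)")
  if (stance_fraction_mean <= 0 || stance_fraction_mean >= 1)
    stop("population_config: 'stance_fraction_mean' must lie in (0, 1)")
  cfg <- list(n_subjects = n_subjects, seed = as.integer(seed),
              body_weight_mean_N = body_weight_mean_N,
              body_weight_sd_N = body_weight_sd_N,
              height_mean_cm = height_mean_cm, height_sd_cm = height_sd_cm,
              heel_delta_mean = heel_delta_mean, heel_delta_sd = heel_delta_sd,
              between_subject_sd = between_subject_sd,
              within_subject_sd = within_subject_sd,
              stance_fraction_mean = stance_fraction_mean,
              stance_fraction_sd = stance_fraction_sd,
              cycle_duration_mean = cycle_duration_mean,
              cycle_duration_sd = cycle_duration_sd,
              osc_amp_mean_cm = osc_amp_mean_cm, osc_amp_sd_cm = osc_amp_sd_cm,
              osc_amp_max_cm = osc_amp_max_cm,
              sensor_noise_sd = sensor_noise_sd, dropout_prob = dropout_prob,
              heels_amp_scale = heels_amp_scale,
              heels_stance_scale = heels_stance_scale,
              heels_time_shift = heels_time_shift,
              sampling_rate_hz = sampling_rate_hz,
              skeleton_fps = skeleton_fps)
  structure(cfg, class = "population_config")
}

# Shared GRF control-point template, amplitudes as fractions of body
# weight, timings as fractions of stance:
#   Fy: double bump, overload and propulsion maxima 1.2 BW at 25 %/75 %
#       of stance, unloading minimum 0.8 BW at mid stance, zero at the
#       contact boundaries;
#   Fx: braking minimum -0.2 BW just before the first Fy maximum,
#       propulsive maximum +0.2 BW just after the second, zero crossing
#       at mid stance;
#   Fz: lateral plateau of 0.1 BW, positive for the left limb and
#       mirrored negative for the right.
base_grf_shape <- function(limb = c("L", "R")) {
  limb <- match.arg(limb)
  fz_sign <- if (limb == "L") 1 else -1
  list(
    fx = data.frame(t = c(0, 0.22, 0.50, 0.78, 1),
                    a = c(0, -0.20, 0, 0.20, 0)),
    fy = data.frame(t = c(0, 0.25, 0.50, 0.75, 1),
                    a = c(0, 1.20, 0.80, 1.20, 0)),
    fz = data.frame(t = c(0, 0.20, 0.50, 0.80, 1),
                    a = fz_sign * c(0, 0.10, 0.10, 0.10, 0))
  )
}

# Perturb a control-point table: multiplicative amplitude noise (zeros
# stay zero, so contact boundaries remain anchored) and additive timing
# noise on interior points, order restored by clamping.
perturb_shape <- function(shape, amp_sd, time_sd) {
  lapply(shape, function(tbl) {
    n <- nrow(tbl)
    if (amp_sd > 0) tbl$a <- tbl$a * (1 + rnorm(n, 0, amp_sd))
    if (time_sd > 0) {
      interior <- 2:(n - 1)
      tbl$t[interior] <- tbl$t[interior] + rnorm(length(interior), 0, time_sd)
      for (i in interior) # keep strictly increasing within (0, 1)
        tbl$t[i] <- min(max(tbl$t[i], tbl$t[i - 1] + 0.01), 0.99 - 0.01 * (n - i))
    }
    tbl
  })
}

rnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Sample a synthetic walking population
#'
#' Draws `n_subjects` subjects with individual body weight, standing
#' height, heel-height effect, gait timing, per-limb GRF control-point
#' shapes and head-height oscillation amplitude.  The draw is fully
#' deterministic given `config$seed`.
#'
#' @param config A [population_config()].
#' @return A list of `subject_params` objects.  Each carries
#'   `subject_id`, `body_weight_N`, `true_height_sport_cm`,
#'   `heel_delta_cm`, `grf_shape` (per-limb control-point tables),
#'   `timing` (`stance_fraction`, `cycle_duration_s`), `osc_amp_cm`, and
#'   the `noise` scales inherited from the config.
#' @examples
#' pop <- sample_population(population_config(n_subjects = 3, seed = 7))
#' pop[[1]]$body_weight_N
#' @export
sample_population <- function(config) {
  if (!inherits(config, "population_config"))
    stop("sample_population: 'config' must be a population_config")
  n <- config$n_subjects
  with_seed(mix_seed(config$seed, 1L), {
    bw <- rnorm_pos(n, config$body_weight_mean_N, config$body_weight_sd_N)
    ht <- rnorm_pos(n, config$height_mean_cm, config$height_sd_cm)
    hd <- rnorm_pos(n, config$heel_delta_mean, config$heel_delta_sd)
    sf <- rnorm(n, config$stance_fraction_mean, config$stance_fraction_sd)
    sf <- pmin(pmax(sf, 0.4), 0.8)
    cd <- rnorm_pos(n, config$cycle_duration_mean, config$cycle_duration_sd)
    osc <- pmin(abs(rnorm(n, config$osc_amp_mean_cm, config$osc_amp_sd_cm)),
                config$osc_amp_max_cm)
    lapply(seq_len(n), function(i) {
      shape <- lapply(list(L = base_grf_shape("L"), R = base_grf_shape("R")),
                      perturb_shape,
                      amp_sd = config$between_subject_sd$amp,
                      time_sd = config$between_subject_sd$time)
      structure(list(
        subject_id = sprintf("S%03d", i),
        body_weight_N = bw[i],
        true_height_sport_cm = ht[i],
        heel_delta_cm = hd[i],
        grf_shape = shape,
        timing = list(stance_fraction = sf[i], cycle_duration_s = cd[i]),
        osc_amp_cm = osc[i],
        noise = list(within_subject_sd = config$within_subject_sd,
                     sensor_noise_sd = config$sensor_noise_sd,
                     dropout_prob = config$dropout_prob),
        heels = list(amp_scale = config$heels_amp_scale,
                     stance_scale = config$heels_stance_scale,
                     time_shift = config$heels_time_shift),
        sampling_rate_hz = config$sampling_rate_hz,
        skeleton_fps = config$skeleton_fps
      ), class = "subject_params")
    })
  })
}
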