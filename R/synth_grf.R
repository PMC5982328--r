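# Shape-preserving piecewise-cubic Hermite interpolant (PCHIP,
# Fritsch-Carlson slopes).  At interior nodes where the secants change
# sign the slope is zero, so the interpolant attains its local extremes
# exactly at the control points and never overshoots them -- the
# printed extreme magnitudes ARE the control amplitudes.
pchip_fun <- function(t, a) {
  n <- length(t)
  dt <- diff(t)
  sec <- diff(a) / dt
  m <- numeric(n)
  m[1] <- sec[1]
  m[n] <- sec[n - 1]
  for (k in 2:(n - 1)) {
    if (sec[k - 1] * sec[k] <= 0) {
      m[k] <- 0                       # local extremum or flat
    } else {
      w1 <- 2 * dt[k] + dt[k - 1]     # weighted harmonic mean of secants
      w2 <- dt[k] + 2 * dt[k - 1]
      m[k] <- (w1 + w2) / (w1 / sec[k - 1] + w2 / sec[k])
    }
  }
  function(x) {
    i <- findInterval(x, t, all.inside = TRUE)
    h <- dt[i]
    s <- (x - t[i]) / h
    s1 <- 1 - s
    a[i] * (1 + 2 * s) * s1^2 + h * m[i] * s * s1^2 +
      a[i + 1] * s^2 * (3 - 2 * s) + h * m[i + 1] * s^2 * (s - 1)
  }
}

#' Generate one synthetic GRF stride
#'
#' Builds the stance-phase force time series of both limbs (three
#' components each) for one stride of one subject.  Each component is a
#' shape-preserving monotone piecewise-cubic (Fritsch--Carlson)
#' interpolant through the subject's control points, perturbed by the
#' within-subject noise, so the printed extreme magnitudes are exactly
#' the (perturbed) control amplitudes: vertical maxima near 120 % of
#' body weight at ~25 % and ~75 % of stance with a sub-BW unloading
#' minimum between them, anterior--posterior extremes near +/-20 % BW
#' with a mid-stance zero crossing, and a lateral plateau near 10 % BW,
#' positive on the left and negative on the right.  High heels scale the
#' extreme amplitudes up and shorten the stance.
#'
#' @param subject A `subject_params` object from [sample_population()].
#' @param footwear `"sport"` or `"heels"`.
#' @param stride_seed Integer seed for the stride's within-subject
#'   perturbation; equal seeds reproduce the stride bit for bit.
#' @param sampling_rate_hz Force-plate rate (Hz); defaults to the
#'   subject's configured rate.
#' @return A `stride_record`: list with `subject_id`, `footwear`,
#'   `body_weight_N`, `sampling_rate_hz`, `stance_s`, `cycle_s` and
#'   `series`, a data frame with columns `time_s`, `fx_L`, `fy_L`,
#'   `fz_L`, `fx_R`, `fy_R`, `fz_R` in newtons.
#' @examples
#' s <- sample_population(population_config(n_subjects = 1, seed = 1))[[1]]
#' st <- synth_grf_stride(s, "sport", stride_seed = 1, sampling_rate_hz = 120)
#' max(st$series$fy_L) / st$body_weight_N  # ~1.2
#' @export
synth_grf_stride <- function(subject, footwear = c("sport", "heels"),
                             stride_seed = 1L, sampling_rate_hz = NULL) {
  if (!inherits(subject, "subject_params"))
    stop("synth_grf_stride: 'subject' must be a subject_params")
  footwear <- match.arg(footwear)
  rate <- if (is.null(sampling_rate_hz)) subject$sampling_rate_hz else sampling_rate_hz
  if (rate <= 0) stop("synth_grf_stride: sampling rate must be positive")

  wsd <- subject$noise$within_subject_sd
  with_seed(mix_seed(stride_seed, 2L), {
    sf <- subject$timing$stance_fraction
    cyc <- subject$timing$cycle_duration_s
    if (wsd$time > 0) {
      sf <- min(max(sf + rnorm(1, 0, wsd$time), 0.4), 0.8)
      cyc <- max(cyc * (1 + rnorm(1, 0, wsd$time)), 0.3)
    }
    amp_scale <- 1
    time_shift <- 0
    if (footwear == "heels") {
      amp_scale <- subject$heels$amp_scale
      sf <- sf * subject$heels$stance_scale
      time_shift <- subject$heels$time_shift
    }
    stance_s <- sf * cyc
    n <- max(12L, as.integer(round(stance_s * rate)))
    tgrid <- seq(0, 1, length.out = n)

    cols <- list()
    for (limb in c("L", "R")) {
      shape <- perturb_shape(subject$grf_shape[[limb]], wsd$amp, wsd$time)
      for (comp in c("fx", "fy", "fz")) {
        tbl <- shape[[comp]]
        if (time_shift != 0 && comp %in% c("fx", "fy")) {
          # heels: weight acceptance arrives earlier in the stance
          tbl$t[2] <- max(tbl$t[2] + time_shift, tbl$t[1] + 0.02)
        }
        f <- pchip_fun(tbl$t, tbl$a * amp_scale)
        cols[[paste(comp, limb, sep = "_")]] <- f(tgrid) * subject$body_weight_N
      }
    }
    series <- data.frame(time_s = (seq_len(n) - 1L) / rate,
                         fx_L = cols$fx_L, fy_L = cols$fy_L, fz_L = cols$fz_L,
                         fx_R = cols$fx_R, fy_R = cols$fy_R, fz_R = cols$fz_R)
    structure(list(subject_id = subject$subject_id, footwear = footwear,
                   body_weight_N = subject$body_weight_N,
                   sampling_rate_hz = rate,
                   stance_s = stance_s, cycle_s = cyc,
                   series = series),
              class = "stride_record")
  })
}

#' @export
print.stride_record <- function(x, ...) {
  cat(sprintf("<stride_record> subject %s, %s, %d samples @ %g Hz, BW %.1f N\n",
              x$subject_id, x$footwear, nrow(x$series),
              x$sampling_rate_hz, x$body_weight_N))
  invisible(x)
}

#' Extract one force component of a stride as a GRF series
#'
#' @param stride A `stride_record`.
#' @param component `"fx"`, `"fy"` or `"fz"`.
#' @param limb `"L"` or `"R"`.
#' @param bw_normalize Divide by body weight so forces are fractions of
#'   BW (the scale on which strides are compared).
#' @return A `grf_series`: list with `samples`, `sampling_rate_hz`,
#'   `component`, `limb`.
#' @export
grf_component <- function(stride, component = c("fx", "fy", "fz"),
                          limb = c("L", "R"), bw_normalize = TRUE) {
  component <- match.arg(component)
  limb <- match.arg(limb)
  x <- stride$series[[paste(component, limb, sep = "_")]]
  if (bw_normalize) x <- x / stride$body_weight_N
  structure(list(samples = x, sampling_rate_hz = stride$sampling_rate_hz,
                 component = component, limb = limb),
            class = "grf_series")
}
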