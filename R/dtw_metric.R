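#' Dynamic time warping cost between two series
#'
#' Classic DTW dynamic program: local cost `|a_i - b_j|`, symmetric
#' unit-weight steps (1,0), (0,1), (1,1), endpoints anchored, no window
#' by default.  The accumulated cost of the optimal warping path is the
#' dissimilarity used throughout the pipeline ("cost of imitation").
#' It is nonnegative, symmetric, zero for identical series and scales
#' linearly under common amplitude scaling; it is not a metric (no
#' triangle inequality).
#'
#' @param a,b `grf_series` objects or numeric vectors (non-empty).  When
#'   both are `grf_series` their component and limb must agree.
#' @param window Optional Sakoe--Chiba band half-width in samples;
#'   `NULL` (default) means unconstrained.
#' @return The minimal accumulated cost (single nonnegative number).
#' @examples
#' dtw_cost(c(0, 1, 2), c(0, 2))  # 1
#' @export
dtw_cost <- function(a, b, window = NULL) {
  if (inherits(a, "grf_series") && inherits(b, "grf_series")) {
    if (a$component != b$component || a$limb != b$limb)
      stop("dtw_cost: series disagree on component/limb (",
           a$component, "/", a$limb, " vs ", b$component, "/", b$limb, ")")
    a <- a$samples
    b <- b$samples
  }
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("dtw_cost: empty series")
  dtw_cost_cpp(a, b, if (is.null(window)) -1L else as.integer(window))
}

# Precompute the per-limb, per-component fragments a stride contributes
# to the five distances: full stance plus the MSt and TSt windows, all
# in fraction-of-BW units.  Cached on the stride so galleries are
# segmented once.
stride_dtw_parts <- function(stride) {
  if (!is.null(stride$dtw_parts)) return(stride$dtw_parts)
  parts <- list()
  for (limb in c("L", "R")) {
    for (comp in c("fx", "fy", "fz")) {
      x <- stride$series[[paste(comp, limb, sep = "_")]] / stride$body_weight_N
      n <- length(x)
      w_mst <- phase_window(n, "MSt")
      w_tst <- phase_window(n, "TSt")
      key <- paste(comp, limb, sep = "_")
      parts[[key]] <- list(full = x,
                           MSt = x[(w_mst$start + 1L):w_mst$end],
                           TSt = x[(w_tst$start + 1L):w_tst$end])
    }
  }
  parts
}

# Flat layout consumed by the C++ profile kernel: for L then R, fx, fy,
# fz, the (MSt, TSt, full) fragments -> 18 vectors.
flatten_parts <- function(parts) {
  out <- vector("list", 18L)
  q <- 1L
  for (limb in c("L", "R")) {
    for (comp in c("fx", "fy", "fz")) {
      p <- parts[[paste(comp, limb, sep = "_")]]
      out[[q]] <- p$MSt; out[[q + 1L]] <- p$TSt; out[[q + 2L]] <- p$full
      q <- q + 3L
    }
  }
  out
}

stride_dtw_flat <- function(stride) {
  if (!is.null(stride$dtw_flat)) return(stride$dtw_flat)
  flatten_parts(stride_dtw_parts(stride))
}

# Attach the cached fragments (used by gallery enrollment).
cache_dtw_parts <- function(stride) {
  stride$dtw_parts <- stride_dtw_parts(stride)
  stride$dtw_flat <- flatten_parts(stride$dtw_parts)
  stride
}

#' Phase distance between two strides
#'
#' Sum of the three per-component DTW costs (Fx, Fy, Fz, each aligned
#' independently, forces in fraction of body weight) over one sub-phase
#' window of one limb.
#'
#' @param probe,gallery `stride_record` objects.
#' @param phase `"MSt"` or `"TSt"`.
#' @param limb `"L"` or `"R"`.
#' @param window Optional Sakoe--Chiba half-width passed to [dtw_cost()].
#' @return Nonnegative phase distance.
#' @export
phase_distance <- function(probe, gallery, phase = c("MSt", "TSt"),
                           limb = c("L", "R"), window = NULL) {
  phase <- match.arg(phase)
  limb <- match.arg(limb)
  pp <- stride_dtw_parts(probe)
  gp <- stride_dtw_parts(gallery)
  w <- if (is.null(window)) -1L else as.integer(window)
  total <- 0
  for (comp in c("fx", "fy", "fz")) {
    key <- paste(comp, limb, sep = "_")
    total <- total + dtw_cost_cpp(pp[[key]][[phase]], gp[[key]][[phase]], w)
  }
  total
}

#' Whole-stride distance between two strides
#'
#' Sum of six full-stance DTW costs: three components times two limbs,
#' each aligned independently (forces in fraction of body weight).
#'
#' @inheritParams phase_distance
#' @return Nonnegative stride distance.
#' @export
stride_distance <- function(probe, gallery, window = NULL) {
  pp <- stride_dtw_parts(probe)
  gp <- stride_dtw_parts(gallery)
  w <- if (is.null(window)) -1L else as.integer(window)
  total <- 0
  for (key in names(pp))
    total <- total + dtw_cost_cpp(pp[[key]]$full, gp[[key]]$full, w)
  total
}

#' Distance profile of a probe stride against a gallery
#'
#' Computes, for every enrolled gallery stride, the five distances used
#' by the ensemble: mid-stance and terminal-stance phase distances for
#' each limb, and the whole-stride distance.
#'
#' @param probe A `stride_record`.
#' @param gallery_strides A list of `stride_record`s (enrollment order
#'   is preserved in the row order).
#' @param window Optional Sakoe--Chiba half-width.
#' @return A data frame with one row per gallery stride and columns
#'   `subject_id`, `rho_MSt_L`, `rho_TSt_L`, `rho_MSt_R`, `rho_TSt_R`,
#'   `rho_Stride`.
#' @export
distance_profile <- function(probe, gallery_strides, window = NULL) {
  if (length(gallery_strides) == 0L)
    stop("distance_profile: empty gallery")
  w <- if (is.null(window)) -1L else as.integer(window)
  out <- dtw_profile_cpp(stride_dtw_flat(probe),
                         lapply(gallery_strides, stride_dtw_flat), w)
  colnames(out) <- c("rho_MSt_L", "rho_TSt_L", "rho_MSt_R", "rho_TSt_R",
                     "rho_Stride")
  ids <- vapply(gallery_strides, function(s) s$subject_id, character(1))
  cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE),
        as.data.frame(out))
}

#' Assemble the six-element fusion vector
#'
#' The fusion vector pairs the five DTW distances of a probe/gallery
#' stride pair with the probe's measured body height:
#' `[rho_MSt_L; rho_TSt_L; rho_MSt_R; rho_TSt_R; rho_Stride; BH]`.
#'
#' @param probe,gallery `stride_record` objects.
#' @param bh_cm Probe body height in cm (> 0).
#' @inheritParams phase_distance
#' @return Named numeric vector of length 6.
#' @export
distance_vector <- function(probe, gallery, bh_cm, window = NULL) {
  if (!is.numeric(bh_cm) || length(bh_cm) != 1L || bh_cm <= 0)
    stop("distance_vector: 'bh_cm' must be a positive height in cm")
  c(rho_MSt_L = phase_distance(probe, gallery, "MSt", "L", window),
    rho_TSt_L = phase_distance(probe, gallery, "TSt", "L", window),
    rho_MSt_R = phase_distance(probe, gallery, "MSt", "R", window),
    rho_TSt_R = phase_distance(probe, gallery, "TSt", "R", window),
    rho_Stride = stride_distance(probe, gallery, window),
    BH = bh_cm)
}
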