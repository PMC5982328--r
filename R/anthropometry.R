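# Segment chains of the body-height model.  Trunk segments are summed;
# the two leg chains are averaged.  Each segment needs both endpoint
# joints fully tracked; a failed leg segment falls back to the
# contralateral segment (averaged over whichever sensors supply it).
trunk_segments <- list(c("head", "neck"), c("neck", "spine_shoulder"),
                       c("spine_shoulder", "spine_mid"),
                       c("spine_mid", "spine_base"))
leg_segments <- list(L = list(c("hip_L", "knee_L"), c("knee_L", "ankle_L"),
                              c("ankle_L", "foot_L")),
                     R = list(c("hip_R", "knee_R"), c("knee_R", "ankle_R"),
                              c("ankle_R", "foot_R")))

# Per-frame chain heights (cm) for a whole log, vectorised over frames.
# Returns a numeric vector (NA = frame unresolvable -> skipped).
chain_heights <- function(log, head_top_offset = head_top_offset_default) {
  ts <- sort(unique(log$timestamp))
  nf <- length(ts)
  nj <- length(skeleton_joints)
  jn <- names(skeleton_joints)
  fidx <- match(log$timestamp, ts)
  jidx <- match(log$joint_id, skeleton_joints)

  mats <- lapply(1:2, function(sensor) {
    sel <- which(log$sensor_id == sensor & !is.na(jidx))
    idx <- cbind(fidx[sel], jidx[sel])
    mk <- function(v, default = NA_real_) {
      m <- matrix(default, nf, nj, dimnames = list(NULL, jn))
      m[idx] <- v[sel]
      m
    }
    list(x = mk(log$x), y = mk(log$y), z = mk(log$z),
         ok = {
           m <- matrix(FALSE, nf, nj, dimnames = list(NULL, jn))
           m[idx] <- log$tracking_state[sel] == "fully_tracked"
           m
         })
  })

  seg_len <- function(s, pair) {
    a <- pair[1]; b <- pair[2]
    len <- sqrt((s$x[, a] - s$x[, b])^2 + (s$y[, a] - s$y[, b])^2 +
                  (s$z[, a] - s$z[, b])^2)
    len[!(s$ok[, a] & s$ok[, b])] <- NA_real_
    len
  }
  both_sensor_mean <- function(pair) {
    m <- rowMeans(cbind(seg_len(mats[[1]], pair), seg_len(mats[[2]], pair)),
                  na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }

  trunk <- rowSums(do.call(cbind, lapply(trunk_segments, both_sensor_mean)))

  leg_chain <- function(side) {
    other <- if (side == "L") "R" else "L"
    vals <- lapply(seq_along(leg_segments[[side]]), function(i) {
      own <- both_sensor_mean(leg_segments[[side]][[i]])
      contra <- both_sensor_mean(leg_segments[[other]][[i]])
      ifelse(is.na(own), contra, own)
    })
    rowSums(do.call(cbind, vals))
  }
  legs <- (leg_chain("L") + leg_chain("R")) / 2
  h <- (trunk + legs) * 100 + head_top_offset
  h[!is.finite(h)] <- NA_real_
  unname(h)
}

#' Body height of a single skeleton frame
#'
#' Applies the chain model to one frame: trunk segments (head, neck,
#' spine shoulder, spine mid, spine base) are summed and the two leg
#' chains (hip, knee, ankle, foot) averaged, plus a fixed head-top
#' offset.  A segment contributes only if both endpoint joints are
#' fully tracked; a failed leg segment is replaced by the contralateral
#' segment, falling back across sensors; values available from both
#' sensors are averaged per segment.  An unresolvable frame yields `NA`
#' (the measurement is omitted).
#'
#' @param frame_log Rows of a `skeleton_log` belonging to one timestamp
#'   (either or both sensors).
#' @param head_top_offset Offset (cm) covering head-joint-to-vertex and
#'   foot-joint-to-ground; must match the value used at generation for
#'   the round trip to be exact.
#' @return Height in cm, or `NA` if the frame is unresolvable.
#' @export
frame_height <- function(frame_log, head_top_offset = head_top_offset_default) {
  if (length(unique(frame_log$timestamp)) > 1L)
    stop("frame_height: 'frame_log' must contain a single timestamp")
  chain_heights(frame_log, head_top_offset)[1L]
}

#' Estimate body height from a skeleton frame log
#'
#' Mean of the per-frame chain heights over all usable frames.
#' Recording several gait cycles averages out the within-cycle
#' head-height oscillation and the per-frame sensor noise, so the mean
#' approaches the subject's standing height in the worn footwear.
#'
#' @param log A `skeleton_log` (see [synth_skeleton_stream()] and
#'   [read_skeleton()]).
#' @inheritParams frame_height
#' @return Height in cm with attributes `n_frames_used` and
#'   `n_frames_skipped`.
#' @export
estimate_body_height <- function(log, head_top_offset = head_top_offset_default) {
  h <- chain_heights(log, head_top_offset)
  used <- sum(!is.na(h))
  if (used == 0L)
    stop("estimate_body_height: no usable frames (all frames unresolvable)")
  structure(mean(h, na.rm = TRUE),
            n_frames_used = used, n_frames_skipped = sum(is.na(h)))
}

#' Footwear correction of a measured body height
#'
#' High heels raise the measured walking height by close to 5 cm on
#' average, so when the footwear classifier reports heels (`y = 1`) the
#' rounded correction of 5 cm is subtracted before the height gate:
#' `BH_norm = BH_measured - 5 * y`.
#'
#' @param bh_measured Measured height (cm, > 0).
#' @param y Footwear label: 0 = sport shoes, 1 = high heels.
#' @param correction_cm Correction constant (cm), default 5.
#' @return The corrected height `BH_norm` (cm).
#' @examples
#' normalize_height(170, 1)  # 165
#' @export
normalize_height <- function(bh_measured, y, correction_cm = 5) {
  if (!is.numeric(bh_measured) || length(bh_measured) != 1L ||
      is.na(bh_measured) || bh_measured <= 0)
    stop("normalize_height: 'bh_measured' must be a positive height in cm")
  if (!(y %in% c(0, 1)))
    stop("normalize_height: 'y' must be 0 (sport) or 1 (heels)")
  bh_measured - correction_cm * y
}

#' Reduce a gallery by the body-height gate
#'
#' Retains only subjects whose enrolled (sport-shoe) height lies within
#' `tol_cm` of the corrected probe height; subjects differing by more
#' than the tolerance are excluded from the candidate set.  The result
#' may be empty, in which case identification yields `NONE`.
#'
#' @param gallery A `gait_gallery` (see [enroll_gallery()]).
#' @param bh_norm Corrected probe height (cm).
#' @param tol_cm Gate half-width (cm), default 2; boundary inclusive.
#' @return The gallery restricted to the retained subjects.
#' @export
reduce_gallery <- function(gallery, bh_norm, tol_cm = 2) {
  stopifnot(inherits(gallery, "gait_gallery"))
  keep <- names(gallery$heights)[abs(gallery$heights - bh_norm) <= tol_cm]
  subset_gallery(gallery, keep)
}
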