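#' Enroll a gallery of reference strides
#'
#' @param strides List of `stride_record`s (the enrollment order defines
#'   the tie-break order of the voters).
#' @param heights Named numeric vector of enrolled body heights (cm),
#'   one per subject, measured in sport shoes.
#' @return A `gait_gallery`: list with `strides` (DTW fragments
#'   pre-computed), `subject_id` (per stride) and `heights`.
#' @export
enroll_gallery <- function(strides, heights) {
  if (length(strides) == 0L) stop("enroll_gallery: no strides")
  ids <- vapply(strides, function(s) s$subject_id, character(1))
  if (is.null(names(heights)) || !all(unique(ids) %in% names(heights)))
    stop("enroll_gallery: 'heights' must be named and cover every enrolled subject")
  structure(list(strides = lapply(strides, cache_dtw_parts),
                 subject_id = ids,
                 heights = heights[unique(ids)]),
            class = "gait_gallery")
}

subset_gallery <- function(gallery, keep_subjects) {
  sel <- gallery$subject_id %in% keep_subjects
  structure(list(strides = gallery$strides[sel],
                 subject_id = gallery$subject_id[sel],
                 heights = gallery$heights[names(gallery$heights) %in% keep_subjects]),
            class = "gait_gallery")
}

#' @export
print.gait_gallery <- function(x, ...) {
  cat(sprintf("<gait_gallery> %d strides from %d subjects\n",
              length(x$strides), length(x$heights)))
  invisible(x)
}

#' Voting configuration of the recognition ensemble
#'
#' @param k Number of nearest neighbours per base voter (default 5).
#' @param Th Rejection threshold on the winning total weight; `Th = 0`
#'   is the most liberal strategy (reject only on ties or an empty
#'   candidate set).
#' @return A `vote_config` list.
#' @export
vote_config <- function(k = 5L, Th = 0) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("vote_config: 'k' must be >= 1")
  if (!is.numeric(Th) || length(Th) != 1L || Th < 0)
    stop("vote_config: 'Th' must be a nonnegative number")
  structure(list(k = k, Th = Th), class = "vote_config")
}

#' Rank-order voting weights
#'
#' Weight of the neighbour at rank R among k: `w_R = (k + 1 - R) / k`,
#' strictly decreasing from 1 (nearest) to 1/k (k-th).
#'
#' @param k Number of neighbours (>= 1).
#' @return Numeric vector of length `k`.
#' @examples
#' rank_weights(5)  # 1.0 0.8 0.6 0.4 0.2
#' @export
rank_weights <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("rank_weights: 'k' must be >= 1")
  (k + 1 - seq_len(k)) / k
}

#' Ranked labels of one base nearest-neighbour voter
#'
#' Orders the gallery strides of one distance column by increasing
#' distance and returns the class labels of the `k` nearest, ties on
#' distance broken by enrollment order (stable sort).  When the
#' (reduced) gallery holds fewer than `k` strides all labels are
#' returned, ranked; an empty gallery yields an empty vote.
#'
#' @param distances Numeric vector of distances, one per gallery stride,
#'   in enrollment order.
#' @param labels Class (subject) label of each gallery stride.
#' @param k Neighbour count.
#' @return Character vector of at most `k` labels, nearest first.
#' @export
base_votes <- function(distances, labels, k) {
  if (length(distances) != length(labels))
    stop("base_votes: 'distances' and 'labels' lengths differ")
  if (length(distances) == 0L) return(character(0))
  k_eff <- min(as.integer(k), length(distances))
  ord <- order(distances)            # stable: ties keep enrollment order
  as.character(labels[ord[seq_len(k_eff)]])
}

#' Decision of the rank-weighted voting ensemble
#'
#' Each of the five base voters contributes, for every neighbour of
#' class i at rank R, the weight `w_R = (k + 1 - R)/k`; a class
#' occupying several ranks within one voter accumulates all of its
#' ranks' weights.  Class totals are summed across voters and the label
#' with the largest total wins.  The probe is rejected (`NONE`) if at
#' least two classes share the maximal total, if the winning total is
#' below the threshold `Th`, or if no votes were cast (empty candidate
#' set).
#'
#' @param vote_lists List of ranked label vectors, one per base voter
#'   (normally five, one per distance).
#' @param config A [vote_config()].
#' @return A `vote_outcome`: list with `totals` (named numeric),
#'   `decided` (label or `"NONE"`) and `top_total`.
#' @export
ensemble_decide <- function(vote_lists, config = vote_config()) {
  stopifnot(inherits(config, "vote_config"))
  w <- rank_weights(config$k)
  totals <- numeric(0)
  for (votes in vote_lists) {
    if (length(votes) == 0L) next
    for (r in seq_along(votes)) {
      lab <- votes[r]
      totals[lab] <- (if (is.na(totals[lab])) 0 else totals[lab]) + w[r]
    }
  }
  if (length(totals) == 0L)
    return(structure(list(totals = totals, decided = "NONE", top_total = 0),
                     class = "vote_outcome"))
  top <- max(totals)
  winners <- names(totals)[abs(totals - top) < 1e-12]
  decided <- if (length(winners) > 1L || top < config$Th) "NONE" else winners[1L]
  structure(list(totals = totals, decided = decided, top_total = top),
            class = "vote_outcome")
}

#' @export
print.vote_outcome <- function(x, ...) {
  cat(sprintf("<vote_outcome> decided: %s (top total %.3f)\n",
              x$decided, x$top_total))
  invisible(x)
}

# Fast path shared with the scenario harness: votes from a precomputed
# distance profile restricted to a set of retained subjects.
decide_from_profile <- function(profile, keep_subjects = NULL,
                                config = vote_config()) {
  if (!is.null(keep_subjects)) {
    profile <- profile[profile$subject_id %in% keep_subjects, , drop = FALSE]
  }
  cols <- c("rho_MSt_L", "rho_TSt_L", "rho_MSt_R", "rho_TSt_R", "rho_Stride")
  votes <- lapply(cols, function(cl)
    base_votes(profile[[cl]], profile$subject_id, config$k))
  ensemble_decide(votes, config)
}

#' Identify the subject of a probe stride
#'
#' Runs the full two-stage pipeline: footwear recognition from the
#' probe's loading-response GRF, footwear correction of the measured
#' body height, height-gated gallery reduction, the five DTW distance
#' profiles, and the rank-weighted ensemble vote with open-set
#' rejection.
#'
#' @param probe A `stride_record`.
#' @param bh_measured Probe body height (cm) measured during the walk
#'   (e.g. [estimate_body_height()] of the probe's skeleton log); may be
#'   `NULL` when `use_height_gate = FALSE`.
#' @param gallery A `gait_gallery`.
#' @param config A [vote_config()].
#' @param classifier A trained footwear classifier
#'   ([train_footwear()]); ignored if `footwear_y` is given.
#' @param footwear_y Optional known footwear label (0/1) bypassing the
#'   classifier (the perfect-footwear scenario).
#' @param use_height_gate If `FALSE`, skip footwear recognition and the
#'   height gate and vote over the whole gallery (GRF-only operation).
#' @param tol_cm Height-gate half-width (cm).
#' @param window Optional Sakoe--Chiba half-width for the DTW.
#' @return A `vote_outcome` with extra fields `footwear_y`, `bh_norm`
#'   and `n_candidates` (strides in the reduced gallery).
#' @export
identify <- function(probe, bh_measured = NULL, gallery,
                     config = vote_config(), classifier = NULL,
                     footwear_y = NULL, use_height_gate = TRUE,
                     tol_cm = 2, window = NULL) {
  stopifnot(inherits(gallery, "gait_gallery"))
  y <- NA
  gal <- gallery
  bh_norm <- NA_real_
  if (use_height_gate) {
    if (is.null(bh_measured))
      stop("identify: 'bh_measured' is required when the height gate is on")
    y <- if (!is.null(footwear_y)) footwear_y
         else if (!is.null(classifier))
           predict_footwear(classifier, lr_poly_features(probe))
         else stop("identify: need 'classifier' or 'footwear_y' for the height gate")
    bh_norm <- normalize_height(bh_measured, y)
    gal <- reduce_gallery(gallery, bh_norm, tol_cm)
  }
  if (length(gal$strides) == 0L) {
    out <- structure(list(totals = numeric(0), decided = "NONE", top_total = 0),
                     class = "vote_outcome")
  } else {
    profile <- distance_profile(probe, gal$strides, window)
    out <- decide_from_profile(profile, NULL, config)
  }
  out$footwear_y <- y
  out$bh_norm <- bh_norm
  out$n_candidates <- length(gal$strides)
  out
}
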