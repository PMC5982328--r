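#' Confusion counts of a binary decision
#'
#' @param truth,pred Vectors of 0/1 labels (1 = positive class, here
#'   high heels).
#' @return A `confusion_counts` list with `TP`, `FN`, `TN`, `FP`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  structure(list(TP = sum(truth == 1 & pred == 1),
                 FN = sum(truth == 1 & pred == 0),
                 TN = sum(truth == 0 & pred == 0),
                 FP = sum(truth == 0 & pred == 1)),
            class = "confusion_counts")
}

#' Sensitivity and specificity in percent
#'
#' `Sensitivity = TP / (TP + FN) * 100`,
#' `Specificity = TN / (TN + FP) * 100`.
#'
#' @param counts A [confusion_counts()] object or a list with `TP`,
#'   `FN`, `TN`, `FP`.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @examples
#' sens_spec(list(TP = 95, FN = 5, TN = 90, FP = 10))  # 95, 90
#' @export
sens_spec <- function(counts) {
  with(counts, {
    if (any(c(TP, FN, TN, FP) < 0)) stop("sens_spec: negative counts")
    if (TP + FN == 0) stop("sens_spec: TP + FN = 0, sensitivity undefined")
    if (TN + FP == 0) stop("sens_spec: TN + FP = 0, specificity undefined")
    c(sensitivity = TP / (TP + FN) * 100, specificity = TN / (TN + FP) * 100)
  })
}

#' Open-set identification rates
#'
#' Over the enrolled probes: CCR is the percentage decided as the true
#' subject, FRR the percentage rejected as `NONE`, FAR the percentage
#' assigned to a wrong subject; the three partition the probes and sum
#' to 100.  If an `enrolled` flag marks impostor probes (subjects absent
#' from the gallery) their acceptance rate is reported separately as the
#' attribute `impostor_far`.
#'
#' @param decisions Data frame with columns `true` and `decided`
#'   (`"NONE"` for rejections) and optionally `enrolled` (logical).
#' @return One-row data frame with `CCR`, `FRR`, `FAR` (percent,
#'   unrounded) and `n` (number of enrolled probes scored).
#' @export
identification_metrics <- function(decisions) {
  stopifnot(is.data.frame(decisions), nrow(decisions) > 0,
            all(c("true", "decided") %in% names(decisions)))
  enrolled <- if ("enrolled" %in% names(decisions)) decisions$enrolled
              else rep(TRUE, nrow(decisions))
  d <- decisions[enrolled, , drop = FALSE]
  if (nrow(d) == 0L) stop("identification_metrics: no enrolled probes")
  out <- data.frame(CCR = 100 * mean(d$decided == d$true),
                    FRR = 100 * mean(d$decided == "NONE"),
                    FAR = 100 * mean(d$decided != d$true & d$decided != "NONE"),
                    n = nrow(d))
  if (any(!enrolled)) {
    imp <- decisions[!enrolled, , drop = FALSE]
    attr(out, "impostor_far") <- 100 * mean(imp$decided != "NONE")
  }
  out
}

#' ROC curve over a sweep of rejection thresholds
#'
#' Re-applies the rejection rule `top_total < Th` to recorded decisions
#' for every threshold in the sweep, plots the correct-classification
#' fraction against the false-acceptance fraction, and integrates the
#' area under the curve by the trapezoidal rule.  The curve is anchored
#' at (0, 0) and (1, 1); duplicate threshold entries collapse to one
#' point.
#'
#' @param decisions Data frame with columns `true`, `decided` and
#'   `total` (the winning ensemble total at `Th = 0`).
#' @param thresholds Numeric vector of at least 2 distinct thresholds.
#' @return List with `points` (data frame `Th`, `far`, `ccr`) and `auc`.
#' @export
roc_curve <- function(decisions, thresholds) {
  stopifnot(is.data.frame(decisions),
            all(c("true", "decided", "total") %in% names(decisions)))
  thresholds <- sort(unique(thresholds))
  if (length(thresholds) < 2L)
    stop("roc_curve: need at least 2 distinct thresholds")
  pts <- do.call(rbind, lapply(thresholds, function(th) {
    dec <- ifelse(decisions$total < th, "NONE", decisions$decided)
    data.frame(Th = th,
               far = mean(dec != decisions$true & dec != "NONE"),
               ccr = mean(dec == decisions$true))
  }))
  xy <- unique(rbind(data.frame(x = 0, y = 0),
                     data.frame(x = pts$far, y = pts$ccr),
                     data.frame(x = 1, y = 1)))
  xy <- xy[order(xy$x, xy$y), ]
  auc <- sum(diff(xy$x) * (head(xy$y, -1) + xy$y[-1]) / 2)
  list(points = pts, auc = auc)
}

clone_population_config <- function(cfg, n_subjects, seed) {
  cfg$n_subjects <- as.integer(n_subjects)
  cfg$seed <- as.integer(seed)
  cfg
}

# Decisions of one scenario over precomputed probe profiles.
scenario_decisions <- function(scenario, ds, profiles, config, tol_cm,
                               classifier = NULL, probe_features = NULL) {
  gated <- scenario %in% c("c", "d", "e")
  rows <- lapply(seq_along(ds$probes), function(p) {
    pr <- ds$probes[[p]]
    keep <- NULL
    if (gated) {
      y <- if (scenario == "e") pr$true_y
           else predict_footwear(classifier, probe_features[p, , drop = FALSE])
      bh_norm <- normalize_height(pr$bh_measured, y)
      keep <- names(ds$gallery$heights)[abs(ds$gallery$heights - bh_norm) <= tol_cm]
    }
    out <- decide_from_profile(profiles[[p]], keep, config)
    data.frame(true = pr$subject_id, decided = out$decided,
               total = out$top_total, footwear = pr$footwear)
  })
  do.call(rbind, rows)
}

#' Run the evaluation scenarios on synthetic populations
#'
#' Reproduces the structure of the standard experiment grid: for each
#' repetition a population of `n_subjects` is drawn (or subsampled from
#' a supplied master population), a gallery/probe dataset is built per
#' the scenario's footwear plan, and every probe stride is identified.
#' Scenarios:
#' \describe{
#'   \item{a}{sport shoes in gallery and probes, GRF only;}
#'   \item{b}{gallery sport-only, probes mixed, GRF only;}
#'   \item{c}{as (a) plus footwear recognition and the height gate;}
#'   \item{d}{as (b) plus footwear recognition and the height gate;}
#'   \item{e}{as (d) with perfect footwear labels.}
#' }
#' Scenarios sharing a dataset within one repetition (a with c, and b
#' with d, e) reuse the same strides and DTW profiles, so rate
#' differences between them reflect the pipeline stages only.  The
#' footwear classifier is trained per repetition on separate strides of
#' the same population (both footwear types, all subjects).
#'
#' @param scenario Character vector of scenarios to run, subset of
#'   `c("a","b","c","d","e")`.
#' @param n_subjects Population (gallery) size per repetition.
#' @param repetitions Number of seeded repetitions.
#' @param seed Root seed of the whole grid.
#' @param gen_config Generator configuration template
#'   ([population_config()]); its `n_subjects`/`seed` are overridden.
#' @param population Optional master population to subsample from
#'   (errors if `n_subjects` exceeds its size).
#' @param per_subject_strides Strides per subject per planned footwear.
#' @param n_train_strides Strides per subject per footwear used to train
#'   the footwear classifier.
#' @param sampling_rate_hz Force-plate rate used for the simulated
#'   strides (the default trades sampling density for runtime; distances
#'   are rate-consistent within a run).
#' @param n_cycles_height Gait cycles per height-measurement walk.
#' @param config A [vote_config()].
#' @param tol_cm Height-gate half-width (cm).
#' @param classifier_method Footwear classifier, `"svm"` or `"knn"`.
#' @param keep_decisions Attach per-probe decisions (for ROC analysis)
#'   as attribute `"decisions"`.
#' @return Data frame with one row per scenario and repetition:
#'   `scenario`, `n_subjects`, `repetition`, `CCR`, `FRR`, `FAR`
#'   (percent, rounded to 2 decimals) and `n_probes`.
#' @export
run_scenario <- function(scenario = c("a", "b", "d", "e"), n_subjects = 50L,
                         repetitions = 10L, seed = 1L,
                         gen_config = population_config(),
                         population = NULL,
                         per_subject_strides = 4L, n_train_strides = 2L,
                         sampling_rate_hz = 120, n_cycles_height = 3L,
                         config = vote_config(), tol_cm = 2,
                         classifier_method = c("svm", "knn"),
                         keep_decisions = FALSE) {
  scenario <- match.arg(scenario, c("a", "b", "c", "d", "e"), several.ok = TRUE)
  classifier_method <- match.arg(classifier_method)
  if (!is.null(population) && n_subjects > length(population))
    stop("run_scenario: subset size ", n_subjects,
         " exceeds population of ", length(population))
  need_mixed <- any(scenario %in% c("b", "d", "e"))
  need_sport <- any(scenario %in% c("a", "c"))
  need_clf <- any(scenario %in% c("c", "d"))

  report <- list()
  decisions_all <- list()
  for (rep in seq_len(repetitions)) {
    rep_seed <- mix_seed(seed, rep, 17L)
    pop <- if (is.null(population)) {
      sample_population(clone_population_config(gen_config, n_subjects, rep_seed))
    } else {
      with_seed(rep_seed, sample(population, n_subjects))
    }

    classifier <- NULL
    if (need_clf) {
      train_strides <- unlist(lapply(seq_along(pop), function(i) {
        lapply(c("sport", "heels"), function(fw)
          lapply(seq_len(n_train_strides), function(j)
            synth_grf_stride(pop[[i]], fw,
                             stride_seed = mix_seed(rep_seed, i, 900L, j,
                                                    as.integer(fw == "heels")),
                             sampling_rate_hz = sampling_rate_hz)))
      }), recursive = FALSE)
      train_strides <- unlist(train_strides, recursive = FALSE)
      classifier <- train_footwear(footwear_features(train_strides),
                                   method = classifier_method, seed = rep_seed)
    }

    run_group <- function(plan_scen, group_scens) {
      ds <- build_dataset(pop, per_subject_strides,
                          footwear_plan = scenario_plan(plan_scen),
                          seed = mix_seed(rep_seed, 23L),
                          sampling_rate_hz = sampling_rate_hz,
                          n_cycles_height = n_cycles_height)
      profiles <- lapply(ds$probes, function(pr)
        distance_profile(pr$stride, ds$gallery$strides))
      feats <- if (need_clf)
        as.data.frame(t(vapply(ds$probes, function(pr)
          lr_poly_features(pr$stride), numeric(24)))) else NULL
      for (sc in group_scens) {
        dec <- scenario_decisions(sc, ds, profiles, config, tol_cm,
                                  classifier, feats)
        m <- identification_metrics(dec)
        report[[length(report) + 1L]] <<- data.frame(
          scenario = sc, n_subjects = n_subjects, repetition = rep,
          CCR = round(m$CCR, 2), FRR = round(m$FRR, 2), FAR = round(m$FAR, 2),
          n_probes = m$n)
        if (keep_decisions) {
          dec$scenario <- sc; dec$repetition <- rep
          decisions_all[[length(decisions_all) + 1L]] <<- dec
        }
      }
    }
    if (need_sport) run_group("a", intersect(scenario, c("a", "c")))
    if (need_mixed) run_group("b", intersect(scenario, c("b", "d", "e")))
  }
  out <- do.call(rbind, report)
  if (keep_decisions) attr(out, "decisions") <- do.call(rbind, decisions_all)
  out
}

#' Summarise a scenario report
#'
#' Mean rates per scenario and population size, shaped like the standard
#' results tables.
#'
#' @param report Output of [run_scenario()].
#' @return Data frame with mean `CCR`, `FRR`, `FAR` per scenario and
#'   `n_subjects`, rounded to 2 decimals.
#' @export
summarize_scenarios <- function(report) {
  agg <- stats::aggregate(report[, c("CCR", "FRR", "FAR")],
                          by = report[, c("scenario", "n_subjects")],
                          FUN = mean)
  agg$CCR <- round(agg$CCR, 2); agg$FRR <- round(agg$FRR, 2)
  agg$FAR <- round(agg$FAR, 2)
  agg[order(agg$scenario, agg$n_subjects), ]
}
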