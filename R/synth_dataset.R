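#' Footwear plan of a gallery/probe experiment
#'
#' Maps the five evaluation scenarios onto enrollment/probe footwear:
#' scenarios (a) and (c) use sport shoes in both sets; (b), (d) and (e)
#' enroll sport shoes only while probes mix sport shoes and high heels.
#'
#' @param scenario One of `"a"` ... `"e"`.
#' @return List with character vectors `gallery` and `probe`.
#' @export
scenario_plan <- function(scenario = c("a", "b", "c", "d", "e")) {
  scenario <- match.arg(scenario)
  if (scenario %in% c("a", "c"))
    list(gallery = "sport", probe = "sport")
  else
    list(gallery = "sport", probe = c("sport", "heels"))
}

#' Build a labeled gallery/probe dataset
#'
#' Generates, per subject and per footwear type named in the plan,
#' `per_subject_strides` GRF strides, splits them disjointly between
#' gallery and probe (footwear present in both sets: the first half,
#' rounded up, enrolls; footwear present in only one set contributes all
#' its strides there), and measures body heights from synthetic skeleton
#' streams: one sport-shoe enrollment walk per subject and one walk per
#' probe footwear.  Fully deterministic given `seed`.
#'
#' @param population List of `subject_params` from [sample_population()].
#' @param per_subject_strides Strides generated per subject per planned
#'   footwear.
#' @param footwear_plan List with `gallery` and `probe` footwear label
#'   vectors (see [scenario_plan()]); labels must be `"sport"` or
#'   `"heels"`.
#' @param seed Integer root seed of the dataset.
#' @param sampling_rate_hz Force-plate rate for the generated strides.
#' @param n_cycles_height Gait cycles per skeleton walk used for height
#'   measurement.
#' @return A `gait_dataset`: list with `gallery` (a [enroll_gallery()]
#'   object), `probes` (list of `stride`, `subject_id`, `footwear`,
#'   `true_y`, `bh_measured`) and the plan/seed used.
#' @export
build_dataset <- function(population, per_subject_strides = 4L,
                          footwear_plan = scenario_plan("a"), seed = 1L,
                          sampling_rate_hz = NULL, n_cycles_height = 3L) {
  fw_all <- unique(c(footwear_plan$gallery, footwear_plan$probe))
  if (length(footwear_plan$probe) == 0L)
    stop("build_dataset: footwear plan requests no probe footwear")
  if (!all(fw_all %in% c("sport", "heels")))
    stop("build_dataset: unknown footwear label in plan: ",
         paste(setdiff(fw_all, c("sport", "heels")), collapse = ", "))
  ns <- as.integer(per_subject_strides)
  if (is.na(ns) || ns < 1L) stop("build_dataset: 'per_subject_strides' must be >= 1")

  gallery_strides <- list()
  probes <- list()
  heights <- numeric(0)
  fw_code <- c(sport = 1L, heels = 2L)
  for (i in seq_along(population)) {
    subj <- population[[i]]
    enroll_log <- synth_skeleton_stream(subj, "sport", n_cycles = n_cycles_height,
                                        seed = mix_seed(seed, i, 100L))
    heights[subj$subject_id] <- as.numeric(estimate_body_height(enroll_log))
    for (fw in fw_all) {
      strides <- lapply(seq_len(ns), function(j)
        synth_grf_stride(subj, fw, stride_seed = mix_seed(seed, i, fw_code[[fw]], j),
                         sampling_rate_hz = sampling_rate_hz))
      in_gal <- fw %in% footwear_plan$gallery
      in_probe <- fw %in% footwear_plan$probe
      n_gal <- if (in_gal && in_probe) ceiling(ns / 2) else if (in_gal) ns else 0L
      if (n_gal > 0L)
        gallery_strides <- c(gallery_strides, strides[seq_len(n_gal)])
      if (in_probe && n_gal < ns) {
        probe_log <- synth_skeleton_stream(subj, fw, n_cycles = n_cycles_height,
                                           seed = mix_seed(seed, i, 200L + fw_code[[fw]]))
        bh <- as.numeric(estimate_body_height(probe_log))
        for (st in strides[(n_gal + 1L):ns]) {
          probes[[length(probes) + 1L]] <-
            list(stride = st, subject_id = subj$subject_id, footwear = fw,
                 true_y = as.integer(fw == "heels"), bh_measured = bh)
        }
      }
    }
  }
  structure(list(gallery = enroll_gallery(gallery_strides, heights),
                 probes = probes, plan = footwear_plan, seed = seed),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("<gait_dataset> gallery: %d strides / %d subjects; probes: %d (%s)\n",
              length(x$gallery$strides), length(x$gallery$heights),
              length(x$probes),
              paste(x$plan$probe, collapse = "+")))
  invisible(x)
}
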