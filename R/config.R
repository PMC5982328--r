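#' Default run configuration
#'
#' Nested list of every tunable of the pipeline, suitable for YAML
#' serialisation: generator parameters (see [population_config()]), DTW
#' options, footwear classifier options, voting parameters and the
#' height gate.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    generator = unclass(population_config())[
      setdiff(names(population_config()), c("n_subjects", "seed"))],
    dtw = list(window = NULL),
    footwear = list(method = "svm", kernel = "radial", cost = 1, k = 3L),
    vote = list(k = 5L, Th = 0),
    height = list(tol_cm = 2, correction_cm = 5,
                  head_top_offset_cm = head_top_offset_default)
  )
}

check_config_keys <- function(cfg, ref, path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown) > 0L)
    stop("config: unknown key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(cfg[[k]]))
      check_config_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) && !is.null(names(base[[k]])))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read a YAML run configuration
#'
#' Values in the file override the defaults of [default_config()];
#' unknown keys are rejected.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return The merged configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  check_config_keys(user, cfg)
  merge_config(cfg, user)
}

#' Write a run configuration to YAML
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# population_config from the generator section of a run configuration.
config_to_population <- function(cfg, n_subjects, seed) {
  do.call(population_config,
          c(list(n_subjects = n_subjects, seed = seed), cfg$generator))
}
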