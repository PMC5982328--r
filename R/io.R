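stride_columns <- c("time_s", "fx_L", "fy_L", "fz_L", "fx_R", "fy_R", "fz_R")
skeleton_columns <- c("timestamp", "sensor_id", "joint_id", "x", "y", "z",
                      "tracking_state")
tracking_states <- c("fully_tracked", "inferred", "not_tracked")

read_meta_header <- function(path, n = 10L) {
  lines <- readLines(path, n = n)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- sub("^#\\s*", "", l)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  meta
}

#' Write a stride record to CSV
#'
#' One file per stride: `# key: value` metadata header lines
#' (`subject_id`, `footwear`, `body_weight_N`, `sampling_rate_hz`,
#' `cycle_s`) followed by the columns `time_s, fx_L, fy_L, fz_L, fx_R,
#' fy_R, fz_R` in newtons, UTF-8, `.` decimal separator.
#'
#' @param stride A `stride_record`.
#' @param path Output file path.
#' @export
write_stride <- function(stride, path) {
  stopifnot(inherits(stride, "stride_record"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s",
                     c("subject_id", "footwear", "body_weight_N",
                       "sampling_rate_hz", "cycle_s"),
                     c(stride$subject_id, stride$footwear,
                       format(stride$body_weight_N, digits = 12),
                       format(stride$sampling_rate_hz, digits = 12),
                       format(stride$cycle_s, digits = 12))), con)
  write.csv(stride$series[, stride_columns], con, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

read_stride_file <- function(path) {
  meta <- read_meta_header(path)
  for (key in c("subject_id", "footwear", "body_weight_N", "sampling_rate_hz"))
    if (is.null(meta[[key]]))
      stop("read_strides: ", path, ": missing metadata header '", key, "'")
  if (!meta$footwear %in% c("sport", "heels"))
    stop("read_strides: ", path, ": unknown footwear '", meta$footwear, "'")
  bw <- as.numeric(meta$body_weight_N)
  rate <- as.numeric(meta$sampling_rate_hz)
  if (is.na(bw) || bw <= 0)
    stop("read_strides: ", path, ": body_weight_N must be a positive number")
  if (is.na(rate) || rate <= 0)
    stop("read_strides: ", path, ": sampling_rate_hz must be a positive number")
  df <- read.csv(path, comment.char = "#", colClasses = "numeric")
  if (nrow(df) == 0L) stop("read_strides: ", path, ": no samples")
  missing <- setdiff(stride_columns, names(df))
  if (length(missing) > 0L)
    stop("read_strides: ", path, ": missing column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), stride_columns)
  if (length(extra) > 0L)
    stop("read_strides: ", path, ": unknown column(s): ",
         paste(extra, collapse = ", "))
  bad <- which(!stats::complete.cases(df))
  if (length(bad) > 0L)
    stop("read_strides: ", path, ": malformed row(s) at line ",
         paste(utils::head(bad, 5) + length(grep("^#", readLines(path))) + 1L,
               collapse = ", "))
  dt <- diff(df$time_s)
  if (nrow(df) > 1 && any(abs(dt - 1 / rate) > 1e-6))
    stop("read_strides: ", path, ": non-uniform time step (expected ",
         format(1 / rate), " s)")
  structure(list(subject_id = meta$subject_id, footwear = meta$footwear,
                 body_weight_N = bw, sampling_rate_hz = rate,
                 stance_s = nrow(df) / rate,
                 cycle_s = if (!is.null(meta$cycle_s)) as.numeric(meta$cycle_s)
                           else NA_real_,
                 series = df[, stride_columns]),
            class = "stride_record")
}

#' Read stride records from CSV
#'
#' @param path A stride CSV file, or a directory of `*.csv` stride
#'   files (read in lexicographic order).
#' @return A list of `stride_record`s.
#' @seealso [write_stride()] for the format.
#' @export
read_strides <- function(path) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  } else path
  if (length(files) == 0L) stop("read_strides: no CSV files in ", path)
  lapply(files, read_stride_file)
}

#' Write a skeleton frame log to CSV
#'
#' Columns `timestamp, sensor_id, joint_id, x, y, z, tracking_state`
#' preceded by `# subject_id` / `# footwear` metadata lines when known.
#'
#' @param log A `skeleton_log`.
#' @param path Output file path.
#' @export
write_skeleton <- function(log, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  meta <- c(subject_id = attr(log, "subject_id"), footwear = attr(log, "footwear"))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  if (length(meta) > 0L)
    writeLines(sprintf("# %s: %s", names(meta), unlist(meta)), con)
  write.csv(as.data.frame(log)[, skeleton_columns], con, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a skeleton frame log from CSV
#'
#' Validates sensor ids (1 or 2), joint ids and tracking states; frames
#' out of timestamp order are sorted with a warning.
#'
#' @param path Skeleton CSV file.
#' @return A `skeleton_log` data frame.
#' @export
read_skeleton <- function(path) {
  df <- read.csv(path, comment.char = "#",
                 colClasses = c(timestamp = "numeric", sensor_id = "integer",
                                joint_id = "integer", x = "numeric",
                                y = "numeric", z = "numeric",
                                tracking_state = "character"))
  missing <- setdiff(skeleton_columns, names(df))
  if (length(missing) > 0L)
    stop("read_skeleton: ", path, ": missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop("read_skeleton: ", path, ": empty log")
  if (!all(df$sensor_id %in% c(1L, 2L)))
    stop("read_skeleton: ", path, ": sensor_id must be 1 or 2")
  bad_state <- setdiff(unique(df$tracking_state), tracking_states)
  if (length(bad_state) > 0L)
    stop("read_skeleton: ", path, ": unknown tracking_state: ",
         paste(bad_state, collapse = ", "))
  if (is.unsorted(df$timestamp)) {
    warning("read_skeleton: ", path, ": timestamps out of order; sorting")
    df <- df[order(df$timestamp, df$sensor_id, df$joint_id), ]
    rownames(df) <- NULL
  }
  meta <- read_meta_header(path)
  structure(df, subject_id = meta$subject_id, footwear = meta$footwear,
            class = c("skeleton_log", "data.frame"))
}
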