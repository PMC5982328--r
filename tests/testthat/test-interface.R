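test_that("stride records round-trip through CSV", {
  subj <- small_pop(5, 11)[[1]]
  st <- quick_stride(subj, "heels", stride_seed = 4)
  path <- tempfile(fileext = ".csv")
  write_stride(st, path)
  back <- read_strides(path)[[1]]
  expect_identical(back$subject_id, st$subject_id)
  expect_identical(back$footwear, "heels")
  expect_equal(back$body_weight_N, st$body_weight_N, tolerance = 1e-9)
  expect_equal(as.matrix(back$series), as.matrix(st$series), tolerance = 1e-9)
})

test_that("malformed stride files fail with the fault named", {
  subj <- small_pop(5, 11)[[1]]
  st <- quick_stride(subj, stride_seed = 1)
  path <- tempfile(fileext = ".csv")
  write_stride(st, path)

  lines <- readLines(path)
  no_col <- sub("fz_R", "fz_X", lines)   # drop a required column
  f1 <- tempfile(fileext = ".csv"); writeLines(no_col, f1)
  expect_error(read_strides(f1), "fz_R")

  f2 <- tempfile(fileext = ".csv")
  writeLines(lines[grepl("^#", lines)][1:4], f2)
  expect_error(read_strides(f2), ".")    # header only -> error, not empty set

  f3 <- tempfile(fileext = ".csv")
  writeLines(sub("^# body_weight_N.*", "# body_weight_N: -5", lines), f3)
  expect_error(read_strides(f3), "positive")

  # non-uniform time step
  df_lines <- lines[!grepl("^#", lines)]
  df_lines[3] <- sub("^[^,]*", "0.5", df_lines[3])
  f4 <- tempfile(fileext = ".csv")
  writeLines(c(lines[grepl("^#", lines)], df_lines), f4)
  expect_error(read_strides(f4), "non-uniform")

  expect_error(suppressWarnings(read_strides(tempfile())),
               "no CSV|cannot open")
})

test_that("skeleton logs round-trip and are validated", {
  subj <- small_pop(5, 11)[[1]]
  log <- synth_skeleton_stream(subj, "sport", n_cycles = 1, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_skeleton(log, path)
  back <- read_skeleton(path)
  expect_equal(nrow(back), nrow(log))
  expect_equal(back$y, log$y, tolerance = 1e-9)
  expect_identical(attr(back, "subject_id"), subj$subject_id)
  expect_equal(as.numeric(estimate_body_height(back)),
               as.numeric(estimate_body_height(log)), tolerance = 1e-6)

  txt <- readLines(path)
  f1 <- tempfile(fileext = ".csv")
  writeLines(sub("fully_tracked", "maybe", txt), f1)
  expect_error(read_skeleton(f1), "maybe")

  f2 <- tempfile(fileext = ".csv")
  writeLines(sub("^(0[^,]*,)1,", "\\13,", txt), f2)
  expect_error(read_skeleton(f2), "sensor_id")

  # out-of-order timestamps are sorted with a warning
  hdr <- grepl("^#|^timestamp", txt)
  f3 <- tempfile(fileext = ".csv")
  writeLines(c(txt[hdr], rev(txt[!hdr])), f3)
  expect_warning(back3 <- read_skeleton(f3), "out of order")
  expect_false(is.unsorted(back3$timestamp))
})

test_that("run configuration merges YAML over defaults and rejects unknown keys", {
  cfg <- read_config(NULL)
  expect_equal(cfg$vote$k, 5L)
  expect_equal(cfg$height$tol_cm, 2)

  f <- tempfile(fileext = ".yaml")
  writeLines("vote:\n  k: 3\nheight:\n  tol_cm: 1.5", f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$vote$k, 3)
  expect_equal(cfg2$height$tol_cm, 1.5)
  expect_equal(cfg2$vote$Th, 0)           # untouched default

  f2 <- tempfile(fileext = ".yaml")
  writeLines("vote:\n  banana: 1", f2)
  expect_error(read_config(f2), "vote.banana")
})

test_that("the CLI simulates, evaluates and reports usage errors", {
  out_dir <- file.path(tempdir(), "cli_sim")
  code <- gait_cli(c("simulate", "--subjects", "2", "--seed", "1",
                     "--out", out_dir, "--strides", "2", "--rate", "120"))
  expect_equal(code, 0L)
  stride_files <- list.files(file.path(out_dir, "strides"), pattern = "csv$")
  expect_length(stride_files, 8)          # 2 subjects x 2 footwear x 2 strides
  expect_length(list.files(file.path(out_dir, "skeletons")), 4)
  expect_true(file.exists(file.path(out_dir, "config.yaml")))
  # outputs are bit-reproducible under the same seed
  out_dir2 <- file.path(tempdir(), "cli_sim2")
  gait_cli(c("simulate", "--subjects", "2", "--seed", "1",
             "--out", out_dir2, "--strides", "2", "--rate", "120"))
  f <- file.path("strides", stride_files[1])
  expect_identical(readLines(file.path(out_dir, f)),
                   readLines(file.path(out_dir2, f)))

  expect_equal(gait_cli(c("simulate", "--bogus", "1")), 1L)
  expect_equal(gait_cli(c("frobnicate")), 2L)
  expect_equal(gait_cli(character(0)), 2L)

  eval_dir <- file.path(tempdir(), "cli_eval")
  code <- gait_cli(c("evaluate", "--scenario", "a", "--subjects", "4",
                     "--reps", "1", "--seed", "2", "--out", eval_dir,
                     "--strides-per-subject", "2", "--rate", "100"))
  expect_equal(code, 0L)
  rep <- read.csv(file.path(eval_dir, "report.csv"))
  expect_true(all(c("scenario", "CCR", "FRR", "FAR") %in% names(rep)))
  expect_true(file.exists(file.path(eval_dir, "summary.csv")))
  expect_true(file.exists(file.path(eval_dir, "metrics.json")))
})

test_that("the CLI identify pipeline runs end to end on files", {
  base <- file.path(tempdir(), "cli_e2e")
  unlink(base, recursive = TRUE)
  gait_cli(c("simulate", "--subjects", "3", "--seed", "5", "--out", base,
             "--strides", "4", "--rate", "120"))
  strides <- file.path(base, "strides")
  model <- file.path(base, "model.rds")
  gallery <- file.path(base, "gallery.rds")
  expect_equal(gait_cli(c("train-footwear", "--data", strides,
                          "--out", model)), 0L)
  # enroll on the sport strides only (copy them to a gallery dir)
  gal_dir <- file.path(base, "gal")
  dir.create(gal_dir)
  sport <- list.files(strides, pattern = "_sport_", full.names = TRUE)
  file.copy(sport, gal_dir)
  expect_equal(gait_cli(c("enroll", "--strides", gal_dir,
                          "--skeletons", file.path(base, "skeletons"),
                          "--out", gallery)), 0L)
  probe <- list.files(strides, pattern = "S001_heels_01", full.names = TRUE)
  skel <- file.path(base, "skeletons", "S001_heels.csv")
  out <- capture.output(
    code <- gait_cli(c("identify", "--gallery", gallery, "--probe", probe,
                       "--skeleton", skel, "--model", model)))
  expect_equal(code, 0L)
  dec <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_true(dec$decided %in% c("S001", "NONE", "S002", "S003"))
  expect_identical(dec$decided, "S001")
})
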