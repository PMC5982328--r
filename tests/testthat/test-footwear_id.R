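# Build a stride_record whose LR window follows a prescribed function of
# normalised time, for exact polynomial checks.
analytic_stride <- function(fun, n = 120, bw = 600) {
  tser <- (seq_len(n) - 1) / 120
  w <- gaitid:::phase_window(n, "LR")
  t01 <- (seq_len(w$end - w$start) - 1) / (w$end - w$start - 1)
  col <- numeric(n)
  col[(w$start + 1):w$end] <- fun(t01) * bw
  series <- data.frame(time_s = tser, fx_L = col, fy_L = col, fz_L = col,
                       fx_R = col, fy_R = col, fz_R = col)
  structure(list(subject_id = "T", footwear = "sport", body_weight_N = bw,
                 sampling_rate_hz = 120, stance_s = n / 120, cycle_s = 1,
                 series = series),
            class = "stride_record")
}

test_that("polynomial features recover exactly representable curves", {
  f5 <- lr_poly_features(analytic_stride(function(t) t^5))
  expect_equal(unname(f5[1:6]), c(1, 0, 0, 0, 0, 0), tolerance = 1e-8)

  fc <- lr_poly_features(analytic_stride(function(t) rep(0.5, length(t))))
  expect_equal(unname(fc[1:6]), c(0, 0, 0, 0, 0, 0.5), tolerance = 1e-8)

  expect_length(f5, 24)
  expect_identical(names(f5)[1], "a_x_L_5")
  expect_identical(names(f5)[24], "a_y_R_0")
})

test_that("least-squares fit matches an independent normal-equations solve", {
  subj <- small_pop(5, 11)[[1]]
  st <- quick_stride(subj, stride_seed = 3)
  feats <- lr_poly_features(st)
  w <- gaitid:::phase_window(nrow(st$series), "LR")
  len <- w$end - w$start
  t01 <- (seq_len(len) - 1) / (len - 1)
  X <- outer(t01, 5:0, `^`)
  yv <- st$series$fy_R[(w$start + 1):w$end] / st$body_weight_N
  beta <- solve(t(X) %*% X, t(X) %*% yv)   # normal equations, not QR
  expect_equal(unname(feats[grep("a_y_R", names(feats))]), as.numeric(beta),
               tolerance = 1e-6)
})

test_that("LR windows too short for a degree-5 fit are rejected", {
  subj <- small_pop(5, 11)[[1]]
  st <- quick_stride(subj)
  st$series <- st$series[1:24, ]   # LR window of 4 samples
  expect_error(lr_poly_features(st), "at least 6")
})

test_that("features are invariant to body-weight rescaling", {
  subj <- small_pop(5, 11)[[1]]
  st <- quick_stride(subj, stride_seed = 5)
  f1 <- lr_poly_features(st)
  st2 <- st
  force_cols <- setdiff(names(st2$series), "time_s")
  st2$series[force_cols] <- st2$series[force_cols] * 2
  st2$body_weight_N <- st2$body_weight_N * 2
  expect_equal(lr_poly_features(st2), f1, tolerance = 1e-12)
})

separable_features <- function(n_per_class = 20, seed = 1) {
  set.seed(seed)
  mk <- function(label, shift) {
    m <- matrix(rnorm(n_per_class * 24, shift, 0.1), ncol = 24)
    df <- as.data.frame(m)
    names(df) <- names(lr_poly_features(analytic_stride(function(t) t)))
    df$label <- as.integer(label)
    df$subject_id <- sprintf("%s%02d", ifelse(label == 1, "H", "S"),
                             seq_len(n_per_class))
    df
  }
  rbind(mk(0, 0), mk(1, 2))
}

test_that("classifier training is deterministic, order-invariant and separable", {
  feats <- separable_features()
  clf <- train_footwear(feats, seed = 3)
  expect_identical(predict_footwear(clf, feats), feats$label)

  clf2 <- train_footwear(feats, seed = 3)
  expect_identical(predict_footwear(clf2, feats), predict_footwear(clf, feats))

  perm <- sample(nrow(feats))
  clf3 <- train_footwear(feats[perm, ], seed = 9)
  expect_identical(predict_footwear(clf3, feats), predict_footwear(clf, feats))

  expect_error(train_footwear(feats[feats$label == 0, ]), "single class")

  clfk <- train_footwear(feats, method = "knn")
  expect_identical(predict_footwear(clfk, feats), feats$label)
})

test_that("classifier state round-trips through its file format", {
  feats <- separable_features()
  clf <- train_footwear(feats)
  path <- tempfile(fileext = ".rds")
  write_footwear_classifier(clf, path)
  clf2 <- read_footwear_classifier(path)
  expect_identical(predict_footwear(clf2, feats), predict_footwear(clf, feats))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(read_footwear_classifier(bad), "not a footwear classifier")
})

test_that("synthetic heels strides are recognised above 90 percent held-out", {
  pop <- small_pop(12, 31)
  mk <- function(subjects, seed0) {
    strides <- unlist(lapply(seq_along(subjects), function(i) {
      lapply(c("sport", "heels"), function(fw)
        lapply(1:3, function(j)
          synth_grf_stride(subjects[[i]], fw,
                           stride_seed = seed0 + 100 * i + 10 * (fw == "heels") + j,
                           sampling_rate_hz = 120)))
    }), recursive = FALSE)
    footwear_features(unlist(strides, recursive = FALSE))
  }
  train <- mk(pop[1:8], 1000)
  test <- mk(pop[9:12], 5000)     # held-out subjects
  clf <- train_footwear(train, seed = 1)
  pred <- predict_footwear(clf, test)
  expect_gt(mean(pred == test$label), 0.9)
})

test_that("grouped cross-validation keeps subjects within one fold", {
  feats <- separable_features(n_per_class = 12)
  cv <- grouped_cv(feats, n_folds = 5, seed = 2)
  expect_equal(nrow(cv$folds), 5)
  expect_true(all(cv$folds$ccr == 100))   # separable blobs
  expect_equal(cv$summary$mean[cv$summary$metric == "ccr"], 100)
  expect_error(grouped_cv(feats, n_folds = 50), "fewer")
})
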