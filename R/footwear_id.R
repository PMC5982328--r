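# Vandermonde least-squares fit of a degree-5 polynomial; coefficients
# in descending degree [a5, ..., a0].
poly5_fit <- function(t, y) {
  X <- outer(t, 5:0, `^`)
  qr.solve(X, y)
}

#' Loading-response polynomial footwear features
#'
#' Fits, for the anterior--posterior (Fx) and vertical (Fy) components
#' of both limbs, a 5th-degree polynomial in the least-squares sense to
#' the loading-response (LR) window of the stance, with time rescaled to
#' \[0, 1\] and force in fraction of body weight.  The 4 x 6
#' coefficients, each block in descending degree and blocks ordered
#' (x, L), (x, R), (y, L), (y, R), form the 24-element input vector of
#' the footwear classifier.
#'
#' @param stride A `stride_record` whose LR window holds at least 6
#'   samples per limb.
#' @return Named numeric vector of length 24
#'   (`a_x_L_5 ... a_x_L_0, a_x_R_5, ..., a_y_R_0`).
#' @export
lr_poly_features <- function(stride) {
  n <- nrow(stride$series)
  w <- phase_window(n, "LR")
  len <- w$end - w$start
  if (len < 6L)
    stop("lr_poly_features: LR window has ", len,
         " samples; at least 6 are needed for a degree-5 fit")
  idx <- (w$start + 1L):w$end
  t01 <- (seq_len(len) - 1) / (len - 1)
  out <- numeric(0)
  for (comp in c("fx", "fy")) {
    for (limb in c("L", "R")) {
      yv <- stride$series[[paste(comp, limb, sep = "_")]][idx] / stride$body_weight_N
      cf <- poly5_fit(t01, yv)
      names(cf) <- sprintf("a_%s_%s_%d", sub("f", "", comp), limb, 5:0)
      out <- c(out, cf)
    }
  }
  out
}

#' Build a labeled footwear feature table
#'
#' @param strides List of `stride_record`s.
#' @return Data frame with the 24 coefficient columns plus `label`
#'   (0 = sport, 1 = heels) and `subject_id`.
#' @export
footwear_features <- function(strides) {
  feats <- t(vapply(strides, lr_poly_features, numeric(24)))
  df <- as.data.frame(feats)
  df$label <- vapply(strides, function(s) as.integer(s$footwear == "heels"),
                     integer(1))
  df$subject_id <- vapply(strides, function(s) s$subject_id, character(1))
  df
}

#' Train the footwear classifier
#'
#' Binary classifier separating sport shoes (0) from high heels (1) on
#' the 24 loading-response polynomial coefficients.  The default model
#' is a soft-margin support vector machine with a radial kernel on
#' standardized inputs; a distance-weighted k-nearest-neighbour model is
#' available as the alternative.
#'
#' @param features Data frame from [footwear_features()] (24 coefficient
#'   columns plus `label`; extra columns are ignored).
#' @param method `"svm"` (default) or `"knn"`.
#' @param seed Integer seed (the fit itself is deterministic; the seed
#'   fixes any library-internal randomness).
#' @param kernel SVM kernel, passed to [e1071::svm()].
#' @param cost SVM cost parameter.
#' @param k Neighbour count for the kNN alternative.
#' @return A `footwear_classifier` object.
#' @export
train_footwear <- function(features, method = c("svm", "knn"), seed = 1L,
                           kernel = "radial", cost = 1, k = 3L) {
  method <- match.arg(method)
  cols <- grep("^a_", names(features), value = TRUE)
  if (length(cols) != 24L)
    stop("train_footwear: expected 24 coefficient columns, found ", length(cols))
  y <- features$label
  if (length(unique(y)) < 2L)
    stop("train_footwear: training set contains a single class")
  x <- as.matrix(features[, cols])
  model <- with_seed(mix_seed(seed, 4L), {
    if (method == "svm") {
      e1071::svm(x = x, y = factor(y, levels = c(0, 1)), kernel = kernel,
                 cost = cost, scale = TRUE, type = "C-classification")
    } else {
      df <- as.data.frame(scale(x))
      ctr <- attr(scale(x), "scaled:center"); scl <- attr(scale(x), "scaled:scale")
      list(fit = e1071::gknn(x = df, y = factor(y, levels = c(0, 1)), k = k),
           center = ctr, scale = scl)
    }
  })
  structure(list(method = method, model = model, feature_names = cols,
                 version = 1L),
            class = "footwear_classifier")
}

#' Predict footwear type
#'
#' @param classifier A `footwear_classifier`.
#' @param features A 24-element coefficient vector
#'   ([lr_poly_features()]) or a data frame / matrix of such rows.
#' @return Integer label(s): 0 = sport shoes, 1 = high heels.
#' @export
predict_footwear <- function(classifier, features) {
  stopifnot(inherits(classifier, "footwear_classifier"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1,
                                                 dimnames = list(NULL, names(features)))
  x <- as.matrix(as.data.frame(features)[, classifier$feature_names, drop = FALSE])
  pred <- if (classifier$method == "svm") {
    predict(classifier$model, x)
  } else {
    xs <- sweep(sweep(x, 2, classifier$model$center), 2, classifier$model$scale, `/`)
    predict(classifier$model$fit, as.data.frame(xs))
  }
  as.integer(as.character(pred))
}

#' Save / load a footwear classifier
#'
#' Serialises the classifier state (with a format version tag) to a
#' file, and restores it.
#'
#' @param classifier A `footwear_classifier`.
#' @param path File path.
#' @return `read_footwear_classifier` returns the restored classifier.
#' @export
write_footwear_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "footwear_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname write_footwear_classifier
#' @export
read_footwear_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "footwear_classifier") || is.null(obj$version))
    stop("read_footwear_classifier: not a footwear classifier file")
  obj
}

#' Subject-grouped k-fold cross-validation of the footwear classifier
#'
#' Folds partition *subjects*, never strides, so all strides of one
#' person fall in the same fold and no identity leaks between training
#' and test sets.  Heels is the positive class.
#'
#' @param features Data frame from [footwear_features()] including
#'   `subject_id` and `label`.
#' @param n_folds Number of folds (default 10).
#' @param seed Seed for the subject-to-fold assignment.
#' @param ... Passed to [train_footwear()].
#' @return List with `folds` (per-fold CCR, sensitivity, specificity in
#'   percent) and `summary` (mean and SD of each).
#' @export
grouped_cv <- function(features, n_folds = 10L, seed = 1L, ...) {
  subjects <- unique(features$subject_id)
  n_folds <- as.integer(n_folds)
  if (length(subjects) < n_folds)
    stop("grouped_cv: ", length(subjects), " subjects is fewer than ",
         n_folds, " folds")
  fold_of <- with_seed(mix_seed(seed, 5L), {
    f <- rep_len(seq_len(n_folds), length(subjects))
    stats::setNames(sample(f), subjects)
  })
  res <- lapply(seq_len(n_folds), function(f) {
    test_subj <- names(fold_of)[fold_of == f]
    test <- features$subject_id %in% test_subj
    clf <- train_footwear(features[!test, , drop = FALSE], seed = seed, ...)
    pred <- predict_footwear(clf, features[test, , drop = FALSE])
    truth <- features$label[test]
    counts <- confusion_counts(truth, pred)
    ss <- tryCatch(sens_spec(counts), error = function(e) c(NA_real_, NA_real_))
    data.frame(fold = f, ccr = 100 * mean(pred == truth),
               sensitivity = ss[1], specificity = ss[2])
  })
  folds <- do.call(rbind, res)
  summary <- data.frame(
    metric = c("ccr", "sensitivity", "specificity"),
    mean = c(mean(folds$ccr), mean(folds$sensitivity, na.rm = TRUE),
             mean(folds$specificity, na.rm = TRUE)),
    sd = c(sd(folds$ccr), sd(folds$sensitivity, na.rm = TRUE),
           sd(folds$specificity, na.rm = TRUE)))
  list(folds = folds, summary = summary)
}
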