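#' @title Linear-SVM stage classification with k-fold cross-validation
#' @name staging_classifier
#' @description
#' The staged dataset concatenates the per-stage texture tables (at the
#' default protocol, 6 stages x 20 ROIs = 120 rows of 9 features). A
#' one-vs-one linear-kernel support vector machine is evaluated by plain
#' (unstratified) 10-fold cross-validation: rows are randomly partitioned
#' into 10 near-equal folds, each fold serves once as the test set (12 test
#' / 108 training rows at defaults) and fold accuracies are averaged.
#' Features are standardized by training-fold statistics inside every fold
#' to avoid information leakage.
NULL

#' Assemble the labelled staging dataset
#'
#' @param tabs Named list (names = stage labels) of per-stage feature data
#'   frames or matrices with columns T1..T9 and optional provenance columns
#'   image_id, roi_row, roi_col.
#' @param n_per_stage Required rows per stage (default 20).
#' @return Object of class `staged_dataset`: data.frame with stage factor,
#'   provenance and feature columns.
#' @export
build_dataset <- function(tabs, n_per_stage = 20) {
  stopifnot(!is.null(names(tabs)))
  unknown <- setdiff(names(tabs), stage_levels())
  if (length(unknown) > 0) {
    stop(sprintf("build_dataset: unknown stage label(s): %s", paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(stage_levels(), names(tabs))
  if (length(missing) > 0) {
    stop(sprintf("build_dataset: missing stage(s): %s", paste(missing, collapse = ", ")))
  }
  rows <- lapply(names(tabs), function(g) {
    t <- tabs[[g]]
    df <- as.data.frame(t)
    if (!is.null(attr(t, "provenance"))) {
      df <- cbind(attr(t, "provenance"), df)
    }
    if (nrow(df) != n_per_stage) {
      stop(sprintf(
        "build_dataset: stage %s has %d rows; %d required", g, nrow(df), n_per_stage
      ))
    }
    if (!all(feature_names() %in% colnames(df))) {
      stop(sprintf("build_dataset: stage %s lacks feature columns T1..T9", g))
    }
    df$stage <- g
    df
  })
  out <- do.call(rbind, rows)
  if (!all(c("image_id", "roi_row", "roi_col") %in% colnames(out))) {
    out$image_id <- out$image_id %||% out$stage
  }
  if (all(c("image_id", "roi_row", "roi_col") %in% colnames(out))) {
    key <- paste(out$image_id, out$roi_row, out$roi_col)
    if (anyDuplicated(key)) {
      stop("build_dataset: duplicate (image, corner) rows")
    }
  }
  out$stage <- factor(out$stage, levels = intersect(stage_levels(), names(tabs)))
  rownames(out) <- NULL
  class(out) <- c("staged_dataset", "data.frame")
  out
}

#' Train a linear-kernel SVM
#'
#' Features are standardized by the training statistics, then a one-vs-one
#' maximum-margin linear classifier is fitted (backed by an established
#' convex solver).
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Class labels (factor or coercible).
#' @param C Regularization (cost) parameter, default 1.
#' @return Object of class `linear_svm`.
#' @export
train_linear_svm <- function(x, y, C = 1) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) {
    stop("train_linear_svm: training data contain a single class")
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  fit <- e1071::svm(xs, droplevels(y), kernel = "linear", cost = C, scale = FALSE)
  structure(list(fit = fit, center = ctr, scale = scl), class = "linear_svm")
}

#' @param object A `linear_svm`.
#' @param newdata Feature matrix to classify.
#' @param ... Unused.
#' @rdname train_linear_svm
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  stats::predict(object$fit, xs)
}

#' k-fold cross-validation of the linear SVM
#'
#' Rows are randomly partitioned into k folds whose sizes differ by at most
#' one (plain random partition, no stratification); every row is tested
#' exactly once. Standardization and fitting happen inside each training
#' fold.
#'
#' @param data A [build_dataset()] result, or a data frame with feature
#'   columns T1..T9 and a `stage` column.
#' @param seed Integer seed determining the partition.
#' @param k Number of folds (default 10).
#' @param C SVM cost parameter.
#' @return Object of class `cv_report`: list with `fold_accuracies`,
#'   `mean_accuracy`, `n_correct`, `fold_assignment`, `confusion`, `seed`,
#'   `k`, `C`.
#' @export
tenfold_cv <- function(data, seed = NULL, k = 10, C = 1) {
  x <- as.matrix(data[, feature_names()])
  y <- factor(data$stage)
  n <- nrow(x)
  if (k > n) {
    stop("tenfold_cv: more folds than rows")
  }
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  fold_of <- integer(n)
  fold_of[with_seed(seed, sample.int(n))] <- rep(seq_len(k), times = sizes)
  acc <- numeric(k)
  correct <- 0
  confusion <- table(factor(character(), levels(y)), factor(character(), levels(y)))
  for (f in seq_len(k)) {
    test <- fold_of == f
    model <- train_linear_svm(x[!test, , drop = FALSE], y[!test], C = C)
    pred <- predict(model, x[test, , drop = FALSE])
    acc[f] <- mean(pred == y[test])
    correct <- correct + sum(pred == y[test])
    confusion <- confusion + table(
      factor(y[test], levels(y)), factor(pred, levels(y))
    )
  }
  structure(
    list(
      fold_accuracies = acc,
      mean_accuracy = mean(acc),
      n_correct = as.integer(correct),
      n = n,
      fold_assignment = fold_of,
      confusion = confusion,
      seed = seed, k = k, C = C
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d-fold CV on %d rows: mean accuracy %.1f%% (%d/%d correct)\n",
    x$k, x$n, 100 * x$mean_accuracy, x$n_correct, x$n
  ))
  invisible(x)
}
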