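#' @title Correlation-matrix PCA and the (F1+F2) discriminant
#' @name pca_discriminant
#' @description
#' Principal component analysis of the per-specimen 20 x 9 texture matrix:
#' features are standardized, their 9 x 9 Pearson correlation matrix is
#' eigendecomposed, components are retained by the cumulative contribution
#' rate (CCR) rule (smallest m with CCR > 80% by default), per-ROI scores
#' F_i are the loadings applied to the feature rows, and a region is called
#' normal when the mean of (F1 + F2) exceeds a threshold (8.5 in the
#' original data's scale; tied to that scale, hence configurable).
NULL

#' Standardize a feature matrix
#'
#' Centers each column to mean 0 and scales it to unit sample standard
#' deviation (denominator n-1). Idempotent.
#'
#' @param T Numeric matrix, ROIs in rows, features in columns.
#' @return Standardized matrix of the same shape.
#' @export
standardize <- function(T) {
  stopifnot(is.matrix(T), nrow(T) >= 2)
  sds <- apply(T, 2, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad) > 0) {
    nm <- colnames(T)[bad] %||% as.character(bad)
    stop(sprintf(
      "standardize: zero-variance feature column(s): %s",
      paste(nm, collapse = ", ")
    ))
  }
  out <- scale(T)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Pearson correlation matrix of a feature matrix
#'
#' @param T Numeric matrix with >= 3 rows and no zero-variance column.
#' @return p x p correlation matrix.
#' @export
correlation_matrix <- function(T) {
  stopifnot(is.matrix(T))
  if (nrow(T) < 3) {
    stop("correlation_matrix: at least 3 rows are required")
  }
  standardize(T) # validates variance; error names the column
  stats::cor(T)
}

fix_sign <- function(v) {
  s <- sum(v)
  if (abs(s) < 1e-10) {
    if (v[which.max(abs(v))] < 0) -v else v
  } else if (s < 0) {
    -v
  } else {
    v
  }
}

#' Eigendecompose a correlation matrix
#'
#' Eigenpairs are sorted by descending eigenvalue. Each eigenvector's sign
#' is fixed so its loading sum is non-negative (tie broken by making the
#' largest-magnitude loading positive) -- the sign of an eigenvector is
#' mathematically arbitrary but changes the sign of the scores, so a fixed
#' convention is essential for a reproducible discriminant.
#'
#' @param R Symmetric correlation matrix.
#' @return List with `values` (descending) and `vectors` (columns, unit
#'   norm, sign-fixed).
#' @export
eigendecompose <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > 1e-8) {
    stop("eigendecompose: input matrix is not symmetric")
  }
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  vecs <- apply(e$vectors, 2, fix_sign)
  list(values = e$values, vectors = vecs)
}

#' Contribution rates and cumulative contribution rates
#'
#' CR_i = lambda_i / sum(lambda); CCR_i is the running sum.
#'
#' @param lambda Eigenvalues sorted in descending order, non-negative up to
#'   numerical noise.
#' @return List with `cr` and `ccr`.
#' @export
contribution_rates <- function(lambda) {
  stopifnot(is.numeric(lambda), length(lambda) >= 1)
  if (is.unsorted(rev(lambda))) {
    stop("contribution_rates: eigenvalues must be sorted in descending order")
  }
  tot <- sum(lambda)
  if (tot <= 0) {
    stop("contribution_rates: eigenvalue sum must be positive")
  }
  cr <- lambda / tot
  list(cr = cr, ccr = cumsum(cr))
}

#' Number of principal components by the CCR rule
#'
#' The smallest m whose cumulative contribution rate exceeds the threshold.
#'
#' @param ccr Non-decreasing cumulative contribution rates ending at 1.
#' @param threshold Fraction in (0, 1); default 0.80.
#' @return Integer m.
#' @export
select_components <- function(ccr, threshold = 0.80) {
  stopifnot(threshold > 0, threshold < 1)
  m <- which(ccr > threshold)[1]
  if (is.na(m)) {
    stop("select_components: no component crosses the threshold")
  }
  as.integer(m)
}

#' Per-ROI principal component scores
#'
#' F_i(row) = l_i . Z(row) for the first m components.
#'
#' @param Z Feature matrix (rows = ROIs); typically standardized.
#' @param vectors Eigenvector matrix (loadings in columns).
#' @param m Number of components (<= ncol(vectors)).
#' @return n x m score matrix with columns F1..Fm.
#' @export
principal_scores <- function(Z, vectors, m) {
  stopifnot(is.matrix(Z), is.matrix(vectors))
  if (m > ncol(vectors) || ncol(Z) != nrow(vectors)) {
    stop("principal_scores: dimension mismatch between features and loadings")
  }
  s <- Z %*% vectors[, seq_len(m), drop = FALSE]
  colnames(s) <- paste0("F", seq_len(m))
  s
}

#' Orient loadings for the regularity discriminant
#'
#' Flips the sign of each loading vector so that its weight on T1 (angular
#' second moment, the canonical textural-uniformity feature) is
#' non-negative; components then score regular texture positively, the
#' orientation under which normal mucosa scores above cancerous tissue.
#' Falls back to the non-negative loading-sum convention when the T1 loading
#' is numerically zero.
#'
#' @param vectors Eigenvector matrix (loadings in columns, features T1..T9
#'   in rows).
#' @return Re-oriented eigenvector matrix.
#' @export
orient_uniformity <- function(vectors) {
  apply(vectors, 2, function(v) {
    if (abs(v[1]) > 1e-10) {
      if (v[1] < 0) -v else v
    } else {
      fix_sign(v)
    }
  })
}

#' Threshold discriminant on the first two component scores
#'
#' Computes the mean and standard deviation over ROIs of (F1 + F2) and
#' labels the region normal when the mean strictly exceeds the threshold;
#' a boundary score equal to the threshold is assigned to the cancer class
#' (favouring sensitivity in a screening-style rule).
#'
#' @param scores Score matrix from [principal_scores()] with >= 2 columns.
#' @param threshold Decision threshold on mean(F1 + F2); default 8.5, the
#'   value reported for the original data's scale.
#' @return List with `score_mean`, `score_sd`, `label` ("normal"/"cancer"),
#'   `threshold`.
#' @export
classify_region <- function(scores, threshold = 8.5) {
  stopifnot(is.matrix(scores))
  if (ncol(scores) < 2) {
    stop("classify_region: at least 2 principal components are required")
  }
  s <- scores[, 1] + scores[, 2]
  m <- mean(s)
  list(
    score_mean = m,
    score_sd = stats::sd(s),
    label = if (m > threshold) "normal" else "cancer",
    threshold = threshold
  )
}

#' Full per-specimen PCA report
#'
#' Runs the whole chain on one specimen's feature matrix: standardize,
#' correlation matrix, eigendecomposition, CR/CCR, CCR component selection,
#' per-ROI scores and the (F1+F2) discriminant. `score_features` selects
#' whether loadings are applied to standardized features (the default;
#' per-specimen score means are then 0 by construction because rows are
#' centered) or to raw features (non-zero specimen means, the form in which
#' published per-specimen summaries are comparable).
#'
#' @param T n x 9 feature matrix of one specimen.
#' @param ccr_threshold CCR selection threshold (default 0.80).
#' @param score_threshold Discriminant threshold (default 8.5).
#' @param score_features `"standardized"` or `"raw"`.
#' @param orientation `"loading-sum"` (eigendecomposition convention) or
#'   `"uniformity"` (see [orient_uniformity()]).
#' @return List with eigenvalues, cr, ccr, n_components, score summaries and
#'   label; suitable for JSON serialization.
#' @export
pca_report <- function(T, ccr_threshold = 0.80, score_threshold = 8.5,
                       score_features = c("standardized", "raw"),
                       orientation = c("loading-sum", "uniformity")) {
  score_features <- match.arg(score_features)
  orientation <- match.arg(orientation)
  Z <- standardize(T)
  R <- correlation_matrix(T)
  eig <- eigendecompose(R)
  vecs <- if (orientation == "uniformity") orient_uniformity(eig$vectors) else eig$vectors
  rates <- contribution_rates(eig$values)
  m <- select_components(rates$ccr, ccr_threshold)
  m_use <- max(2L, m)
  X <- if (score_features == "standardized") Z else T
  scores <- principal_scores(X, vecs, m_use)
  cls <- classify_region(scores, score_threshold)
  list(
    eigenvalues = eig$values,
    cr = rates$cr,
    ccr = rates$ccr,
    n_components = m,
    ccr_selected = rates$ccr[m_use],
    F1_mean = mean(scores[, 1]), F1_sd = stats::sd(scores[, 1]),
    F2_mean = mean(scores[, 2]), F2_sd = stats::sd(scores[, 2]),
    sum_mean = cls$score_mean, sum_sd = cls$score_sd,
    label = cls$label,
    score_features = score_features,
    orientation = orientation,
    threshold = score_threshold
  )
}

#' Pooled cross-stage component scores
#'
#' Standardizes the pooled feature rows of all stages together, performs one
#' PCA in that common frame and summarizes (F1 + F2) per stage. A common
#' projection is required for cross-stage comparison: per-specimen
#' standardized scores have mean 0 for every specimen and carry no
#' between-stage information.
#'
#' @param mats Named list of per-stage feature matrices (names = stages).
#' @param orientation Loading orientation, default `"uniformity"`.
#' @return List with `table` (data.frame: stage, mean, sd of F1+F2),
#'   `eigenvalues`, `ccr`, `scores`, `stage` (per-row labels).
#' @export
pooled_stage_scores <- function(mats, orientation = c("uniformity", "loading-sum")) {
  orientation <- match.arg(orientation)
  stopifnot(length(mats) >= 2, !is.null(names(mats)))
  pooled <- do.call(rbind, mats)
  stage <- rep(names(mats), vapply(mats, nrow, 0L))
  Z <- standardize(pooled)
  eig <- eigendecompose(stats::cor(pooled))
  vecs <- if (orientation == "uniformity") orient_uniformity(eig$vectors) else eig$vectors
  scores <- principal_scores(Z, vecs, 2)
  s <- scores[, 1] + scores[, 2]
  tab <- data.frame(
    stage = names(mats),
    mean = vapply(names(mats), function(g) mean(s[stage == g]), 0),
    sd = vapply(names(mats), function(g) stats::sd(s[stage == g]), 0),
    row.names = NULL
  )
  rates <- contribution_rates(eig$values)
  list(
    table = tab, eigenvalues = eig$values, ccr = rates$ccr,
    scores = scores, stage = stage, orientation = orientation
  )
}
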