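#' @title GLCM texture features
#' @name texture_features
#' @description
#' Regions of interest (default 50 x 50 pixels, 20 per image) are sampled
#' uniformly at random among all placements fully contained in an analysis
#' mask. Each ROI's gray levels are linearly quantized from the 8-bit range
#' into K bins and tallied into a gray-level co-occurrence matrix (GLCM),
#' from which nine Haralick statistics are computed: angular second moment,
#' inertia (contrast), inverse difference moment, entropy, correlation, sum
#' average, difference average, sum entropy and difference entropy.
#' Logarithms are base 2 and 0*log(0) is taken as 0.
NULL

feature_names <- function() paste0("T", 1:9)

#' Sample regions of interest from an image
#'
#' Draws `n` ROIs of side `size` whose top-left corners are sampled
#' uniformly at random, without replacement, among all placements for which
#' the full ROI lies inside `mask` (and the image). ROI coordinates are
#' 0-based, row-major; spans are half-open.
#'
#' @param image A `projection_image` or an integer gray-level matrix.
#' @param mask Logical matrix of admissible pixels; NULL means the whole
#'   image.
#' @param n Number of ROIs (default 20).
#' @param size ROI side in pixels (default 50).
#' @param seed Integer seed for reproducible placement.
#' @param image_id Identifier stored with each ROI.
#' @return List of `roi` objects: list(pixels, row, col, image_id) with
#'   0-based top-left (row, col).
#' @export
sample_rois <- function(image, mask = NULL, n = 20, size = 50, seed = NULL,
                        image_id = "image") {
  gray <- if (inherits(image, "projection_image")) image$gray else image
  stopifnot(is.matrix(gray), n >= 1, size >= 2)
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(gray), ncol(gray))
  }
  stopifnot(identical(dim(mask), dim(gray)))
  ws <- window_sums(mask, size)
  ok <- which(ws == size * size)
  if (length(ok) < n) {
    stop(sprintf(
      "sample_rois: mask admits only %d placements of a %dx%d ROI; %d more needed",
      length(ok), size, size, n - length(ok)
    ))
  }
  picks <- with_seed(seed, sample(ok, n))
  nr <- nrow(ws)
  lapply(picks, function(p) {
    r <- as.integer((p - 1) %% nr + 1)
    c <- as.integer((p - 1) %/% nr + 1)
    structure(
      list(
        pixels = gray[r:(r + size - 1), c:(c + size - 1)],
        row = r - 1L, col = c - 1L, image_id = image_id
      ),
      class = "roi"
    )
  })
}

#' Standard co-occurrence offsets
#'
#' The four standard directions at distance `d`: 0, 45, 90 and 135 degrees,
#' as (row, col) displacements.
#'
#' @param d Offset distance in pixels.
#' @return List of four integer pairs.
#' @export
default_offsets <- function(d = 1) {
  list(c(0, d), c(-d, d), c(-d, 0), c(-d, -d))
}

#' Compute a gray-level co-occurrence matrix
#'
#' Gray levels are quantized by linear binning of the full 8-bit range into
#' K levels (level = floor(gray * K / 256)). Co-occurring quantized pairs
#' are counted at each offset, symmetrized if requested, pooled over
#' offsets, and normalized so the entries sum to 1.
#'
#' @param roi An `roi` from [sample_rois()] or a gray-level matrix (0-255).
#' @param K Number of quantized gray levels (>= 2, default 16).
#' @param offsets List of integer (row, col) displacement pairs; default the
#'   four standard directions at distance `d`.
#' @param symmetric Count each pair in both directions (default TRUE).
#' @param d Offset distance used when `offsets` is NULL.
#' @return Object of class `glcm`: list with `C` (K x K probability matrix),
#'   `K`, `offsets`, `symmetric`.
#' @export
compute_glcm <- function(roi, K = 16, offsets = NULL, symmetric = TRUE, d = 1) {
  gray <- if (inherits(roi, "roi")) roi$pixels else roi
  stopifnot(is.matrix(gray), K >= 2)
  if (is.null(offsets)) {
    offsets <- default_offsets(d)
  }
  if (length(offsets) == 0) {
    stop("compute_glcm: offset list must not be empty")
  }
  if (any(gray < 0) || any(gray > 255)) {
    stop("compute_glcm: gray levels must lie in [0, 255]")
  }
  q <- pmin(floor(gray * K / 256), K - 1)
  nr <- nrow(q)
  nc <- ncol(q)
  counts <- matrix(0, K, K)
  for (off in offsets) {
    dr <- off[1]
    dc <- off[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    if (length(r1) == 0 || length(c1) == 0) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    idx <- a * K + b + 1
    tab <- tabulate(idx, nbins = K * K)
    counts <- counts + matrix(tab, K, K, byrow = TRUE)
  }
  if (symmetric) {
    counts <- counts + t(counts)
  }
  tot <- sum(counts)
  if (tot == 0) {
    stop("compute_glcm: no co-occurring pairs for the given offsets")
  }
  structure(
    list(C = counts / tot, K = K, offsets = offsets, symmetric = symmetric),
    class = "glcm"
  )
}

log2_safe <- function(p) ifelse(p > 0, log2(p), 0)

#' Nine Haralick texture statistics of a GLCM
#'
#' Returns the feature vector (T1..T9): angular second moment, inertia,
#' inverse difference moment, entropy, correlation, sum average, difference
#' average, sum entropy and difference entropy. Entropies use base-2
#' logarithms with 0*log(0) = 0. For a degenerate (constant-ROI) GLCM whose
#' marginal variance vanishes, correlation is reported as 0 with a warning
#' rather than an error, so random ROI sampling cannot abort a pipeline run.
#'
#' @param glcm A [compute_glcm()] result.
#' @return Named numeric vector T1..T9.
#' @export
haralick_features <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  C <- glcm$C
  K <- glcm$K
  if (abs(sum(C) - 1) > 1e-8) {
    stop("haralick_features: GLCM must be normalized")
  }
  lev <- 0:(K - 1)
  i <- matrix(lev, K, K)
  j <- matrix(lev, K, K, byrow = TRUE)

  cx <- rowSums(C)
  cy <- colSums(C)
  mux <- sum(lev * cx)
  muy <- sum(lev * cy)
  sdx <- sqrt(sum((lev - mux)^2 * cx))
  sdy <- sqrt(sum((lev - muy)^2 * cy))

  # Sum and absolute-difference marginals of the co-occurrence distribution.
  csum <- as.numeric(tapply(as.numeric(C), as.numeric(i + j), sum))
  csum_k <- sort(unique(as.numeric(i + j)))
  cdiff <- as.numeric(tapply(as.numeric(C), as.numeric(abs(i - j)), sum))
  cdiff_k <- sort(unique(as.numeric(abs(i - j))))

  t1 <- sum(C^2)
  t2 <- sum((i - j)^2 * C)
  t3 <- sum(C / (1 + (i - j)^2))
  t4 <- -sum(C * log2_safe(C))
  t5 <- if (sdx * sdy > 0) {
    (sum(i * j * C) - mux * muy) / (sdx * sdy)
  } else {
    warning("haralick_features: degenerate ROI (zero marginal variance); correlation set to 0")
    0
  }
  t6 <- sum(csum_k * csum)
  t7 <- sum(cdiff_k * cdiff)
  t8 <- -sum(csum * log2_safe(csum))
  t9 <- -sum(cdiff * log2_safe(cdiff))

  stats::setNames(c(t1, t2, t3, t4, t5, t6, t7, t8, t9), feature_names())
}

#' Texture feature matrix of a set of ROIs
#'
#' Row k is `haralick_features(compute_glcm(roi_k, ...))`; columns are fixed
#' in the order T1..T9. ROI provenance (image id and 0-based corner) is
#' attached as attribute `"provenance"`.
#'
#' @param rois List of `roi` objects (default protocol: 20 of them).
#' @inheritParams compute_glcm
#' @return n x 9 numeric matrix with columns T1..T9.
#' @export
feature_matrix <- function(rois, K = 16, offsets = NULL, symmetric = TRUE, d = 1) {
  stopifnot(length(rois) >= 1)
  rows <- lapply(seq_along(rois), function(k) {
    tryCatch(
      haralick_features(compute_glcm(rois[[k]], K, offsets, symmetric, d)),
      error = function(e) stop(sprintf("feature_matrix: ROI %d: %s", k, conditionMessage(e)))
    )
  })
  fm <- do.call(rbind, rows)
  rownames(fm) <- NULL
  attr(fm, "provenance") <- data.frame(
    image_id = vapply(rois, function(r) if (inherits(r, "roi")) r$image_id else NA_character_, ""),
    roi_row = vapply(rois, function(r) if (inherits(r, "roi")) r$row else NA_integer_, 0L),
    roi_col = vapply(rois, function(r) if (inherits(r, "roi")) r$col else NA_integer_, 0L)
  )
  fm
}

#' Write a feature matrix as CSV
#'
#' Columns: image_id, roi_row, roi_col, T1..T9, stage.
#'
#' @param fm A [feature_matrix()] result.
#' @param stage Stage label recorded for every row.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_features_csv <- function(fm, stage, path) {
  prov <- attr(fm, "provenance")
  df <- cbind(prov, as.data.frame(fm), stage = stage)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
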