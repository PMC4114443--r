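# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so seeded operations compose without
# side effects. A NULL seed leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# DFT sample frequencies (cycles per unit), numpy-style ordering.
fft_freq <- function(n, d = 1) {
  c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L)) / (n * d)
}

# Rotate a matrix about its centre by `angle` degrees (counter-clockwise in
# row/col coordinates) using bilinear interpolation; out-of-frame samples
# take `fill`.
rotate_bilinear <- function(mat, angle, fill = 0) {
  if (angle %% 360 == 0) {
    return(mat)
  }
  n <- nrow(mat)
  m <- ncol(mat)
  th <- angle * pi / 180
  cy <- (n + 1) / 2
  cx <- (m + 1) / 2
  y <- rep(seq_len(n), times = m) - cy
  x <- rep(seq_len(m), each = n) - cx
  xs <- cos(th) * x + sin(th) * y + cx
  ys <- -sin(th) * x + cos(th) * y + cy
  x0 <- floor(xs)
  y0 <- floor(ys)
  fx <- xs - x0
  fy <- ys - y0
  pick <- function(r, c) {
    ok <- r >= 1 & r <= n & c >= 1 & c <= m
    v <- rep(fill, length(r))
    v[ok] <- mat[cbind(r[ok], c[ok])]
    v
  }
  v <- (1 - fx) * (1 - fy) * pick(y0, x0) +
    fx * (1 - fy) * pick(y0, x0 + 1) +
    (1 - fx) * fy * pick(y0 + 1, x0) +
    fx * fy * pick(y0 + 1, x0 + 1)
  matrix(v, n, m)
}

# Sum of mask values over every size x size window; result[r, c] is the sum
# for the window whose top-left corner is (r, c). Used for ROI placement.
window_sums <- function(mask, size) {
  n <- nrow(mask)
  m <- ncol(mask)
  if (size > n || size > m) {
    return(matrix(numeric(0), 0, 0))
  }
  cs <- matrix(0, n + 1, m + 1)
  cs[-1, -1] <- apply(apply(mask * 1, 2, cumsum), 1, cumsum) |> t()
  r <- seq_len(n - size + 1)
  c <- seq_len(m - size + 1)
  cs[r + size, c + size, drop = FALSE] - cs[r, c + size, drop = FALSE] -
    cs[r + size, c, drop = FALSE] + cs[r, c, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
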