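# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# The default study conditions: six 256 px stage phantoms imaged once each,
# 20 ROIs of 50 px per image, features per the default GLCM protocol.
stage_feature_mats <- function(seed = 1, size = 256) {
  fixture(sprintf("mats_%d_%d", seed, size), function() {
    cfg <- physics_config()
    specs <- default_stage_specs(seed)
    mats <- list()
    for (g in stage_levels()) {
      k <- match(g, stage_levels())
      map <- make_stage_phantom(g, size, specs[[g]], cfg)
      img <- acquire_projection(
        map, 0, cfg,
        seed = seed + 50 + k,
        quantize = "fixed", qrange = c(0, 2.5), invert = TRUE
      )
      rois <- sample_rois(img, map$roi_mask, 20, 50,
        seed = seed + 70 + k, image_id = g
      )
      mats[[g]] <- suppressWarnings(feature_matrix(rois))
    }
    mats
  })
}

# Analytic parallel-beam sinogram of a centred uniform disk of radius R (m)
# and attenuation mu0 (1/m): p_theta(s) = 2 * mu0 * sqrt(R^2 - s^2).
analytic_disk_sinogram <- function(nd = 256, n_angles = 180, tau = 9e-6,
                                   radius_px = 60, mu0 = 100) {
  R <- radius_px * tau
  angles <- seq(0, 180, length.out = n_angles + 1)[seq_len(n_angles)]
  s <- (seq_len(nd) - (nd + 1) / 2) * tau
  chord <- 2 * sqrt(pmax(R^2 - s^2, 0))
  p <- matrix(rep(mu0 * chord, each = n_angles), n_angles, nd)
  sinogram(p, angles, tau)
}

disk_truth <- function(nd = 256, tau = 9e-6, radius_px = 60, mu0 = 100) {
  coord <- (seq_len(nd) - (nd + 1) / 2) * tau
  rr <- sqrt(outer(coord^2, coord^2, `+`))
  list(rr = rr, truth = mu0 * (rr <= radius_px * tau), mu0 = mu0, R = radius_px * tau)
}

# Brute-force GLCM by explicit pair enumeration -- the independent oracle
# against which the vectorized implementation is checked.
brute_force_glcm <- function(img, K, offsets, symmetric) {
  q <- pmin(floor(img * K / 256), K - 1)
  counts <- matrix(0, K, K)
  for (off in offsets) {
    for (r in seq_len(nrow(q))) {
      for (c in seq_len(ncol(q))) {
        r2 <- r + off[1]
        c2 <- c + off[2]
        if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
          counts[q[r, c] + 1, q[r2, c2] + 1] <- counts[q[r, c] + 1, q[r2, c2] + 1] + 1
          if (symmetric) {
            counts[q[r2, c2] + 1, q[r, c] + 1] <- counts[q[r2, c2] + 1, q[r, c] + 1] + 1
          }
        }
      }
    }
  }
  counts / sum(counts)
}

uniform_angles <- function(n) seq(0, 180, length.out = n + 1)[seq_len(n)]
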