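#' @title Stage-labelled synthetic gastric phantoms
#' @name phantom
#' @description
#' The phantom generator produces per-pixel refractive-index maps (delta and
#' beta grids) of an air-filled stomach-like specimen cross-section: an
#' annular tissue wall around an air lumen, with a perturbed boundary, a
#' stationary Gaussian random texture inside the wall, and discrete
#' hyperplasic nodules at later stages. Wall thickness and textural
#' irregularity grow monotonically over six stage classes
#' (normal, d3, d5, d7, d9, d11), emulating progressive tumour development.
NULL

#' Ordered stage levels
#'
#' @return Character vector of the six stage labels, normal first.
#' @export
stage_levels <- function() c("normal", "d3", "d5", "d7", "d9", "d11")

#' Per-stage texture specification
#'
#' @param wall_thickness Tissue wall thickness in metres.
#' @param roughness_amplitude Relative (fractional) standard deviation of the
#'   delta texture inside the wall; also scales the boundary perturbation.
#' @param roughness_correlation_length Correlation length of the wall texture
#'   in metres.
#' @param nodule_count Number of hyperplasic nodules seeded on the inner wall.
#' @param seed Integer seed controlling all randomness of the phantom.
#' @return An object of class `stage_texture_spec`.
#' @export
stage_texture_spec <- function(wall_thickness,
                               roughness_amplitude,
                               roughness_correlation_length,
                               nodule_count = 0,
                               seed = 1) {
  stopifnot(
    wall_thickness > 0, roughness_amplitude >= 0,
    roughness_correlation_length > 0, nodule_count >= 0
  )
  structure(
    list(
      wall_thickness = wall_thickness,
      roughness_amplitude = roughness_amplitude,
      roughness_correlation_length = roughness_correlation_length,
      nodule_count = as.integer(nodule_count),
      seed = as.integer(seed)
    ),
    class = "stage_texture_spec"
  )
}

#' Default per-stage texture specifications
#'
#' The shipped stage table encodes the qualitative disease progression the
#' pipeline is designed to emulate: wall thickness and textural roughness
#' increase monotonically from the normal specimen to 11 days of tumour
#' growth, texture becomes finer grained, and discrete nodules appear from
#' day 5 on. Values are order-of-magnitude choices for a mouse-stomach-scale
#' specimen on a 9 micrometre detector, not histological measurements.
#'
#' @param seed Base seed; stage k uses `seed + k` so the six phantoms form a
#'   reproducible seed family.
#' @return Named list of [stage_texture_spec()] objects, one per stage.
#' @export
default_stage_specs <- function(seed = 1) {
  tab <- data.frame(
    stage = stage_levels(),
    wall_thickness = c(7.2e-5, 1.0e-4, 1.35e-4, 1.7e-4, 2.05e-4, 2.4e-4),
    roughness_amplitude = c(0.04, 0.055, 0.07, 0.085, 0.105, 0.125),
    roughness_correlation_length = c(2.7e-5, 2.4e-5, 2.15e-5, 1.9e-5, 1.6e-5, 1.35e-5),
    nodule_count = c(0L, 0L, 2L, 4L, 7L, 10L)
  )
  specs <- lapply(seq_len(nrow(tab)), function(k) {
    stage_texture_spec(
      wall_thickness = tab$wall_thickness[k],
      roughness_amplitude = tab$roughness_amplitude[k],
      roughness_correlation_length = tab$roughness_correlation_length[k],
      nodule_count = tab$nodule_count[k],
      seed = seed + k
    )
  })
  names(specs) <- tab$stage
  specs
}

#' Default tissue optical constants
#'
#' Water-like electron density (3.34e29 electrons/m^3) for the phase
#' decrement, and an absorption index chosen so the linear attenuation
#' coefficient is of soft-tissue order (~250 per metre) at 13 keV. These are
#' order-of-magnitude stand-ins: quantitative delta/beta for gastric wall or
#' tumour tissue are not tabulated for this geometry.
#'
#' @return Named list with `rho_e` and `beta`.
#' @export
tissue_defaults <- function() {
  list(rho_e = 3.34e29, beta = 1.9e-9)
}

# Stationary Gaussian random field with unit variance, Gaussian correlation
# kernel of standard deviation `corr_px` pixels; built by spectral filtering
# of white noise.
gaussian_random_field <- function(n, corr_px) {
  w <- matrix(stats::rnorm(n * n), n, n)
  if (corr_px <= 0.25) {
    return(w / stats::sd(w))
  }
  g <- gaussian_blur(w, corr_px)
  g / stats::sd(g)
}

# Periodic Gaussian blur via spectral filtering; adequate here because the
# blurred grids vanish near the frame border.
gaussian_blur <- function(mat, sigma_px) {
  n <- nrow(mat)
  m <- ncol(mat)
  fy <- fft_freq(n, 1)
  fx <- fft_freq(m, 1)
  h <- exp(-2 * (pi * sigma_px)^2 * outer(fy^2, fx^2, `+`))
  Re(stats::fft(stats::fft(mat) * h, inverse = TRUE)) / (n * m)
}

#' Generate a stage-labelled refractive-index phantom
#'
#' Builds an annulus-like tissue wall (air lumen inside, air outside) whose
#' geometry and texture follow the given [stage_texture_spec()]: the outer
#' boundary is perturbed by low-order angular harmonics, delta inside the
#' wall is modulated by a stationary Gaussian random field, and at later
#' stages hyperplasic nodules bulge from the inner wall. beta is a scaled
#' copy of delta so the tissue delta/beta ratio is fixed. Generation is a
#' pure function of its arguments: identical seeds give bit-identical grids.
#'
#' The map serves two imaging geometries. The `delta`/`beta` grids are the
#' tomographic cross-section (per-pixel decrements on the annulus) used for
#' sinograms. For en-face projective images the organ is treated as a
#' closed shell: the through-beam tissue chord at in-plane radius r is
#' 2*(sqrt(R_out^2 - r^2) - sqrt(R_in^2 - r^2)), nonzero over the whole
#' silhouette (front plus back wall, longest at the rim, which renders the
#' characteristic bright ring), and the stage texture modulates the tissue
#' column everywhere. The resulting path integrals are stored as
#' `path_delta`/`path_beta` (metres of delta, beta path length).
#'
#' @param stage One of [stage_levels()].
#' @param size Image side in pixels (>= 64).
#' @param spec A [stage_texture_spec()]; defaults to the shipped table entry
#'   for `stage`.
#' @param cfg A [physics_config()].
#' @param tissue Tissue constants, see [tissue_defaults()].
#' @return An object of class `refractive_map`: list with `delta`, `beta`
#'   (per-pixel decrements on the cross-section), `path_delta`, `path_beta`
#'   (en-face projected path integrals, m), `thickness` (projected tissue
#'   chord, m), `wall_mask`, `interior_mask` (specimen silhouette),
#'   `roi_mask` (silhouette eroded away from the organ border, the natural
#'   ROI sampling mask), `pixel_size`, `stage`, and `spec`.
#' @export
make_stage_phantom <- function(stage,
                               size = 256,
                               spec = NULL,
                               cfg = physics_config(),
                               tissue = tissue_defaults()) {
  stage <- match.arg(stage, stage_levels())
  stopifnot(size >= 64)
  if (is.null(spec)) {
    spec <- default_stage_specs()[[stage]]
  }
  stopifnot(inherits(spec, "stage_texture_spec"))
  px <- cfg$pixel_size
  r_out0 <- 0.40 * size
  thick_px <- spec$wall_thickness / px
  if (thick_px >= r_out0) {
    stop("make_stage_phantom: wall thicker than the specimen radius (geometry error)")
  }
  delta_tissue <- delta_from_electron_density(tissue$rho_e, cfg)
  beta_tissue <- tissue$beta

  ctr <- (size + 1) / 2
  y <- rep(seq_len(size), times = size) - ctr
  x <- rep(seq_len(size), each = size) - ctr
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)

  with_seed(spec$seed, {
    # Perturbed outer boundary: low-order angular harmonics whose total
    # standard deviation scales with the stage roughness.
    amp_px <- spec$roughness_amplitude * 40
    modes <- 2:7
    a <- stats::rnorm(length(modes), 0, amp_px / sqrt(2 * length(modes)))
    b <- stats::rnorm(length(modes), 0, amp_px / sqrt(2 * length(modes)))
    pert <- rep(0, length(th))
    for (k in seq_along(modes)) {
      pert <- pert + a[k] * cos(modes[k] * th) + b[k] * sin(modes[k] * th)
    }
    r_out <- r_out0 + pert
    r_in <- r_out - thick_px
    wall <- r <= r_out & r >= r_in
    interior <- r <= r_out
    # ROI sampling region: silhouette eroded by a safety margin so texture
    # patches sample projected tissue, not the organ border whose strong
    # edge fringes would dominate every stage alike.
    rim_margin <- max(8, round(0.05 * size))
    roi_region <- r <= r_out - rim_margin

    # Hyperplasic nodules on the inner wall, bulging into the lumen.
    nod <- rep(FALSE, length(r))
    nod_chord <- rep(0, length(r)) # projected chord through the nodules, px
    if (spec$nodule_count > 0) {
      ang <- stats::runif(spec$nodule_count, -pi, pi)
      rad_px <- stats::runif(spec$nodule_count, 0.8, 1.4) * thick_px
      for (k in seq_len(spec$nodule_count)) {
        rc <- (r_out0 + mean(pert) - thick_px) - 0.4 * rad_px[k]
        cx <- rc * cos(ang[k])
        cy <- rc * sin(ang[k])
        d2 <- (x - cx)^2 + (y - cy)^2
        nod <- nod | (d2 <= rad_px[k]^2)
        nod_chord <- nod_chord + 2 * sqrt(pmax(rad_px[k]^2 - d2, 0))
      }
      nod <- nod & interior
      nod_chord[!interior] <- 0
    }
    tissue_mask <- wall | nod

    # Cross-section decrements (tomographic slice): textured tissue on the
    # annulus and nodules.
    tex <- gaussian_random_field(size, spec$roughness_correlation_length / px)
    mod <- pmax(1 + spec$roughness_amplitude * tex, 0.05)
    delta <- rep(0, length(r))
    delta[tissue_mask] <- delta_tissue * mod[tissue_mask]
    delta[nod] <- delta[nod] * 1.3

    # En-face projected tissue chord of the closed shell (front + back
    # wall): 2*(sqrt(R_out^2 - r^2) - sqrt(R_in^2 - r^2)); equals twice the
    # wall thickness at the centre of the silhouette and peaks at the rim.
    chord_px <- 2 * (sqrt(pmax(r_out^2 - r^2, 0)) - sqrt(pmax(r_in^2 - r^2, 0))) +
      nod_chord * 1.3
    # Soften the ideal shell's tangent-ring singularity: real wall surfaces
    # are not geometrically sharp at the pixel scale.
    chord_px <- gaussian_blur(matrix(chord_px, size, size), 1.2)
    thickness <- pmax(chord_px, 0) * px
    path_delta <- delta_tissue * mod * thickness
    path_delta[!interior] <- 0
  })

  if (!any(tissue_mask)) {
    stop("make_stage_phantom: empty wall mask")
  }
  dim(delta) <- c(size, size)
  dim(thickness) <- c(size, size)
  dim(path_delta) <- c(size, size)
  beta_ratio <- beta_tissue / delta_tissue
  beta <- delta * beta_ratio

  structure(
    list(
      delta = delta,
      beta = beta,
      path_delta = path_delta,
      path_beta = path_delta * beta_ratio,
      thickness = thickness,
      wall_mask = matrix(tissue_mask, size, size),
      interior_mask = matrix(interior, size, size),
      roi_mask = matrix(roi_region, size, size),
      pixel_size = px,
      stage = stage,
      spec = spec
    ),
    class = "refractive_map"
  )
}

#' @export
print.refractive_map <- function(x, ...) {
  cat(
    sprintf(
      "<refractive_map> stage=%s  %dx%d px @ %.1f um  wall px=%d  mean delta=%.3g\n",
      x$stage, nrow(x$delta), ncol(x$delta), x$pixel_size * 1e6,
      sum(x$wall_mask), mean(x$delta[x$wall_mask])
    )
  )
  invisible(x)
}
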