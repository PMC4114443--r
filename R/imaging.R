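#' @title Forward in-line phase-contrast imaging
#' @name forward_imaging
#' @description
#' The forward model composes three steps: (i) `transmit()` applies the
#' projection approximation to a refractive map, yielding the complex exit
#' wavefield exp(-i*(2*pi/lambda)*int(delta dz)) * exp(-(2*pi/lambda)*int(beta dz));
#' (ii) `fresnel_propagate()` carries the field over the specimen-to-detector
#' distance with an exact (non-paraxial) angular-spectrum kernel, which turns
#' phase gradients into measurable intensity fringes; (iii)
#' `acquire_projection()` converts intensity to expected photon counts,
#' Poisson-samples them and quantizes to 8 bits. `acquire_sinogram()` batches
#' slice-geometry projections over a uniform angle grid.
NULL

#' Complex wavefield container
#'
#' @param field Complex-valued matrix (a 1 x n matrix represents a single
#'   detector row).
#' @param pixel_size Sample spacing in metres.
#' @param wavelength Wavelength in metres.
#' @return Object of class `complex_field`.
#' @export
complex_field <- function(field, pixel_size, wavelength) {
  stopifnot(is.matrix(field), all(is.finite(Mod(field))), pixel_size > 0, wavelength > 0)
  structure(
    list(field = field, pixel_size = pixel_size, wavelength = wavelength),
    class = "complex_field"
  )
}

#' Exit wavefield of a specimen under plane-wave illumination
#'
#' Two geometries are supported. `"screen"` uses the map's en-face projected
#' path integrals (`path_delta`/`path_beta`, the delta and beta columns
#' through the closed-shell organ; projection approximation), yielding a
#' full 2-D exit field used for projective images and texture analysis. `"slice"`
#' treats the map as a tomographic cross-section: the grids are rotated
#' in-plane by `angle` and integrated along rays (rows), yielding the 1 x n
#' exit field of a single detector row used for sinograms.
#'
#' @param map A `refractive_map`.
#' @param angle Rotation angle in degrees; for slice geometry it must lie in
#'   [0, 180).
#' @param cfg A [physics_config()].
#' @param geometry `"screen"` or `"slice"`.
#' @return A [complex_field()].
#' @export
transmit <- function(map, angle = 0, cfg = physics_config(),
                     geometry = c("screen", "slice")) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(map, "refractive_map"))
  if (length(map$delta) == 0) {
    stop("transmit: empty refractive map")
  }
  k <- 2 * pi / cfg$wavelength
  if (geometry == "screen") {
    pd <- rotate_bilinear(map$path_delta, angle)
    pb <- rotate_bilinear(map$path_beta, angle)
    field <- exp(complex(real = -k * pb, imaginary = -k * pd))
    dim(field) <- dim(map$delta)
  } else {
    if (angle < 0 || angle >= 180) {
      stop("transmit: slice-geometry angle must lie in [0, 180)")
    }
    rd <- rotate_bilinear(map$delta, angle)
    rb <- rotate_bilinear(map$beta, angle)
    pd <- colSums(rd) * map$pixel_size
    pb <- colSums(rb) * map$pixel_size
    field <- matrix(exp(complex(real = -k * pb, imaginary = -k * pd)), nrow = 1)
  }
  complex_field(field, map$pixel_size, cfg$wavelength)
}

#' Free-space propagation by the angular-spectrum method
#'
#' Multiplies the field's spectrum by the exact free-space transfer function
#' H(f) = exp(i*(2*pi/lambda)*z*sqrt(1 - (lambda*f)^2)); evanescent
#' components (lambda*|f| > 1) are suppressed. The kernel is unitary on the
#' propagating band, so total intensity is conserved for lossless fields.
#' Negative `z` applies the inverse kernel (back-propagation). `z = 0`
#' returns the input unchanged.
#'
#' @param field A [complex_field()].
#' @param z Propagation distance in metres (may be negative).
#' @return A [complex_field()].
#' @export
fresnel_propagate <- function(field, z) {
  stopifnot(inherits(field, "complex_field"), is.finite(z))
  if (z == 0) {
    return(field)
  }
  u <- field$field
  lam <- field$wavelength
  dx <- field$pixel_size
  nr <- nrow(u)
  nc <- ncol(u)
  # Sampling bound of the unpadded angular-spectrum propagator: beyond
  # z = n*dx^2/lambda the kernel phase aliases across the grid.
  n_min <- min(c(nr, nc)[c(nr, nc) > 1])
  z_max <- n_min * dx^2 / lam
  if (abs(z) > z_max) {
    stop(sprintf(
      paste0(
        "fresnel_propagate: |z| = %.3g m exceeds the aliasing bound %.3g m ",
        "for this sampling; enlarge the grid, coarsen pixels or shorten z"
      ),
      abs(z), z_max
    ))
  }
  fx <- if (nc > 1) fft_freq(nc, dx) else 0
  fy <- if (nr > 1) fft_freq(nr, dx) else 0
  f2 <- outer((lam * fy)^2, (lam * fx)^2, `+`)
  h <- matrix(0i, nr, nc)
  prop <- f2 < 1
  h[prop] <- exp(1i * (2 * pi / lam) * z * sqrt(1 - f2[prop]))
  out <- stats::fft(stats::fft(u) * h, inverse = TRUE) / length(u)
  complex_field(out, dx, lam)
}

quantize_8bit <- function(intensity, photon_count,
                          quantize = c("minmax", "fixed"),
                          qrange = c(0, 2.5), invert = FALSE) {
  quantize <- match.arg(quantize)
  if (quantize == "minmax") {
    lo <- min(intensity)
    hi <- max(intensity)
    if (hi <= lo) {
      g <- matrix(255L, nrow(intensity), ncol(intensity))
      return(g)
    }
    rel <- (intensity - lo) / (hi - lo)
  } else {
    stopifnot(length(qrange) == 2, qrange[2] > qrange[1])
    rel <- (intensity / photon_count - qrange[1]) / (qrange[2] - qrange[1])
    rel <- pmin(pmax(rel, 0), 1)
  }
  if (invert) {
    rel <- 1 - rel
  }
  g <- round(255 * rel)
  storage.mode(g) <- "integer"
  g
}

#' Acquire a noisy 8-bit projection image
#'
#' Intensity is |U_z|^2 scaled to the configured photon count, Poisson
#' sampled (unless `noise = FALSE`, the infinite-dose limit) and linearly
#' quantized to 8 bits. Quantization is per-image min-max by default;
#' `quantize = "fixed"` maps the relative-intensity window `qrange` to
#' [0, 255] for cross-image comparability, and `invert = TRUE` renders high
#' attenuation bright (radiographic display convention). The quantization
#' mode is recorded in the returned metadata because texture features depend
#' on it.
#'
#' @inheritParams transmit
#' @param seed Integer seed fixing the Poisson draw (NULL leaves the global
#'   RNG stream in charge).
#' @param noise Logical; FALSE disables photon noise.
#' @param quantize `"minmax"` or `"fixed"`.
#' @param qrange Relative-intensity window for fixed quantization (units of
#'   the empty-beam intensity).
#' @param invert Render attenuation bright.
#' @return Object of class `projection_image`: list with `gray` (integer
#'   matrix in [0, 255]), `intensity` (photon counts), `angle`, `pixel_size`
#'   and `meta`.
#' @export
acquire_projection <- function(map, angle = 0, cfg = physics_config(),
                               seed = NULL, geometry = c("screen", "slice"),
                               noise = TRUE,
                               quantize = c("minmax", "fixed"),
                               qrange = c(0, 2.5), invert = FALSE) {
  geometry <- match.arg(geometry)
  quantize <- match.arg(quantize)
  stopifnot(cfg$photon_count > 0)
  u <- transmit(map, angle, cfg, geometry)
  uz <- fresnel_propagate(u, cfg$propagation_distance)
  intensity <- Mod(uz$field)^2 * cfg$photon_count
  if (noise) {
    counts <- with_seed(seed, stats::rpois(length(intensity), intensity))
    intensity <- matrix(as.numeric(counts), nrow(intensity), ncol(intensity))
  }
  gray <- quantize_8bit(intensity, cfg$photon_count, quantize, qrange, invert)
  structure(
    list(
      gray = gray,
      intensity = intensity,
      angle = angle,
      pixel_size = map$pixel_size,
      meta = list(
        stage = map$stage, z = cfg$propagation_distance,
        wavelength = cfg$wavelength, photon_count = cfg$photon_count,
        geometry = geometry, quantize = quantize,
        qrange = if (quantize == "fixed") qrange else NULL,
        invert = invert, noise = noise, seed = seed
      )
    ),
    class = "projection_image"
  )
}

#' Acquire an intensity sinogram over a uniform angle grid
#'
#' One central detector row (slice geometry) per angle; rows keep raw photon
#' counts so that [neglog()] can form line integrals for reconstruction.
#' Angles must be uniformly spaced within [0, 180); the acquisition protocol
#' of the emulated setup is 0.1 degree steps from 0 to 180.
#'
#' @inheritParams acquire_projection
#' @param angles Strictly increasing, uniformly spaced angles in degrees.
#' @return Object of class `sinogram`: list with `data` (n_angles x n_det
#'   intensity matrix), `angles`, `pixel_size`.
#' @export
acquire_sinogram <- function(map, angles, cfg = physics_config(),
                             seed = NULL, noise = TRUE) {
  check_uniform_angles(angles)
  rows <- with_seed(seed, {
    lapply(angles, function(a) {
      u <- transmit(map, a, cfg, geometry = "slice")
      uz <- fresnel_propagate(u, cfg$propagation_distance)
      intensity <- as.numeric(Mod(uz$field)^2 * cfg$photon_count)
      if (noise) as.numeric(stats::rpois(length(intensity), intensity)) else intensity
    })
  })
  sinogram(do.call(rbind, rows), angles, map$pixel_size)
}

#' Sinogram container
#'
#' @param data Matrix, one row per angle, one column per detector bin.
#' @param angles Uniformly spaced angles in degrees, strictly increasing,
#'   within [0, 180).
#' @param pixel_size Detector bin width in metres.
#' @return Object of class `sinogram`.
#' @export
sinogram <- function(data, angles, pixel_size) {
  stopifnot(is.matrix(data), nrow(data) == length(angles), pixel_size > 0)
  check_uniform_angles(angles)
  structure(
    list(data = data, angles = angles, pixel_size = pixel_size),
    class = "sinogram"
  )
}

check_uniform_angles <- function(angles) {
  if (length(angles) < 1 || any(angles < 0) || any(angles >= 180)) {
    stop("angles must lie in [0, 180)")
  }
  if (length(angles) > 1) {
    d <- diff(angles)
    if (any(d <= 0) || max(abs(d - d[1])) > 1e-9 * max(abs(d))) {
      stop("angles must be strictly increasing and uniformly spaced")
    }
  }
  invisible(angles)
}
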