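vacuum_map <- function(size = 64) {
  map <- make_stage_phantom("normal", size)
  z <- matrix(0, size, size)
  map$delta <- z
  map$beta <- z
  map$path_delta <- z
  map$path_beta <- z
  map$thickness <- z
  map
}

test_that("transmission obeys the projection approximation limits", {
  cfg <- physics_config()
  vac <- vacuum_map()
  # vacuum: field identically 1 in both geometries
  expect_equal(unname(transmit(vac, 0, cfg, "screen")$field), matrix(1 + 0i, 64, 64))
  expect_equal(unname(transmit(vac, 30, cfg, "slice")$field), matrix(1 + 0i, 1, 64))

  # pure phase object: |field| = 1 everywhere
  pp <- vacuum_map()
  pp$path_delta <- matrix(1e-10, 64, 64)
  pp$delta <- matrix(1e-6, 64, 64)
  expect_equal(max(abs(Mod(transmit(pp, 0, cfg, "screen")$field) - 1)), 0)
  expect_equal(max(abs(Mod(transmit(pp, 0, cfg, "slice")$field) - 1)), 0)

  # single-pixel absorber: amplitude exp(-(2 pi / lambda) * beta * t)
  # along that ray, i.e. exp(-mu t / 2) in intensity terms
  ab <- vacuum_map()
  beta0 <- 1.9e-9
  ab$beta[32, 20] <- beta0
  f <- transmit(ab, 0, cfg, "slice")
  t_chord <- ab$pixel_size
  expect_equal(Mod(f$field[1, 20]), exp(-2 * pi / cfg$wavelength * beta0 * t_chord))
  expect_equal(
    Mod(f$field[1, 20])^2,
    exp(-mu_from_beta(beta0, cfg) * t_chord)
  )

  expect_error(transmit(ab, 200, cfg, "slice"), "\\[0, 180\\)")
})

test_that("angular-spectrum propagation has the free-space limits", {
  lam <- 500e-9
  dx <- 5e-6
  n <- 512
  x <- (seq_len(n) - (n + 1) / 2) * dx
  u <- matrix(complex(real = exp(-x^2 / (30e-6)^2)), nrow = 1)
  f <- complex_field(u, dx, lam)

  # z = 0 is the identity, bit for bit
  expect_identical(fresnel_propagate(f, 0), f)

  # a uniform plane wave is an eigenfunction: unchanged up to global phase
  pw <- complex_field(matrix(1 + 0i, 1, n), dx, lam)
  out <- fresnel_propagate(pw, 0.01)$field
  expect_equal(Mod(out), matrix(1, 1, n), tolerance = 1e-10)
  expect_lt(max(Mod(out / out[1, 1] - 1)), 1e-10)

  # Gaussian beam spreading matches the closed form w(z) = w0 sqrt(1+(z/zR)^2)
  w0 <- 30e-6
  z <- 0.005
  g <- fresnel_propagate(f, z)
  I <- as.numeric(Mod(g$field)^2)
  mx <- sum(x * I) / sum(I)
  w_meas <- 2 * sqrt(sum((x - mx)^2 * I) / sum(I)) # amplitude 1/e radius
  zR <- pi * w0^2 / lam
  w_true <- w0 * sqrt(1 + (z / zR)^2)
  expect_equal(w_meas, w_true, tolerance = 0.01)

  # energy conservation and reciprocity
  expect_equal(sum(Mod(g$field)^2), sum(Mod(u)^2), tolerance = 1e-6)
  back <- fresnel_propagate(g, -z)
  expect_lt(sqrt(mean(Mod(back$field - u)^2)), 1e-8)

  # aliasing bound is checked with an advisory message
  expect_error(fresnel_propagate(f, 10), "aliasing")
})

test_that("propagation creates edge fringes on a pure-phase disk", {
  cfg <- physics_config()
  size <- 256
  map <- vacuum_map(size)
  ctr <- (size + 1) / 2
  rr <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, `+`))
  disk <- rr <= 60
  map$path_delta[disk] <- 1.363e-6 * 2e-4 # water-like column
  f0 <- transmit(map, 0, cfg, "screen")
  I_contact <- Mod(f0$field)^2
  I_prop <- Mod(fresnel_propagate(f0, 0.85)$field)^2
  # contact plane: pure phase leaves no intensity signature
  expect_lt(stats::sd(I_contact), 1e-12)
  # after 0.85 m the boundary shows bright/dark fringes
  expect_gt(stats::sd(I_prop), 1e-3)
  edge_band <- abs(rr - 60) < 4
  expect_gt(max(I_prop[edge_band]), 1.05)
  expect_lt(min(I_prop[edge_band]), 0.95)
})

test_that("projection images quantize to 8 bits with the documented modes", {
  cfg <- physics_config()
  vac <- vacuum_map()
  img <- acquire_projection(vac, 0, cfg, noise = FALSE)
  # vacuum, noise-free: flat image at the top quantization level
  expect_true(all(img$gray == 255L))

  map <- make_stage_phantom("d9", 128)
  a <- acquire_projection(map, 0, cfg, seed = 5)
  b <- acquire_projection(map, 0, cfg, seed = 5)
  c <- acquire_projection(map, 0, cfg, seed = 6)
  expect_identical(a$gray, b$gray)
  expect_false(identical(a$gray, c$gray))
  expect_true(all(a$gray >= 0L & a$gray <= 255L))

  # noise-free equals the quantized noiseless intensity and is reproducible
  nf <- acquire_projection(map, 0, cfg, noise = FALSE)
  nf2 <- acquire_projection(map, 0, cfg, noise = FALSE)
  expect_identical(nf$gray, nf2$gray)

  # fixed-reference quantization maps the window ends to 0 and 255
  fx <- acquire_projection(map, 0, cfg, noise = FALSE, quantize = "fixed", qrange = c(0, 2.5))
  iv <- acquire_projection(map, 0, cfg,
    noise = FALSE, quantize = "fixed",
    qrange = c(0, 2.5), invert = TRUE
  )
  expect_identical(iv$gray, 255L - fx$gray)
  expect_identical(fx$meta$quantize, "fixed")
})

test_that("sinogram acquisition follows the rotation protocol", {
  cfg <- physics_config()
  # rotationally symmetric phantom: rows equal up to noise
  size <- 64
  map <- vacuum_map(size)
  ctr <- (size + 1) / 2
  rr <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, `+`))
  map$beta[rr <= 20] <- 1.9e-9
  sino <- acquire_sinogram(map, uniform_angles(8), cfg, noise = FALSE)
  spread <- apply(sino$data, 2, function(col) diff(range(col)))
  expect_lt(max(spread) / max(sino$data), 0.02)

  # vacuum map: constant sinogram
  vsino <- acquire_sinogram(vacuum_map(size), uniform_angles(4), cfg, noise = FALSE)
  expect_equal(max(vsino$data), min(vsino$data))

  # the acquisition protocol's angle grid: 0.1 degree steps over [0, 180)
  protocol <- seq(0, 179.9, by = 0.1)
  expect_length(protocol, 1800)
  expect_silent(sinogram(matrix(0, 1800, 4), protocol, 9e-6))

  expect_error(sinogram(matrix(0, 3, 4), c(0, 10, 15), 9e-6), "uniform")
  expect_error(sinogram(matrix(0, 2, 4), c(0, 181), 9e-6))
})
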