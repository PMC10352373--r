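test_that("gaussian source is normalised and honours both width conventions", {
  f <- gaussian_source(300, "fwhm")
  expect_equal(sum(abs(f$amplitude)^2) * f$dx, 1, tolerance = 1e-12)
  expect_equal(fwhm(profile1d(f$x, abs(f$amplitude)^2)), 300, tolerance = f$dx / 300)

  w <- gaussian_source(300, "waist")
  prof <- abs(w$amplitude)^2
  r_e2 <- approx(prof[w$x >= 0], w$x[w$x >= 0], xout = max(prof) / exp(2))$y
  expect_equal(r_e2, 300, tolerance = 1e-2)
  expect_equal(fwhm(profile1d(w$x, prof)), 300 * sqrt(2 * log(2)),
               tolerance = 1e-2)
  expect_error(gaussian_source(300, n_points = 100), "power of two")
  expect_error(gaussian_source(2000, n_points = 1024, dx = 1), "too narrow")
})

test_that("free-space diffraction matches the analytic Gaussian width", {
  w0 <- 50  # um waist -> strong diffraction over 2 cm
  src <- gaussian_source(w0, "waist", n_points = 2048, dx = 1)
  idx <- build_index_field(acoustic_cavity(nA = 0), x_extent = 2048,
                           z_extent = 20000, dx = 1, dz = 10)
  res <- bpm_propagate(src, idx, dz = 10)
  lam <- 0.66; n0 <- 1.33
  zr <- pi * w0^2 * n0 / lam
  expected <- w0 * sqrt(1 + (20000 / zr)^2) * sqrt(2 * log(2))
  expect_equal(fwhm(res$profile), expected, tolerance = 0.01)
  expect_equal(gaussian_diffraction_fwhm(w0, 20000), expected, tolerance = 1e-9)
})

test_that("a plane wave through a uniform medium is unchanged away from the boundary", {
  src <- gaussian_source(100, n_points = 1024)
  src$amplitude <- rep(complex(real = 1 / sqrt(1024)), 1024)
  idx <- build_index_field(acoustic_cavity(nA = 0), x_extent = 1024,
                           z_extent = 2000, dx = 1, dz = 10)
  res <- bpm_propagate(src, idx, dz = 10)
  core <- abs(src$x) < 250
  rel <- abs(abs(res$field$amplitude[core])^2 - 1 / 1024) * 1024
  expect_lt(max(rel), 1e-6)
})

test_that("power is conserved for a beam far from the absorbing edges", {
  src <- gaussian_source(120, "waist", n_points = 2048, dx = 1)
  idx <- build_index_field(acoustic_cavity(nA = 8e-5), x_extent = 2048,
                           z_extent = 5000, dx = 1, dz = 5)
  res <- bpm_propagate(src, idx)
  expect_equal(res$power_out / res$power_in, 1, tolerance = 1e-6)
})

test_that("the focal plane sits near the paraxial quarter pitch", {
  # holds for beams mostly inside the parabolic core of the Bessel
  # profile; wider beams focus later because the potential flattens
  cav <- acoustic_cavity(nA = 8e-5)
  qp_um <- paraxial_grin(cav)$quarter_pitch * 1e3
  src <- gaussian_source(80, n_points = 2048, dx = 1)  # paraxial beam
  idx <- build_index_field(cav, x_extent = 2048, z_extent = 22000,
                           dx = 1, dz = 5)
  res <- bpm_propagate(src, idx, record_every = 40)  # every 200 um
  widths <- apply(res$intensity_map, 2, function(I) {
    tryCatch(fwhm(profile1d(res$field$x, I)), error = function(e) NA_real_)
  })
  z_focus <- res$z[which.min(widths)]
  expect_lt(abs(z_focus - qp_um) / qp_um, 0.10)
})

test_that("halving the grid steps changes the focal width by under 2 %", {
  cav <- acoustic_cavity(nA = 8e-5)
  src1 <- gaussian_source(300, n_points = 2048, dx = 1)
  idx1 <- build_index_field(cav, x_extent = 2048, z_extent = 20000,
                            dx = 1, dz = 5)
  f1 <- fwhm(bpm_propagate(src1, idx1, dz = 5)$profile)
  src2 <- gaussian_source(300, n_points = 4096, dx = 0.5)
  idx2 <- build_index_field(cav, x_extent = 2048, z_extent = 20000,
                            dx = 0.5, dz = 2.5)
  f2 <- fwhm(bpm_propagate(src2, idx2, dz = 2.5)$profile)
  expect_lt(abs(f1 - f2) / f2, 0.02)
})

test_that("sampling mismatch and too-coarse dz are rejected", {
  src <- gaussian_source(300, n_points = 1024, dx = 2)
  idx <- build_index_field(acoustic_cavity(nA = 8e-5), x_extent = 1024,
                           z_extent = 1000, dx = 1, dz = 5)
  expect_error(bpm_propagate(src, idx), "mismatch")
  src1 <- gaussian_source(150, n_points = 1024, dx = 1)
  idx_strong <- build_index_field(
    acoustic_cavity(nA = 8e-4, k = 1.58), x_extent = 1024,
    z_extent = 1000, dx = 1, dz = 5)
  expect_error(bpm_propagate(src1, idx_strong, dz = 20), "dz")
})

test_that("the external cavity leg plus free space forms a Bessel-like beam", {
  src <- gaussian_source(300, n_points = 2048, dx = 1)
  res <- bpm_propagate_external(src, acoustic_cavity(nA = 2e-5),
                                free_distance = 20000)
  p <- res$profile
  lobe <- fwhm(p)
  expect_lt(lobe, 80)  # narrow central lobe
  # oscillating side lobes: local maxima away from the centre
  I <- p$intensity
  sm <- stats::filter(I, rep(1 / 5, 5))
  interior <- which(!is.na(sm))
  locmax <- interior[which(diff(sign(diff(sm[interior]))) == -2) + 1]
  side <- p$x[locmax][abs(p$x[locmax]) > lobe & abs(p$x[locmax]) < 300]
  expect_gte(length(side), 2)

  # zero free distance reduces to plain cavity propagation
  res0 <- bpm_propagate_external(src, acoustic_cavity(nA = 2e-5),
                                 free_distance = 0)
  idx <- build_index_field(acoustic_cavity(nA = 2e-5), x_extent = 2048,
                           z_extent = 20000, dx = 1, dz = 5)
  direct <- bpm_propagate(gaussian_source(300, n_points = 2048, dx = 1), idx)
  expect_equal(res0$profile$intensity, direct$profile$intensity,
               tolerance = 1e-10)
})

test_that("external propagation with nA = 0 matches free-space diffraction", {
  w0 <- 60
  src <- gaussian_source(w0, "waist", n_points = 2048, dx = 1)
  res <- bpm_propagate_external(src, acoustic_cavity(nA = 0),
                                free_distance = 20000)
  expect_equal(fwhm(res$profile), gaussian_diffraction_fwhm(w0, 40000),
               tolerance = 0.01)
})
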