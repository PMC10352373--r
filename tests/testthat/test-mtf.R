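# synthesize a slanted-edge scan through a Gaussian PSF without noise
edge_scan <- function(sigma = 10, step = 10, angle = 5, extent = 2000,
                      pixel = 2) {
  target <- make_knife_edge(extent = extent, pixel = pixel, angle = angle)
  psf <- psf_gaussian(fwhm = 2 * sqrt(2 * log(2)) * sigma,
                      background_fraction = 0)
  simulate_scan(target, psf, step = step,
                noise = list(photon_budget = Inf, read_sigma = 0,
                             line_bias_sigma = 0),
                seed = 1)
}

test_that("an ideal step edge yields a one-bin ESF transition", {
  target <- make_knife_edge(extent = 1000, pixel = 2, angle = 5)
  img <- new_scan <- structure(
    list(signal = target$reflectance, step = 2, meta = list()),
    class = "scan_image")
  esf <- extract_esf(img, supersample = 4)
  rise <- diff(range(esf$x[esf$intensity > 0.1 & esf$intensity < 0.9]))
  # the target edge itself is anti-aliased over one native pixel
  expect_lte(rise, 2 * attr(esf, "pitch") + 1e-9)
})

test_that("a Gaussian-blurred edge gives the Gaussian CDF as ESF", {
  sigma <- 10
  img <- edge_scan(sigma = sigma, step = 10)
  esf <- extract_esf(img, supersample = 4)
  # compare to the cumulative Gaussian; align at the 50 % point
  half <- max(esf$intensity) / 2
  j <- which(esf$intensity[-nrow(esf)] < half & esf$intensity[-1] >= half)[1]
  x50 <- esf$x[j] + (half - esf$intensity[j]) /
    (esf$intensity[j + 1] - esf$intensity[j]) * (esf$x[j + 1] - esf$x[j])
  pred <- pnorm((esf$x - x50) / sigma) * max(esf$intensity)
  core <- abs(esf$x - x50) < 4 * sigma
  expect_lt(max(abs(esf$intensity - pred)[core]), 0.01 * max(esf$intensity))
})

test_that("a vertical edge falls back to the per-line average", {
  img <- edge_scan(sigma = 8, step = 10, angle = 0)
  esf <- extract_esf(img)
  expect_equal(attr(esf, "angle"), 0)
  half <- max(esf$intensity) / 2
  j <- which(esf$intensity[-nrow(esf)] < half & esf$intensity[-1] >= half)[1]
  x50 <- esf$x[j] + (half - esf$intensity[j]) /
    (esf$intensity[j + 1] - esf$intensity[j]) * (esf$x[j + 1] - esf$x[j])
  pred <- pnorm((esf$x - x50) / 8) * max(esf$intensity)
  expect_lt(max(abs(esf$intensity - pred)), 0.03 * max(esf$intensity))
})

test_that("edge extraction guards trigger", {
  flat <- structure(list(signal = matrix(0.5, 20, 40), step = 10,
                         meta = list()), class = "scan_image")
  expect_error(extract_esf(flat), "No edge")
  steep <- make_knife_edge(extent = 1000, pixel = 2, angle = 30)
  img <- structure(list(signal = steep$reflectance, step = 2, meta = list()),
                   class = "scan_image")
  expect_error(extract_esf(img), "angle")
})

test_that("the LSF of a Gaussian-CDF ESF is the matching Gaussian", {
  sigma <- 12
  x <- seq(-80, 80, by = 1)
  esf <- profile1d(x, pnorm(x / sigma))
  attr(esf, "pitch") <- 1
  lsf <- lsf_from_esf(esf)
  # area-normalised; the taper only touches the far tails
  core <- abs(lsf$x) < 2 * sigma
  pred <- dnorm(lsf$x, 0, sigma)
  expect_lt(max(abs(lsf$intensity - pred)[core]), 0.01 * max(pred))
  expect_true(all(lsf$intensity >= 0))
  expect_error(lsf_from_esf(profile1d(1:10, c(rep(0, 5), rep(1, 5)))), "16")
})

test_that("an ideal step ESF gives an impulse-like LSF and near-flat low-frequency MTF", {
  x <- seq(-20, 20, by = 1)
  esf <- profile1d(x, as.numeric(x >= 0))
  attr(esf, "pitch") <- 1
  lsf <- lsf_from_esf(esf)
  # central differences spread the step derivative over two adjacent bins
  nz <- which(lsf$intensity > 1e-6)
  expect_lte(length(nz), 2)
  expect_lte(diff(range(lsf$x[nz])), 1 + 1e-9)
  mtf <- mtf_from_lsf(lsf)
  expect_true(all(mtf$mtf[mtf$freq <= 0.1] > 0.95))
})

test_that("MTF of a Gaussian LSF matches the analytic transform", {
  sigma <- 10
  x <- seq(-100, 100, by = 0.5)
  lsf <- profile1d(x, dnorm(x, 0, sigma))
  attr(lsf, "pitch") <- 0.5
  mtf <- mtf_from_lsf(lsf)
  keep <- mtf$mtf > 0.05
  expect_lt(max(abs(mtf$mtf - gaussian_mtf(mtf$freq, sigma))[keep]), 0.02)
  expect_equal(mtf$mtf[1], 1)
})

test_that("a two-impulse LSF gives |cos(pi f s)|", {
  x <- seq(-32, 32, by = 1)
  s <- 16
  I <- numeric(length(x)); I[x == -s / 2] <- 0.5; I[x == s / 2] <- 0.5
  lsf <- profile1d(x, I)
  attr(lsf, "pitch") <- 1
  mtf <- mtf_from_lsf(lsf)
  expect_equal(mtf$mtf, abs(cos(pi * mtf$freq * s)), tolerance = 1e-8)
})

test_that("the cutoff matches the closed-form Gaussian solution", {
  sigma <- 25 / (2 * sqrt(2 * log(2)))  # 25 um FWHM PSF
  x <- seq(-200, 200, by = 0.5)
  lsf <- profile1d(x, dnorm(x, 0, sigma))
  attr(lsf, "pitch") <- 0.5
  curve <- mtf_from_lsf(lsf)
  r <- resolution_from_mtf(curve, threshold = 0.1)
  f_expected <- sqrt(log(10)) / (pi * sigma * sqrt(2))
  expect_equal(r$cutoff, f_expected, tolerance = 0.02)
  expect_equal(r$resolution, 1 / f_expected, tolerance = 0.02)
  expect_false(r$nyquist_limited)

  r_hi <- resolution_from_mtf(curve, threshold = 0.999)
  expect_lt(r_hi$cutoff, curve$freq[5])  # degenerate: cutoff at the first bins
  expect_error(resolution_from_mtf(curve, threshold = 0), "range")
})

test_that("end-to-end slanted-edge recovery matches known Gaussian PSFs", {
  res <- numeric(0)
  for (sigma in c(5, 10, 20)) {
    curve <- mtf_slanted_edge(edge_scan(sigma = sigma), step = 10)
    keep <- curve$mtf > 0.1
    rms <- sqrt(mean((curve$mtf - gaussian_mtf(curve$freq, sigma))[keep]^2))
    expect_lt(rms, 0.05)
    res <- c(res, glance(curve)$resolution)
  }
  expect_true(all(diff(res) > 0))  # resolution degrades with blur
})

test_that("reported cutoffs never exceed the scan Nyquist limit", {
  curve <- mtf_slanted_edge(edge_scan(sigma = 2), step = 10)
  g <- glance(curve)
  expect_lte(g$cutoff, 1 / (2 * 10) + 1e-12)
  expect_true(g$nyquist_limited)
})

test_that("resolution is stable across noise realisations at moderate SNR", {
  target <- make_knife_edge(extent = 1500, pixel = 2.5, angle = 5)
  psf <- psf_gaussian(fwhm = 30)
  res <- vapply(1:12, function(s) {
    img <- simulate_scan(target, psf, step = 10,
                         noise = list(photon_budget = 2000, read_sigma = 0.005,
                                      line_bias_sigma = 0),
                         seed = s)
    glance(mtf_slanted_edge(img, step = 10))$resolution
  }, numeric(1))
  expect_lt((max(res) - min(res)) / mean(res), 0.10)
})
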