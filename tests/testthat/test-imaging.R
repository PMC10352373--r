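test_that("USAF bar widths follow the chart formula", {
  round_half_up <- function(x) floor(x * 100 + 0.5) / 100
  expect_equal(round_half_up(usaf_bar_width(4, 3)), 24.80)
  expect_equal(round_half_up(usaf_bar_width(4, 2)), 27.84)
  expect_equal(round_half_up(usaf_bar_width(5, 1)), 15.63)
  expect_equal(usaf_bar_width(5, 1), 500 / 2^5)  # 15.625 exactly
  expect_error(usaf_bar_width(4, 7), "1..6")
})

test_that("knife-edge targets are area-exact with the requested slant", {
  t0 <- make_knife_edge(extent = 600, pixel = 2, angle = 0)
  nx <- ncol(t0$reflectance)
  expect_true(all(t0$reflectance[, 1:(nx / 2 - 1)] == 0))
  expect_true(all(t0$reflectance[, (nx / 2 + 2):nx] == 1))
  expect_equal(mean(t0$reflectance), 0.5, tolerance = 1e-6)

  t5 <- make_knife_edge(extent = 600, pixel = 2, angle = 5)
  expect_equal(mean(t5$reflectance), 0.5, tolerance = 1e-6)
  # 50 % crossings per row sit exactly on the slanted line
  ys <- (seq_len(nrow(t5$reflectance)) - 0.5) * 2
  xs <- (seq_len(ncol(t5$reflectance)) - 0.5) * 2
  crossings <- apply(t5$reflectance, 1, function(row) {
    j <- which(row[-length(row)] < 0.5 & row[-1] >= 0.5)[1]
    xs[j] + (0.5 - row[j]) / (row[j + 1] - row[j]) * 2
  })
  fit <- lm(crossings ~ ys)
  expect_equal(unname(coef(fit)[2]), tan(5 * pi / 180), tolerance = 1e-3)
  # crossings collinear to a small fraction of a pixel (the two-point
  # crossing estimator carries a sub-pixel wobble of its own)
  expect_lt(summary(fit)$sigma, 0.2)
  expect_error(make_knife_edge(extent = 50, pixel = 2), "Degenerate")
})

test_that("USAF elements have three bars of the standard geometry", {
  tg <- make_usaf_element(4, 3, pixel = 2)
  w <- usaf_bar_width(4, 3)
  expect_equal(diff(tg$description$bar_centres), rep(2 * w, 2))  # pitch 49.6
  # three bars along the modulation axis
  mid <- tg$reflectance[round(nrow(tg$reflectance) / 2), ]
  runs <- rle(mid > 0.5)
  expect_equal(sum(runs$values), 3)
  # conservation: total bright area = 3 * w * 5w
  area <- sum(tg$reflectance) * tg$pixel^2
  expect_equal(area, 3 * w * 5 * w, tolerance = 1e-6)
  expect_error(make_usaf_element(4, 3, pixel = 10), "undersamples")

  th <- make_usaf_element(4, 3, pixel = 2, orientation = "horizontal")
  expect_equal(t(th$reflectance), tg$reflectance)
})

test_that("an impulse PSF and no noise reproduce the sampled target", {
  tg <- make_knife_edge(extent = 400, pixel = 2, angle = 0)
  psf <- psf_gaussian(fwhm = 0.1, background_fraction = 0)
  img <- simulate_scan(tg, psf, step = 10,
                       noise = list(photon_budget = Inf, read_sigma = 0,
                                    line_bias_sigma = 0))
  ref <- tg$reflectance[seq(1, nrow(tg$reflectance), by = 5),
                        seq(1, ncol(tg$reflectance), by = 5)]
  expect_equal(img$signal, ref, tolerance = 1e-6)
  expect_error(simulate_scan(tg, psf, step = 3), "integer multiple")
})

test_that("a uniform target maps to a flat image at the attenuation level", {
  tg <- make_knife_edge(extent = 800, pixel = 2)
  tg$reflectance[] <- 1
  psf <- psf_gaussian(fwhm = 20, background_fraction = 0.3,
                      pedestal_fwhm = 60, attenuation = 0.6)
  img <- simulate_scan(tg, psf, step = 10,
                       noise = list(photon_budget = Inf, read_sigma = 0,
                                    line_bias_sigma = 0))
  interior <- img$signal[20:60, 20:60]
  expect_equal(mean(interior), 0.6, tolerance = 1e-3)
  expect_lt(stats::sd(interior), 1e-6)
})

test_that("scan signals match a direct PSF-weighted sum (brute-force oracle)", {
  tg <- make_usaf_element(4, 3, pixel = 2)
  psf <- psf_gaussian(fwhm = 25, background_fraction = 0.3,
                      pedestal_fwhm = 60, attenuation = 0.8)
  img <- simulate_scan(tg, psf, step = 2,
                       noise = list(photon_budget = Inf, read_sigma = 0,
                                    line_bias_sigma = 0))
  # direct bucket-detector sum at a few scan positions
  max_r <- max(3 * psf$pedestal_fwhm / 2, max(psf$core_x))
  k <- usfocus:::psf_kernel(psf, 2, max_r)
  nk <- (nrow(k) - 1) / 2
  refl <- tg$reflectance
  direct <- function(i, j) {
    acc <- 0
    for (di in -nk:nk) for (dj in -nk:nk) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(refl) && jj >= 1 && jj <= ncol(refl)) {
        acc <- acc + k[di + nk + 1, dj + nk + 1] * refl[ii, jj]
      }
    }
    0.8 * acc
  }
  set.seed(1)
  for (t in 1:4) {
    i <- sample(10:(nrow(refl) - 10), 1); j <- sample(10:(ncol(refl) - 10), 1)
    expect_equal(img$signal[i, j], direct(i, j), tolerance = 1e-6)
  }
})

test_that("bar modulation distinguishes a sharp from a blurred PSF", {
  tg <- make_usaf_element(4, 3, pixel = 2)
  nz <- list(photon_budget = Inf, read_sigma = 0, line_bias_sigma = 0)
  sharp <- simulate_scan(tg, psf_gaussian(25, 0.3), step = 10, noise = nz)
  blurred <- simulate_scan(tg, psf_gaussian(170, 0.3), step = 10, noise = nz)
  expect_gt(bar_modulation(sharp, tg), 0.1)
  expect_lt(bar_modulation(blurred, tg), 0.1)
  # oracle: fine-pitch acquisition gives the same verdicts
  sharp_fine <- simulate_scan(tg, psf_gaussian(25, 0.3), step = 2, noise = nz)
  expect_equal(bar_modulation(sharp_fine, tg), bar_modulation(sharp, tg),
               tolerance = 0.05)
})

test_that("line-artifact removal restores a biased flat field", {
  set.seed(4)
  flat <- structure(list(signal = matrix(0.5, 30, 40), step = 10,
                         meta = list()), class = "scan_image")
  offs <- rnorm(30, 0, 0.05)
  biased <- flat; biased$signal <- biased$signal + offs
  fixed <- remove_line_artifacts(biased)
  resid <- apply(fixed$signal, 1, mean) - 0.5
  expect_lt(var(resid) / var(offs), 1e-6)
  expect_equal(mean(fixed$signal), mean(biased$signal), tolerance = 1e-9)
  # an offset-free image passes through unchanged (up to the preserved mean)
  same <- remove_line_artifacts(flat)
  expect_equal(same$signal, flat$signal, tolerance = 1e-9)
  expect_error(remove_line_artifacts(
    structure(list(signal = matrix(1, 2, 5), step = 1, meta = list()),
              class = "scan_image")), "3 scan lines")
})

test_that("line bias barely perturbs bar modulation after removal", {
  tg <- make_usaf_element(4, 3, pixel = 2)
  nz0 <- list(photon_budget = Inf, read_sigma = 0, line_bias_sigma = 0)
  nzb <- list(photon_budget = Inf, read_sigma = 0, line_bias_sigma = 0.03)
  clean <- simulate_scan(tg, psf_gaussian(25, 0.2), step = 10, noise = nz0)
  biased <- remove_line_artifacts(
    simulate_scan(tg, psf_gaussian(25, 0.2), step = 10, noise = nzb, seed = 3))
  m0 <- bar_modulation(clean, tg)
  m1 <- bar_modulation(biased, tg)
  expect_lt(abs(m1 - m0) / m0, 0.05)
})

test_that("PSF decomposition from profiles recovers the pedestal share", {
  pure <- gaussian_profile(sigma = 10, dx = 0.5, extent = 600)
  psf <- psf_from_profile(pure)
  expect_lt(psf$background_fraction, 0.02)

  mixed <- profile1d(pure$x, pure$intensity + 0.01)
  known_bf <- (0.01 * 600) / (0.01 * 600 + sqrt(2 * pi) * 10)
  psf2 <- psf_from_profile(mixed)
  expect_equal(psf2$background_fraction, known_bf, tolerance = 0.1 * known_bf)

  # energy split is conservative
  h <- 0.5
  total <- sum(mixed$intensity) * h
  core_e <- (1 - psf2$background_fraction) * total
  ped_e <- psf2$background_fraction * total
  expect_equal(core_e + ped_e, total, tolerance = 1e-6)
  expect_error(psf_from_profile(profile1d(1:20, rep(1, 20))), "unresolved")
})

test_that("reflection mode doubles the traversal degradation", {
  psf <- psf_gaussian(fwhm = 25, background_fraction = 0.05, loss_rate = 1)
  expect_equal(reflection_mode_psf(psf, 0), psf)
  tau <- 1.3
  refl <- reflection_mode_psf(psf_after_tau(psf, tau), tau)
  trans2 <- psf_after_tau(psf, 2 * tau)
  expect_equal(refl$attenuation, trans2$attenuation, tolerance = 1e-12)
  expect_equal(refl$background_fraction, trans2$background_fraction,
               tolerance = 1e-12)
})

test_that("image contrast falls strictly as the background fraction grows", {
  tg <- make_usaf_element(4, 3, pixel = 2)
  nz <- list(photon_budget = Inf, read_sigma = 0, line_bias_sigma = 0)
  mods <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(bf) {
    img <- simulate_scan(tg, psf_gaussian(25, bf), step = 10, noise = nz)
    bar_modulation(img, tg)
  }, numeric(1))
  expect_true(all(diff(mods) < 0))
})
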