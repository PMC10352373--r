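# independent oracles used across the suite

# power-series evaluation of J0 (independent of base besselJ)
j0_series <- function(x, terms = 40) {
  acc <- 0
  for (m in 0:(terms - 1)) {
    acc <- acc + (-1)^m * (x / 2)^(2 * m) / factorial(m)^2
  }
  acc
}

# first positive root of J0, bisection on the series
j0_first_root <- function(tol = 1e-12) {
  lo <- 2; hi <- 3
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (j0_series(lo) * j0_series(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Henyey-Greenstein density of cos(theta) (3D polar marginal)
hg_pdf <- function(ct, g) (1 - g^2) / (2 * (1 + g^2 - 2 * g * ct)^1.5)

# analytic MTF of a Gaussian PSF of standard deviation sigma (um)
gaussian_mtf <- function(f, sigma) exp(-2 * pi^2 * sigma^2 * f^2)

# a clean Gaussian profile1d
gaussian_profile <- function(sigma = 10, dx = 0.5, extent = 40 * sigma,
                             centre = 0, amplitude = 1, pedestal = 0) {
  x <- seq(-extent / 2, extent / 2, by = dx)
  profile1d(x, amplitude * exp(-(x - centre)^2 / (2 * sigma^2)) + pedestal)
}

# small embedded-modulation medium/source pair for quick MC runs
quick_grid <- function(nA = 7e-5, mus = 0, length = 20000, ...) {
  cav <- if (nA > 0) acoustic_cavity(nA = nA) else NULL
  medium_grid(length = length, mus = mus, cavity = cav, ...)
}
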