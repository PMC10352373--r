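#' Bar width of a USAF-1951 element
#'
#' The chart doubles its spatial frequency every group:
#' line pairs/mm \eqn{= 2^{g + (e - 1)/6}}, so the bar width in um is
#' \eqn{500 / 2^{g + (e - 1)/6}}.
#'
#' @param group Chart group (integer, may be negative).
#' @param element Element within the group, 1..6.
#' @return Bar width in um (exact; round only for display).
#' @examples
#' round(usaf_bar_width(4, 2:3), 2)  # 27.84, 24.80
#' @export
usaf_bar_width <- function(group, element) {
  if (any(element < 1 | element > 6 | element != round(element))) {
    abort("`element` must be an integer in 1..6.")
  }
  500 / 2^(group + (element - 1) / 6)
}

new_target_map <- function(reflectance, pixel, description) {
  stopifnot(all(reflectance >= 0 & reflectance <= 1))
  structure(list(reflectance = reflectance, pixel = pixel,
                 description = description),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("<target_map> %s: %d x %d px at %g um\n",
              x$description$kind, nrow(x$reflectance), ncol(x$reflectance),
              x$pixel))
  invisible(x)
}

#' Knife-edge reflectance target
#'
#' A binary step (dark left, bright right) with an anti-aliased,
#' optionally slanted edge: each pixel takes the area fraction of its
#' bright side, and the 50 %-crossing of row y sits exactly on
#' `x = x0 + tan(angle) (y - y0)`.
#'
#' @param extent Square extent in um (or length-2 `c(x, y)`).
#' @param pixel Pixel pitch in um.
#' @param angle Edge slant in degrees from vertical.
#' @return A `target_map`.
#' @export
make_knife_edge <- function(extent = 2000, pixel = 2, angle = 5) {
  if (length(extent) == 1) extent <- c(extent, extent)
  check_number(pixel, "pixel", lower = 0, strict_lower = TRUE)
  check_number(angle, "angle", lower = -45, upper = 45)
  nx <- round(extent[1] / pixel); ny <- round(extent[2] / pixel)
  if (nx < 100 || ny < 3) {
    abort("Degenerate extent: need >= 50 pixels on each side of the edge.")
  }
  xs <- (seq_len(nx) - 0.5) * pixel
  ys <- (seq_len(ny) - 0.5) * pixel
  x0 <- extent[1] / 2; y0 <- extent[2] / 2
  slope <- tan(angle * pi / 180)
  refl <- t(vapply(ys, function(y) {
    xe <- x0 + slope * (y - y0)
    pmin(1, pmax(0, (xs - xe) / pixel + 0.5))
  }, numeric(nx)))
  new_target_map(refl, pixel,
                 list(kind = "knife_edge", angle = angle, x0 = x0, y0 = y0))
}

#' USAF-1951 three-bar reflectance target
#'
#' One standard element: three bright bars of width `w` and length
#' `5 w` separated by gaps of width `w`, on a dark background with a
#' `w` margin, anti-aliased onto the pixel grid.
#'
#' @param group,element Chart indices (see [usaf_bar_width()]).
#' @param pixel Pixel pitch in um (must not exceed `w / 4`).
#' @param orientation `"vertical"` bars (modulation along x) or
#'   `"horizontal"`.
#' @return A `target_map`; `description` carries the bar/gap centre
#'   coordinates (um) along the modulation axis.
#' @export
make_usaf_element <- function(group, element, pixel = 2,
                              orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  w <- usaf_bar_width(group, element)
  if (pixel > w / 4) {
    abort(sprintf("`pixel` = %g um undersamples %.2f um bars (max %.2f).",
                  pixel, w, w / 4))
  }
  margin <- w
  wx <- 5 * w + 2 * margin   # 3 bars + 2 gaps across
  wy <- 5 * w + 2 * margin   # bar length 5w
  nx <- ceiling(wx / pixel); ny <- ceiling(wy / pixel)
  xs <- (seq_len(nx) - 0.5) * pixel
  ys <- (seq_len(ny) - 0.5) * pixel
  # 1D coverage of [a, b] by a pixel centred at c
  cover <- function(c, a, b) {
    pmax(0, pmin(b, c + pixel / 2) - pmax(a, c - pixel / 2)) / pixel
  }
  bar_starts <- margin + c(0, 2, 4) * w
  cov_mod <- rowSums(vapply(bar_starts, function(a) cover(xs, a, a + w),
                            numeric(nx)))
  cov_len <- cover(ys, margin, margin + 5 * w)
  refl <- outer(cov_len, cov_mod)  # rows y, cols x
  if (orientation == "horizontal") refl <- t(refl)
  bar_centres <- bar_starts + w / 2
  gap_centres <- margin + c(1.5, 3.5) * w
  new_target_map(refl, pixel,
                 list(kind = "usaf", group = group, element = element,
                      bar_width = w, orientation = orientation,
                      bar_centres = bar_centres, gap_centres = gap_centres))
}

# PSF model ----------------------------------------------------------------

new_psf_model <- function(core_x, core_I, background_fraction, pedestal_fwhm,
                          attenuation, loss_rate = 1, diffuse_fraction = 0) {
  h <- core_x[2] - core_x[1]
  # normalise the radial core to unit 1D integral over (-inf, inf)
  area <- (2 * sum(core_I) - core_I[1]) * h
  if (background_fraction + diffuse_fraction >= 1) {
    abort("Background fractions must sum to below 1.")
  }
  structure(
    list(core_x = core_x, core_I = core_I / area,
         background_fraction = background_fraction,
         diffuse_fraction = diffuse_fraction,
         pedestal_fwhm = pedestal_fwhm, attenuation = attenuation,
         loss_rate = loss_rate),
    class = "psf_model"
  )
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf(
    "<psf_model> core FWHM ~ %.1f um, background %.1f %%, pedestal %.0f um, throughput %.3g\n",
    psf_core_fwhm(x), 100 * x$background_fraction, x$pedestal_fwhm,
    x$attenuation))
  invisible(x)
}

psf_core_fwhm <- function(psf) {
  half <- max(psf$core_I) / 2
  i <- which(psf$core_I < half)[1]
  if (is.na(i) || i < 2) return(NA_real_)
  2 * approx(psf$core_I[c(i - 1, i)], psf$core_x[c(i - 1, i)], xout = half)$y
}

#' Parametric Gaussian point-spread-function model
#'
#' A focused Gaussian core of the given intensity FWHM plus a broad
#' Gaussian pedestal holding `background_fraction` of the detected
#' energy — the focused-versus-background decomposition of the beam.
#'
#' @param fwhm Core intensity FWHM, um.
#' @param background_fraction Fraction of energy in the partially
#'   scattered halo pedestal, in `[0, 1)`.
#' @param pedestal_fwhm Halo pedestal FWHM, um.
#' @param attenuation Overall multiplicative throughput in (0, 1].
#' @param loss_rate Per-unit-tau degradation rate used by
#'   [psf_after_tau()] (1 = ballistic/external focusing; guided focusing
#'   degrades about an order of magnitude slower).
#' @param diffuse_fraction Fraction of energy in the multiply scattered
#'   background, modeled as uniform over the field of view (its width,
#'   set by the transport mean free path, far exceeds the imaged
#'   region).
#' @return A `psf_model`.
#' @export
psf_gaussian <- function(fwhm = 25, background_fraction = 0,
                         pedestal_fwhm = 170, attenuation = 1,
                         loss_rate = 1, diffuse_fraction = 0) {
  check_number(fwhm, "fwhm", lower = 0, strict_lower = TRUE)
  check_number(background_fraction, "background_fraction", lower = 0, upper = 1)
  check_number(diffuse_fraction, "diffuse_fraction", lower = 0, upper = 1)
  check_number(attenuation, "attenuation", lower = 0, strict_lower = TRUE, upper = 1)
  s <- fwhm / (2 * sqrt(2 * log(2)))
  r <- seq(0, 5 * s, length.out = 201)
  new_psf_model(r, exp(-r^2 / (2 * s^2)), background_fraction, pedestal_fwhm,
                attenuation, loss_rate, diffuse_fraction)
}

#' Build a PSF model from a simulated exit profile
#'
#' Splits a beam profile into a focused core — the part within 3 FWHM of
#' the peak, above the surrounding background level — and a diffuse
#' pedestal holding the remaining energy, whose width is estimated from
#' its second moment (a broad-Gaussian fit).
#'
#' @param profile A [profile1d()] (e.g. `fluence_map$profile` or a BPM
#'   exit profile).
#' @param background_fit Estimate the pedestal width from the remainder
#'   (otherwise a default 170 um pedestal is assumed).
#' @param loss_rate Stored degradation rate (see [psf_gaussian()]).
#' @return A `psf_model` with `background_fraction` equal to the
#'   pedestal share of the total energy.
#' @export
psf_from_profile <- function(profile, background_fit = TRUE, loss_rate = 1) {
  p <- as_profile1d(profile)
  w <- fwhm(p)  # errors if there is no peak
  ip <- which.max(p$intensity)
  xp <- p$x[ip]
  h <- median(diff(p$x))
  core_reg <- abs(p$x - xp) <= 3 * w
  bg_lvl <- if (any(!core_reg)) mean(p$intensity[!core_reg]) else 0
  core_part <- pmax(0, p$intensity - bg_lvl) * core_reg
  total <- sum(p$intensity) * h
  core_e <- sum(core_part) * h
  bf <- max(0, min(1 - 1e-9, 1 - core_e / total))
  ped_fwhm <- 170
  if (background_fit && bf > 1e-6) {
    rem <- pmax(0, p$intensity - core_part)
    m2 <- sum(rem * (p$x - xp)^2) / sum(rem)
    ped_fwhm <- 2 * sqrt(2 * log(2)) * sqrt(m2)
  }
  # radialise the core about the peak
  r <- abs(p$x - xp)
  ord <- order(r)
  rx <- seq(0, 3 * w, length.out = 121)
  ry <- approx(r[ord], core_part[ord], xout = rx, rule = 2, ties = mean)$y
  new_psf_model(rx, ry, bf, ped_fwhm, 1, loss_rate)
}

#' Degrade a PSF by further optical thickness
#'
#' The focused core loses energy at the model's `loss_rate` per unit
#' optical thickness; the lost energy splits evenly between the
#' partially scattered halo pedestal and the diffuse field-wide
#' background, and the throughput of the focused channel attenuates by
#' the same factor:
#' `core -> core exp(-rate tau)`,
#' `attenuation -> attenuation exp(-rate tau)`.
#'
#' @param psf A `psf_model`.
#' @param tau Additional optical thickness (dimensionless, >= 0).
#' @return The degraded `psf_model`.
#' @export
psf_after_tau <- function(psf, tau) {
  stopifnot(inherits(psf, "psf_model"))
  check_number(tau, "tau", lower = 0)
  f <- exp(-psf$loss_rate * tau)
  core <- 1 - psf$background_fraction - psf$diffuse_fraction
  moved <- core * (1 - f)
  psf$background_fraction <- psf$background_fraction + moved / 2
  psf$diffuse_fraction <- psf$diffuse_fraction + moved / 2
  psf$attenuation <- psf$attenuation * f
  psf
}

#' Reflection-mode PSF
#'
#' In reflection both illumination and detection cross the sample, so
#' the light traverses the scattering medium twice: the effective
#' optical thickness doubles. Modeled by applying the transmission
#' degradation for a second `tau`, so that
#' `attenuation(reflection, tau) = attenuation(transmission, 2 tau)`.
#'
#' @param psf The transmission-mode `psf_model` at optical thickness
#'   `tau`.
#' @param tau The single-pass optical thickness.
#' @return The reflection-mode `psf_model`.
#' @export
reflection_mode_psf <- function(psf, tau) {
  psf_after_tau(psf, tau)
}

# sample the focused-core + halo-pedestal kernel on a pixel grid; the
# diffuse background is handled separately as a field-wide constant
psf_kernel <- function(psf, pixel, max_radius) {
  nk <- ceiling(max_radius / pixel)
  ax <- (seq(-nk, nk)) * pixel
  r <- sqrt(outer(ax^2, ax^2, "+"))
  core <- approx(psf$core_x, psf$core_I, xout = r, rule = 1)$y
  core[is.na(core)] <- 0
  dim(core) <- dim(r)
  sp <- psf$pedestal_fwhm / (2 * sqrt(2 * log(2)))
  ped <- exp(-r^2 / (2 * sp^2))
  core <- core / sum(core)
  ped <- ped / sum(ped)
  w_core <- 1 - psf$background_fraction - psf$diffuse_fraction
  w_core * core + psf$background_fraction * ped
}

# linear 2D convolution via FFT, cropped to the input size ("same")
conv2_same <- function(m, k) {
  nr <- nrow(m) + nrow(k) - 1
  nc <- ncol(m) + ncol(k) - 1
  pm <- matrix(0, nr, nc); pm[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  pk <- matrix(0, nr, nc); pk[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  full <- Re(fft(fft(pm) * fft(pk), inverse = TRUE)) / (nr * nc)
  r0 <- (nrow(k) - 1) / 2; c0 <- (ncol(k) - 1) / 2
  full[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))]
}

new_scan_image <- function(signal, step, meta = list()) {
  if (any(!is.finite(signal))) abort("Scan image must be finite.")
  structure(list(signal = signal, step = step, meta = meta),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("<scan_image> %d x %d points at %g um step\n",
              nrow(x$signal), ncol(x$signal), x$step))
  invisible(x)
}

#' Tidy a scan image
#'
#' @param x A `scan_image`.
#' @param ... Unused.
#' @return Long tibble with `x`, `y` (um) and `signal`.
#' @export
tidy.scan_image <- function(x, ...) {
  tibble(
    x = rep((seq_len(ncol(x$signal)) - 1) * x$step, each = nrow(x$signal)),
    y = rep((seq_len(nrow(x$signal)) - 1) * x$step, times = ncol(x$signal)),
    signal = as.vector(x$signal)
  )
}

#' @export
autoplot.scan_image <- function(object, ...) {
  ggplot(tidy(object), aes(.data$x, .data$y, fill = .data$signal)) +
    geom_raster() + scale_fill_viridis_c() +
    labs(x = "x (um)", y = "y (um)", fill = "signal") +
    theme_minimal()
}

#' Simulate a point-by-point scanned acquisition
#'
#' Forward imaging model of the raster-scanned microscope: at each scan
#' position the detected signal is the PSF-weighted integral of the
#' target reflectance (a bucket detector over the illuminated region),
#' `attenuation * [(1 - bf) core + bf pedestal] (*) reflectance`,
#' followed by Poisson shot noise at `photon_budget` counts per point,
#' Gaussian read noise, and a per-scan-line intensity offset emulating
#' line-to-line bias.
#'
#' @param target A `target_map`.
#' @param psf A `psf_model` (kernels are sampled at the target pixel
#'   pitch).
#' @param step Scan pitch in um; must be an integer multiple of the
#'   target pixel.
#' @param noise List with `photon_budget` (counts per point; `Inf`
#'   disables shot noise), `read_sigma` and `line_bias_sigma` (fractions
#'   of full scale; 0 disables).
#' @param seed RNG seed (fixed seed gives identical images).
#' @return A `scan_image`.
#' @export
simulate_scan <- function(target, psf, step = 10,
                          noise = list(photon_budget = 1e4,
                                       read_sigma = 0.01,
                                       line_bias_sigma = 0.02),
                          seed = 1L) {
  stopifnot(inherits(target, "target_map"), inherits(psf, "psf_model"))
  check_number(step, "step", lower = 0, strict_lower = TRUE)
  ratio <- step / target$pixel
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort("`step` must be an integer multiple of the target pixel pitch.")
  }
  ratio <- as.integer(round(ratio))
  max_r <- max(3 * psf$pedestal_fwhm / 2, max(psf$core_x))
  max_r <- min(max_r, max(dim(target$reflectance)) * target$pixel)
  k <- psf_kernel(psf, target$pixel, max_r)
  dc <- psf$diffuse_fraction * mean(target$reflectance)
  img <- psf$attenuation * (conv2_same(target$reflectance, k) + dc)
  rows <- seq(1, nrow(img), by = ratio)
  cols <- seq(1, ncol(img), by = ratio)
  sig <- img[rows, cols, drop = FALSE]
  set.seed(seed)
  if (is.finite(noise$photon_budget)) {
    sig[] <- rpois(length(sig), pmax(0, sig) * noise$photon_budget) /
      noise$photon_budget
  }
  if (noise$read_sigma > 0) {
    sig <- sig + rnorm(length(sig), 0, noise$read_sigma)
  }
  if (noise$line_bias_sigma > 0) {
    sig <- sig + rnorm(nrow(sig), 0, noise$line_bias_sigma)
  }
  new_scan_image(sig, step,
                 meta = list(noise = noise, seed = seed,
                             target = target$description,
                             pixel = target$pixel))
}

#' Remove line-to-line intensity bias
#'
#' Estimates each scan line's offset as its median minus the global
#' median and subtracts it, preserving the image mean.
#'
#' @param image A `scan_image` with at least 3 lines.
#' @return The corrected `scan_image`.
#' @export
remove_line_artifacts <- function(image) {
  stopifnot(inherits(image, "scan_image"))
  sig <- image$signal
  if (nrow(sig) < 3) abort("Need at least 3 scan lines.")
  offs <- apply(sig, 1, median) - median(sig)
  out <- sig - offs
  out <- out + (mean(sig) - mean(out))
  image$signal <- out
  image
}

#' Three-bar modulation of a scanned USAF element
#'
#' Averages the image along the bar length and applies the Michelson
#' formula to the mean signal at the bar centres versus the gap centres
#' (positions known from the generating `target_map`).
#'
#' @param image A `scan_image` of a [make_usaf_element()] target.
#' @param target The generating `target_map`.
#' @return Modulation value (can be slightly negative in pure noise).
#' @export
bar_modulation <- function(image, target) {
  stopifnot(inherits(image, "scan_image"), inherits(target, "target_map"))
  d <- target$description
  if (!identical(d$kind, "usaf")) abort("`target` must be a USAF element.")
  sig <- image$signal
  if (identical(d$orientation, "horizontal")) sig <- t(sig)
  prof <- colMeans(sig)
  pos <- (seq_along(prof) - 1) * image$step
  level_at <- function(centres) {
    mean(vapply(centres, function(cc) {
      prof[which.min(abs(pos - cc))]
    }, numeric(1)))
  }
  i_max <- level_at(d$bar_centres)
  i_min <- level_at(d$gap_centres)
  (i_max - i_min) / (i_max + i_min)
}
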