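#' Construct a 1D intensity profile
#'
#' @param x Positions in um, strictly increasing, length >= 8.
#' @param intensity Non-negative intensities (arbitrary units).
#' @return A tibble of class `profile1d` with columns `x`, `intensity`.
#' @export
profile1d <- function(x, intensity) {
  if (length(x) < 8) abort("A profile needs at least 8 samples.")
  if (length(x) != length(intensity)) abort("`x` and `intensity` lengths differ.")
  if (any(!is.finite(x)) || any(!is.finite(intensity))) {
    abort("Profile values must be finite.")
  }
  if (any(diff(x) <= 0)) abort("`x` must be strictly increasing.")
  if (any(intensity < 0)) abort("Intensities must be non-negative.")
  out <- tibble(x = as.numeric(x), intensity = as.numeric(intensity))
  class(out) <- c("profile1d", class(out))
  out
}

as_profile1d <- function(p) {
  if (inherits(p, "profile1d")) return(p)
  if (is.data.frame(p) && all(c("x", "intensity") %in% names(p))) {
    return(profile1d(p$x, p$intensity))
  }
  abort("Expected a `profile1d` or a data frame with columns x, intensity.")
}

# interpolated half-maximum crossing between samples i and i+1
interp_crossing <- function(x, y, i, level) {
  x[i] + (level - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
}

#' Full width at half maximum of a profile
#'
#' The background — the median of the outer 10 % of samples on each side —
#' is subtracted first; the width is the distance between the two
#' half-maximum crossings nearest the peak, linearly interpolated between
#' samples.
#'
#' @param profile A [profile1d()] (or data frame with `x`, `intensity`).
#' @return Width in um.
#' @examples
#' fwhm(profile1d(-10:10, exp(-(-10:10)^2 / 18)))  # ~ 2.355 * 3
#' @export
fwhm <- function(profile) {
  p <- as_profile1d(profile)
  n <- nrow(p)
  n_edge <- max(1L, floor(0.05 * n))
  bg <- median(c(p$intensity[seq_len(n_edge)],
                 p$intensity[seq(n - n_edge + 1L, n)]))
  y <- p$intensity - bg
  ip <- which.max(y)
  peak <- y[ip]
  if (peak <= 0) abort("unresolved profile: no peak above background")
  half <- peak / 2
  left <- which(y[seq_len(ip)] < half)
  right <- which(y[seq(ip, n)] < half)
  if (length(left) == 0 || length(right) == 0) {
    abort("unresolved profile: no half-maximum crossing on one side")
  }
  il <- max(left)                 # crossing between il and il + 1
  ir <- ip - 1L + min(right)      # crossing between ir - 1 and ir
  xl <- interp_crossing(p$x, y, il, half)
  xr <- interp_crossing(p$x, y, ir - 1L, half)
  xr - xl
}

#' Michelson-type intensity contrast
#'
#' \deqn{C = (I_{max} - I_{min}) / (I_{max} + I_{min})}
#'
#' @param i_max,i_min Non-negative intensities with
#'   `i_max >= i_min`, not both zero.
#' @return Contrast in `[0, 1]`.
#' @export
contrast <- function(i_max, i_min) {
  if (any(i_min < 0) || any(i_max < 0)) abort("Intensities must be non-negative.")
  if (any(i_min > i_max)) abort("`i_min` must not exceed `i_max`.")
  if (any(i_max + i_min == 0)) abort("Contrast undefined: both intensities zero.")
  (i_max - i_min) / (i_max + i_min)
}

#' Focusing contrast of a beam profile
#'
#' Applies the Michelson contrast to focused versus background photons:
#' `i_max` is the profile peak within `lobe_radius` of the maximum and
#' `i_min` the mean intensity beyond `3 * lobe_radius` from the peak
#' (outside the first side lobes for a Bessel-like channel).
#'
#' @param profile A [profile1d()].
#' @param lobe_radius Half-width of the focal lobe in um; defaults to the
#'   measured [fwhm()] of the profile.
#' @return Contrast in `[0, 1]`.
#' @export
focusing_contrast <- function(profile, lobe_radius = NULL) {
  p <- as_profile1d(profile)
  if (is.null(lobe_radius)) lobe_radius <- fwhm(p)
  ip <- which.max(p$intensity)
  xp <- p$x[ip]
  in_lobe <- abs(p$x - xp) <= lobe_radius
  in_bg <- abs(p$x - xp) > 3 * lobe_radius
  if (!any(in_bg)) {
    abort("Profile too narrow to contain a background region beyond 3 lobe radii.")
  }
  contrast(max(p$intensity[in_lobe]), mean(p$intensity[in_bg]))
}

#' Relative focusing-contrast loss
#'
#' `100 * (1 - c_scattering / c_reference)`, in percent. Values above the
#' reference give a negative loss.
#'
#' @param c_scattering Contrast measured in the scattering medium.
#' @param c_reference Contrast of the non-scattering reference, `> 0`.
#' @return Loss in percent.
#' @export
contrast_loss <- function(c_scattering, c_reference) {
  if (any(c_reference <= 0)) abort("`c_reference` must be positive.")
  100 * (1 - c_scattering / c_reference)
}

#' Optical thickness of a slab
#'
#' \eqn{\tau = \mu_s d}: the expected number of scattering events across
#' a medium of thickness `d`.
#'
#' @param mus Scattering coefficient, cm^-1.
#' @param d Thickness, cm.
#' @return Dimensionless optical thickness.
#' @export
optical_thickness <- function(mus, d) {
  if (any(mus < 0) || any(d < 0)) abort("`mus` and `d` must be non-negative.")
  mus * d
}

#' Fit a scattering coefficient from collimated attenuation
#'
#' Ordinary least squares on `log(intensity)` versus thickness
#' (Beer-Lambert); the slope estimates `-mus`.
#'
#' @param thicknesses Slab thicknesses in cm (>= 2 distinct values).
#' @param intensities Positive transmitted intensities (>= 3 points).
#' @return An object of class `attenuation_fit`; see [tidy.attenuation_fit()].
#' @examples
#' d <- c(0, 0.5, 1, 2)
#' fit <- fit_scattering_coefficient(d, 10 * exp(-1.5 * d))
#' glance(fit)$mus  # 1.5
#' @export
fit_scattering_coefficient <- function(thicknesses, intensities) {
  if (length(intensities) < 3) abort("Need at least 3 intensity points.")
  if (length(unique(thicknesses)) < 2) abort("Need >= 2 distinct thicknesses.")
  if (any(intensities <= 0)) abort("Intensities must be positive to take logs.")
  fit <- lm(log(intensities) ~ thicknesses)
  mus <- -unname(coef(fit)[2])
  if (mus < 0) warn("Negative attenuation slope: reporting `mus` < 0 as-is.")
  y <- log(intensities)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 1
  structure(
    list(mus = mus, intercept = unname(coef(fit)[1]),
         r_squared = r2, fit = fit,
         data = tibble(thickness = thicknesses, intensity = intensities)),
    class = "attenuation_fit"
  )
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf("<attenuation_fit> mus = %.4g cm^-1, I0 = %.4g, r^2 = %.4f\n",
              x$mus, exp(x$intercept), x$r_squared))
  invisible(x)
}

#' Tidy an attenuation fit
#'
#' @param x An `attenuation_fit`.
#' @param ... Unused.
#' @return Per-observation tibble (`thickness`, `intensity`, `fitted`,
#'   `residual_log`) for `tidy()`; a one-row model summary (`mus`,
#'   `intercept`, `r_squared`, `n`) for `glance()`.
#' @export
tidy.attenuation_fit <- function(x, ...) {
  mutate(x$data,
         fitted = exp(x$intercept - x$mus * .data$thickness),
         residual_log = log(.data$intensity) - log(.data$fitted))
}

#' @rdname tidy.attenuation_fit
#' @export
glance.attenuation_fit <- function(x, ...) {
  tibble(mus = x$mus, intercept = x$intercept,
         r_squared = x$r_squared, n = nrow(x$data))
}

#' @export
autoplot.attenuation_fit <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$thickness)) +
    geom_point(aes(y = .data$intensity)) +
    geom_line(aes(y = .data$fitted)) +
    labs(x = "thickness (cm)", y = "intensity") +
    theme_minimal()
}
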