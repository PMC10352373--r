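#' Gaussian optical source field
#'
#' Builds the transverse complex amplitude of a collimated Gaussian beam
#' on a power-of-two grid, normalised to unit power. Two width
#' conventions are supported: `"fwhm"` (the intensity full width at half
#' maximum equals `width`) and `"waist"` (the 1/e^2 intensity radius
#' equals `width`); they are related by
#' \eqn{\mathrm{FWHM} = w_0 \sqrt{2 \ln 2}}.
#'
#' @param width Beam width in um.
#' @param width_convention `"fwhm"` or `"waist"`.
#' @param n_points Number of grid points (power of two).
#' @param dx Transverse sampling in um.
#' @param wavelength Vacuum wavelength in um (660 nm: 0.66).
#' @param n0 Background refractive index.
#' @return An object of class `optical_field` with complex `amplitude`,
#'   `x`, `dx`, `wavelength`, `n0` and current axial position `z`.
#' @export
gaussian_source <- function(width = 300, width_convention = c("fwhm", "waist"),
                            n_points = 2048, dx = 1,
                            wavelength = 0.66, n0 = 1.33) {
  width_convention <- match.arg(width_convention)
  check_number(width, "width", lower = 0, strict_lower = TRUE)
  check_number(dx, "dx", lower = 0, strict_lower = TRUE)
  check_number(wavelength, "wavelength", lower = 0, strict_lower = TRUE)
  if (bitwAnd(n_points, n_points - 1L) != 0L || n_points < 16L) {
    abort("`n_points` must be a power of two (>= 16).")
  }
  w0 <- if (width_convention == "fwhm") width / sqrt(2 * log(2)) else width
  x <- (seq_len(n_points) - n_points / 2 - 0.5) * dx
  amp <- exp(-x^2 / w0^2)
  edge <- max(amp[1], amp[n_points])^2
  if (edge > 1e-6) {
    abort(sprintf(
      "Grid too narrow: boundary intensity is %.2g of peak; extend to >= %g um.",
      edge, 2 * w0 * sqrt(log(1e6) / 2) / 0.9))
  }
  amp <- amp / sqrt(sum(abs(amp)^2) * dx)  # unit power
  structure(
    list(amplitude = as.complex(amp), x = x, dx = dx,
         wavelength = wavelength, n0 = n0, z = 0),
    class = "optical_field"
  )
}

#' @export
print.optical_field <- function(x, ...) {
  cat(sprintf("<optical_field> %d points, dx = %g um, lambda = %g um, z = %g um\n",
              length(x$amplitude), x$dx, x$wavelength, x$z))
  invisible(x)
}

field_power <- function(field) sum(abs(field$amplitude)^2) * field$dx

field_profile <- function(field) profile1d(field$x, abs(field$amplitude)^2)

# supergaussian absorber over the outer `frac` of the window
absorber_mask <- function(x, frac = 0.1, order = 4, strength = 0.5) {
  wabs <- frac * (max(x) - min(x) + (x[2] - x[1]))
  edge <- pmin(x - min(x), max(x) - x)
  exp(-strength * pmax(0, 1 - edge / wabs)^order)
}

# split-step kernel: nsteps through transverse index profile `nprof`
# (length matching field), step dz; absorber applied with the phase screen
split_step <- function(field, nprof, dz, nsteps, absorb = TRUE,
                       boundary_frac = 0.1, record_every = 0L) {
  n <- length(field$amplitude)
  k0 <- 2 * pi / field$wavelength
  kx <- 2 * pi * c(0:(n / 2 - 1), -(n / 2):-1) / (n * field$dx)
  h_full <- exp(-1i * kx^2 * dz / (2 * k0 * field$n0))
  h_half <- exp(-1i * kx^2 * (dz / 2) / (2 * k0 * field$n0))
  phase <- exp(1i * k0 * (nprof - field$n0) * dz)
  mask <- if (absorb) absorber_mask(field$x, boundary_frac) else rep(1, n)
  a <- field$amplitude
  rec <- if (record_every > 0) {
    matrix(NA_real_, n, floor(nsteps / record_every))
  }
  irec <- 0L
  a <- fft(h_half * fft(a), inverse = TRUE) / n
  for (s in seq_len(nsteps)) {
    a <- a * phase * mask
    if (s < nsteps) {
      a <- fft(h_full * fft(a), inverse = TRUE) / n
    } else {
      a <- fft(h_half * fft(a), inverse = TRUE) / n
    }
    if (record_every > 0 && s %% record_every == 0) {
      irec <- irec + 1L
      rec[, irec] <- abs(a)^2
    }
  }
  field$amplitude <- a
  field$z <- field$z + nsteps * dz
  list(field = field, record = if (record_every > 0) rec[, seq_len(irec), drop = FALSE])
}

#' Split-step beam propagation through an index field
#'
#' Paraxial split-step Fourier propagation: half a diffraction step in
#' the spatial-frequency domain, a thin phase screen
#' \eqn{\exp(i k_0 (n - n_0) \Delta z)}, half a diffraction step, with a
#' supergaussian absorbing boundary applied together with each screen.
#' The phase increment per step must satisfy
#' \eqn{k_0 \max|n - n_0| \Delta z < 0.1} rad.
#'
#' @param field An [gaussian_source()] `optical_field`.
#' @param index An `ri_field` from [build_index_field()] whose `dx`
#'   matches the field sampling.
#' @param dz Axial step in um (defaults to the index field `dz`, capped
#'   at 5 um).
#' @param record_every Record the transverse intensity every this many
#'   steps into the returned intensity map (0 = none).
#' @param boundary_frac Fraction of the window occupied by the absorbing
#'   boundary on each side.
#' @return A `bpm_result`: final `field`, exit-intensity `profile`
#'   ([profile1d()]), optional `intensity_map` (x by z), `z` axis of the
#'   map, and the launch/exit power bookkeeping.
#' @examples
#' \donttest{
#' cav <- acoustic_cavity(nA = 8e-5)
#' idx <- build_index_field(cav, x_extent = 2048, z_extent = 20000, dx = 1, dz = 5)
#' res <- bpm_propagate(gaussian_source(300), idx)
#' fwhm(res$profile)  # ~ 21 um focal spot
#' }
#' @export
bpm_propagate <- function(field, index, dz = NULL, record_every = 0L,
                          boundary_frac = 0.1) {
  stopifnot(inherits(field, "optical_field"), inherits(index, "ri_field"))
  if (abs(field$dx - index$dx) > 1e-9) {
    abort("Sampling mismatch: field `dx` must equal index-field `dx`.")
  }
  if (is.null(dz)) dz <- min(index$dz, 5)
  k0 <- 2 * pi / field$wavelength
  dev <- max(abs(range(index$values) - field$n0))
  if (k0 * dev * dz >= 0.1) {
    abort(sprintf("Phase-step criterion violated: need dz < %.3g um.",
                  0.1 / (k0 * dev)))
  }
  z_extent <- length(index$z) * index$dz
  nsteps <- round(z_extent / dz)
  # the index profile is z-invariant within the modulated range; propagate
  # each maximal z-block with its own transverse profile
  zb <- unique(c(0, index$modulated_z[index$modulated_z > 0 &
                                      index$modulated_z < z_extent], z_extent))
  zb <- sort(zb)
  p_in <- field_power(field)
  recs <- list()
  for (b in seq_len(length(zb) - 1)) {
    jz <- min(length(index$z), max(1L, ceiling((zb[b] + dz / 2) / index$dz)))
    nprof_full <- index$values[, jz]
    nprof <- resample_profile(index$x, nprof_full, field$x, field$n0)
    ns <- round((zb[b + 1] - zb[b]) / dz)
    if (ns == 0) next
    step <- split_step(field, nprof, dz, ns,
                       boundary_frac = boundary_frac,
                       record_every = record_every)
    field <- step$field
    if (!is.null(step$record)) recs[[length(recs) + 1]] <- step$record
  }
  imap <- if (length(recs)) do.call(cbind, recs)
  structure(
    list(field = field, profile = field_profile(field),
         intensity_map = imap,
         z = if (!is.null(imap)) seq_len(ncol(imap)) * dz * record_every,
         power_in = p_in, power_out = field_power(field)),
    class = "bpm_result"
  )
}

# nearest/linear resample of the index profile onto the optical grid,
# padding with n0 outside the modulated region
resample_profile <- function(x_idx, n_idx, x_field, n0) {
  out <- approx(x_idx, n_idx, xout = x_field, rule = 1)$y
  out[is.na(out)] <- n0
  out
}

#' Propagate through an external modulated cavity then free space
#'
#' The classical external-lens scenario: the beam crosses the
#' ultrasound-modulated water-filled cavity (length
#' `cavity$cavity_length`), then continues `free_distance` through the
#' uniform background medium. With a weak modulation the cavity acts as
#' an aberrated GRIN lens and a Bessel-like transverse profile develops
#' beyond it.
#'
#' @inheritParams bpm_propagate
#' @param cavity An [acoustic_cavity()] describing the external lens
#'   (external-lens default `nA = 2e-5`).
#' @param free_distance Propagation distance beyond the cavity, um.
#' @return A `bpm_result` (see [bpm_propagate()]).
#' @export
bpm_propagate_external <- function(field, cavity = acoustic_cavity(nA = 2e-5),
                                   free_distance = 20000, dz = 5,
                                   record_every = 0L, boundary_frac = 0.1) {
  stopifnot(inherits(field, "optical_field"))
  check_number(free_distance, "free_distance", lower = 0)
  l_cav <- cavity$cavity_length * 1e3
  idx <- build_index_field(cavity,
                           x_extent = length(field$amplitude) * field$dx,
                           z_extent = l_cav + free_distance,
                           dx = field$dx, dz = dz,
                           modulated_z = c(0, l_cav))
  bpm_propagate(field, idx, dz = dz, record_every = record_every,
                boundary_frac = boundary_frac)
}

#' @export
print.bpm_result <- function(x, ...) {
  cat(sprintf("<bpm_result> z = %g um, exit FWHM = %.2f um, power ratio %.4f\n",
              x$field$z, fwhm(x$profile), x$power_out / x$power_in))
  invisible(x)
}

#' Tidy a BPM result
#'
#' @param x A `bpm_result`.
#' @param ... Unused.
#' @return `tidy()`: the exit intensity profile as a tibble;
#'   `glance()`: one row with `fwhm_exit`, `power_in`, `power_out`, `z`.
#' @export
tidy.bpm_result <- function(x, ...) as_tibble(x$profile)

#' @rdname tidy.bpm_result
#' @export
glance.bpm_result <- function(x, ...) {
  tibble(fwhm_exit = fwhm(x$profile), power_in = x$power_in,
         power_out = x$power_out, z = x$field$z)
}

#' @export
autoplot.bpm_result <- function(object, ...) {
  if (is.null(object$intensity_map)) {
    return(ggplot(tidy(object), aes(.data$x, .data$intensity)) +
             geom_line() + labs(x = "x (um)", y = "intensity") + theme_minimal())
  }
  df <- tibble(
    x = rep(object$field$x, times = ncol(object$intensity_map)),
    z = rep(object$z, each = nrow(object$intensity_map)),
    intensity = as.vector(object$intensity_map)
  )
  ggplot(df, aes(.data$z, .data$x, fill = .data$intensity)) +
    geom_raster() + scale_fill_viridis_c() +
    labs(x = "z (um)", y = "x (um)", fill = "I") + theme_minimal()
}

#' Analytic free-space Gaussian diffraction width
#'
#' Intensity FWHM of a Gaussian beam of waist `w0` (1/e^2 radius, um)
#' after propagating `distance` um in a medium of index `n0`:
#' \eqn{w(z) = w_0 \sqrt{1 + (z \lambda / (\pi w_0^2 n_0))^2}}.
#'
#' @param w0 Waist (1/e^2 intensity radius), um.
#' @param distance Propagation distance, um.
#' @param wavelength Vacuum wavelength, um.
#' @param n0 Medium refractive index.
#' @return Intensity FWHM in um.
#' @export
gaussian_diffraction_fwhm <- function(w0, distance, wavelength = 0.66, n0 = 1.33) {
  zr <- pi * w0^2 * n0 / wavelength
  w <- w0 * sqrt(1 + (distance / zr)^2)
  w * sqrt(2 * log(2))
}
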