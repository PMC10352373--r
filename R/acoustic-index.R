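#' Acoustic cavity specification
#'
#' Describes the ultrasound-modulated refractive index inside a resonant
#' cylindrical cavity. A radial standing wave imprints
#' \deqn{n(r, t) = n_0 + n_A \, J_0(k r) \cos(\omega t)}
#' on the fluid, where \eqn{J_0} is the zeroth-order Bessel function,
#' \eqn{k} the acoustic wavevector and \eqn{\omega t} the snapshot phase.
#' With pulsed illumination much shorter than the acoustic period the
#' light interacts with a frozen snapshot of this profile; the default
#' `phase = 0` is the instant of maximum positive on-axis modulation.
#'
#' The perturbation regime requires `nA/n0 < 1e-2`; amplitudes beyond
#' that are rejected.
#'
#' @param n0 Static refractive index of the fluid (water: 1.33).
#' @param nA Modulation amplitude (dimensionless), `>= 0`.
#' @param k Acoustic wavevector in mm^-1 (4 MHz resonance: 15.8).
#' @param freq Drive frequency in MHz (metadata only; the snapshot field
#'   depends on `phase`, not `freq`).
#' @param phase Snapshot acoustic phase \eqn{\omega t} in radians.
#' @param cavity_length Cavity length along the optical axis, mm.
#' @param cavity_radius Radial extent of validity of the profile, mm.
#' @return An object of class `us_cavity`.
#' @examples
#' cav <- acoustic_cavity(nA = 8e-5)
#' refractive_index(0, cav) - 1.33
#' @export
acoustic_cavity <- function(n0 = 1.33, nA = 8e-5, k = 15.8, freq = 4,
                            phase = 0, cavity_length = 20, cavity_radius = 8) {
  check_number(n0, "n0", lower = 0, strict_lower = TRUE)
  check_number(nA, "nA", lower = 0)
  check_number(k, "k", lower = 0, strict_lower = TRUE)
  check_number(freq, "freq", lower = 0)
  check_number(phase, "phase")
  check_number(cavity_length, "cavity_length", lower = 0, strict_lower = TRUE)
  check_number(cavity_radius, "cavity_radius", lower = 0, strict_lower = TRUE)
  if (nA / n0 >= 1e-2) {
    abort("`nA/n0` must stay below 1e-2 (acousto-optic perturbation regime).")
  }
  structure(
    list(n0 = n0, nA = nA, k = k, freq = freq, phase = phase,
         cavity_length = cavity_length, cavity_radius = cavity_radius),
    class = "us_cavity"
  )
}

#' @export
print.us_cavity <- function(x, ...) {
  cat(sprintf(
    "<us_cavity> n0 = %g, nA = %g, k = %g mm^-1, %g MHz, phase = %g rad\n",
    x$n0, x$nA, x$k, x$freq, x$phase))
  cat(sprintf("  cavity: length %g mm, radius %g mm\n",
              x$cavity_length, x$cavity_radius))
  invisible(x)
}

#' Ultrasound-modulated refractive index at radius r
#'
#' Evaluates \eqn{n_0 + n_A J_0(k r) \cos(\omega t)} at radial distance
#' `r` (micrometres) from the cavity axis.
#'
#' @param r Radial distance(s) in um, `>= 0`.
#' @param cavity An [acoustic_cavity()] specification.
#' @return Refractive index value(s), same length as `r`.
#' @export
refractive_index <- function(r, cavity) {
  stopifnot(inherits(cavity, "us_cavity"))
  if (!is.numeric(r) || any(!is.finite(r))) abort("`r` must be finite numeric.")
  if (any(r < 0)) abort("`r` must be non-negative.")
  k_um <- cavity$k * 1e-3  # mm^-1 -> um^-1
  cavity$n0 + cavity$nA * besselJ(k_um * r, 0) * cos(cavity$phase)
}

# transverse index and gradient along a 1D x-axis (um), r = |x - origin|
index_profile_1d <- function(cavity, x, origin = 0) {
  k_um <- cavity$k * 1e-3
  r <- abs(x - origin)
  ph <- cos(cavity$phase)
  list(
    n = cavity$n0 + cavity$nA * besselJ(k_um * r, 0) * ph,
    # d/dx J0(k|x|) = -k J1(k|x|) sign(x)
    dndx = -cavity$nA * k_um * besselJ(k_um * r, 1) * sign(x - origin) * ph
  )
}

#' Sample the modulated index on a 2D (x, z) grid
#'
#' Builds the discretised refractive-index map used by both propagation
#' engines. The simulations run in a Cartesian (x, z) slice through the
#' cylinder axis with \eqn{r = |x - \mathrm{origin}|}; the profile is
#' z-invariant inside `modulated_z` and equals `n0` outside it (external
#' lens scenarios).
#'
#' @param cavity An [acoustic_cavity()].
#' @param x_extent,z_extent Physical extents in um.
#' @param dx,dz Cell sizes in um.
#' @param origin Transverse coordinate of the acoustic axis, um.
#' @param modulated_z Length-2 numeric, z-range (um) over which the
#'   modulation is applied; defaults to the whole z extent.
#' @param on_wide Action when `x_extent` exceeds the cavity diameter:
#'   `"error"` (default) or `"clamp"` (warn and clamp to the diameter).
#' @return An object of class `ri_field` with fields `values`
#'   (nx x nz matrix, rows = x), `x`, `z` (cell centres, um), `dx`, `dz`,
#'   `origin` and the generating `cavity`.
#' @export
build_index_field <- function(cavity, x_extent = 500, z_extent = 20000,
                              dx = 4, dz = 4, origin = 0,
                              modulated_z = NULL,
                              on_wide = c("error", "clamp")) {
  stopifnot(inherits(cavity, "us_cavity"))
  on_wide <- match.arg(on_wide)
  for (nm in c("x_extent", "z_extent", "dx", "dz")) {
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  diameter_um <- 2 * cavity$cavity_radius * 1e3
  if (x_extent > diameter_um) {
    if (on_wide == "error") {
      abort(sprintf("`x_extent` (%g um) exceeds the cavity diameter (%g um).",
                    x_extent, diameter_um))
    }
    warn("`x_extent` clamped to the cavity diameter.")
    x_extent <- diameter_um
  }
  nx <- max(2L, round(x_extent / dx))
  nz <- max(1L, round(z_extent / dz))
  x <- (seq_len(nx) - (nx + 1) / 2) * dx
  z <- (seq_len(nz) - 0.5) * dz
  if (is.null(modulated_z)) modulated_z <- c(0, nz * dz)
  prof <- index_profile_1d(cavity, x, origin = origin)
  inside <- z > modulated_z[1] & z <= modulated_z[2]
  values <- matrix(cavity$n0, nx, nz)
  dndx <- matrix(0, nx, nz)
  if (cavity$nA > 0 && any(inside)) {
    values[, inside] <- prof$n
    dndx[, inside] <- prof$dndx
  }
  structure(
    list(values = values, dndx = dndx, x = x, z = z, dx = dx, dz = dz,
         origin = origin, modulated_z = modulated_z, cavity = cavity),
    class = "ri_field"
  )
}

#' @export
print.ri_field <- function(x, ...) {
  cat(sprintf("<ri_field> %d x %d cells, dx = %g um, dz = %g um\n",
              nrow(x$values), ncol(x$values), x$dx, x$dz))
  cat(sprintf("  n in [%.8f, %.8f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Long-format view of an index field
#'
#' @param x An `ri_field`.
#' @param ... Unused.
#' @return A tibble with columns `x`, `z` (um) and `n`.
#' @export
tidy.ri_field <- function(x, ...) {
  tibble(
    x = rep(x$x, times = length(x$z)),
    z = rep(x$z, each = length(x$x)),
    n = as.vector(x$values)
  )
}

#' @export
autoplot.ri_field <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$z, y = .data$x, fill = .data$n)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "z (um)", y = "x (um)", fill = "n") +
    theme_minimal()
}

#' Paraxial GRIN constants of the modulated channel
#'
#' Near the axis \eqn{J_0(kr) \approx 1 - (kr)^2/4}, so the channel is a
#' parabolic gradient-index (GRIN) medium with gradient constant
#' \eqn{g = k \sqrt{n_A / (2 n_0)}} and quarter pitch \eqn{\pi / (2g)} —
#' the focal distance of a collimated paraxial input.
#'
#' @param cavity An [acoustic_cavity()] with `nA > 0`.
#' @return A tibble with columns `g_grin` (mm^-1) and `quarter_pitch`
#'   (mm).
#' @examples
#' paraxial_grin(acoustic_cavity(nA = 8e-5))  # quarter pitch ~ 18 mm
#' @export
paraxial_grin <- function(cavity) {
  stopifnot(inherits(cavity, "us_cavity"))
  if (cavity$nA <= 0) abort("`nA` must be positive: no lensing without modulation.")
  g <- cavity$k * sqrt(cavity$nA / (2 * cavity$n0))
  tibble(g_grin = g, quarter_pitch = pi / (2 * g))
}
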