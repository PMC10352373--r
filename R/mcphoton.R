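#' Gridded scattering medium for Monte Carlo transport
#'
#' Builds the rectangular 2D cell grid (x transverse, z axial) carrying
#' the optical properties per cell: scattering coefficient `mus`,
#' absorption `mua`, Henyey-Greenstein anisotropy `g` and refractive
#' index from an optional modulated cavity. The default region is
#' 2 cm x 500 um at 4 um cells.
#'
#' Side walls at the +-x boundary carry a refractive-index step to
#' `n_out` (Fresnel reflection, total internal reflection beyond the
#' critical angle), which retains obliquely scattered light in the
#' water-filled chamber; `n_out = NA` makes the walls open (packets
#' leaving the region are dropped).
#'
#' @param width,length Region extents in um.
#' @param cell Cell size in um.
#' @param mus Scattering coefficient in cm^-1: a scalar or an
#'   `nx x nz` matrix.
#' @param mua Absorption coefficient in cm^-1 (uniform).
#' @param g Scattering anisotropy, in (-1, 1).
#' @param cavity Optional [acoustic_cavity()] whose index modulation is
#'   applied over `modulated_z`; `NULL` gives a uniform index `n0`.
#' @param modulated_z Length-2 z-range (um) of the modulation.
#' @param scattering_z Optional length-2 z-range (um) outside of which
#'   `mus` is zeroed (e.g. scattering confined to the far half).
#' @param n0 Background refractive index (used when `cavity` is `NULL`).
#' @param n_out Exterior index at the side walls (default 1, air; `NA`
#'   for open boundaries).
#' @return An object of class `medium_grid`.
#' @export
medium_grid <- function(width = 500, length = 20000, cell = 4,
                        mus = 0, mua = 0, g = 0.94,
                        cavity = NULL, modulated_z = NULL,
                        scattering_z = NULL, n0 = 1.33, n_out = 1.0) {
  check_number(width, "width", lower = 0, strict_lower = TRUE)
  check_number(length, "length", lower = 0, strict_lower = TRUE)
  check_number(cell, "cell", lower = 0, strict_lower = TRUE)
  check_number(mua, "mua", lower = 0)
  check_number(g, "g", lower = -1, upper = 1)
  if (abs(g) >= 1) abort("`g` must lie strictly inside (-1, 1).")
  nx <- max(2L, round(width / cell))
  nz <- max(1L, round(length / cell))
  if (is.null(cavity)) {
    n <- matrix(n0, nx, nz)
    dndx <- matrix(0, nx, nz)
    x <- (seq_len(nx) - (nx + 1) / 2) * cell
  } else {
    stopifnot(inherits(cavity, "us_cavity"))
    fld <- build_index_field(cavity, x_extent = width, z_extent = length,
                             dx = cell, dz = cell, modulated_z = modulated_z)
    n <- fld$values; dndx <- fld$dndx; x <- fld$x; n0 <- cavity$n0
  }
  z <- (seq_len(nz) - 0.5) * cell
  if (is.matrix(mus)) {
    if (!all(dim(mus) == c(nx, nz))) abort("`mus` matrix must be nx x nz.")
    mus_m <- mus
  } else {
    check_number(mus, "mus", lower = 0)
    mus_m <- matrix(mus, nx, nz)
  }
  if (!is.null(scattering_z)) {
    outside <- z <= scattering_z[1] | z > scattering_z[2]
    mus_m[, outside] <- 0
  }
  if (any(mus_m < 0)) abort("`mus` must be non-negative.")
  structure(
    list(n = n, dndx = dndx, mus = mus_m, mua = mua, g = g,
         cell = cell, x = x, z = z, n0 = n0,
         n_out = if (is.na(n_out)) 0 else n_out),
    class = "medium_grid"
  )
}

#' @export
print.medium_grid <- function(x, ...) {
  cat(sprintf(
    "<medium_grid> %d x %d cells of %g um (%.1f x %.0f um), g = %g\n",
    nrow(x$n), ncol(x$n), x$cell, nrow(x$n) * x$cell, ncol(x$n) * x$cell, x$g))
  cat(sprintf("  mus in [%g, %g] cm^-1, mua = %g cm^-1, walls n_out = %g\n",
              min(x$mus), max(x$mus), x$mua, x$n_out))
  invisible(x)
}

#' Angular spread of a diffraction-limited Gaussian beam
#'
#' Standard deviation of the far-field angular intensity distribution of
#' a Gaussian beam: \eqn{\sigma_\theta = \lambda / (2 \pi w_0)} with
#' `w0` the waist implied by the intensity FWHM. Used as the default
#' source divergence of the Monte Carlo line source.
#'
#' @param fwhm Intensity FWHM of the beam, um.
#' @param wavelength Vacuum wavelength, um.
#' @return Divergence sigma in radians.
#' @export
beam_divergence_sigma <- function(fwhm = 300, wavelength = 0.66) {
  w0 <- fwhm / sqrt(2 * log(2))
  wavelength / (2 * pi * w0)
}

#' Monte Carlo photon source
#'
#' A transverse line source centred on the axis at z = 0, launching
#' packets uniformly along its length with a Gaussian angular tilt.
#'
#' @param length Source extent in um.
#' @param divergence_sigma Standard deviation of the Gaussian launch
#'   angle, radians. Defaults to the diffraction-limited spread of a
#'   300 um FWHM, 660 nm beam ([beam_divergence_sigma()]).
#' @param photons Packet count.
#' @param fluence_in Input-plane fluence in J/cm^2.
#' @return An object of class `mc_source`.
#' @export
mc_source <- function(length = 300,
                      divergence_sigma = beam_divergence_sigma(),
                      photons = 1e5, fluence_in = 1) {
  check_number(length, "length", lower = 0, strict_lower = TRUE)
  check_number(divergence_sigma, "divergence_sigma", lower = 0)
  check_number(photons, "photons", lower = 1)
  check_number(fluence_in, "fluence_in", lower = 0, strict_lower = TRUE)
  structure(
    list(length = length, divergence_sigma = divergence_sigma,
         photons = as.integer(photons), fluence_in = fluence_in),
    class = "mc_source"
  )
}

#' Sample free optical depths
#'
#' Path lengths between scattering events in units of optical depth:
#' \eqn{-\ln \xi} with \eqn{\xi \sim U(0, 1)} (Exp(1)).
#'
#' @param n Number of draws.
#' @return Positive depths with unit mean.
#' @export
sample_free_optical_depth <- function(n = 1) {
  -log(runif(n))
}

#' Sample Henyey-Greenstein deflection angles
#'
#' Draws the polar deflection cosine from the Henyey-Greenstein phase
#' function by inverse-CDF sampling,
#' \deqn{\cos\theta = \frac{1}{2g}\left[1 + g^2 -
#'   \left(\frac{1 - g^2}{1 - g + 2 g \xi}\right)^2\right],}
#' (isotropic, \eqn{2\xi - 1}, for `g = 0`) and collapses the azimuth to
#' a random sign for the in-plane 2D geometry. `E[cos theta] = g`
#' exactly.
#'
#' @param n Number of draws.
#' @param g Anisotropy factor, strictly inside (-1, 1).
#' @return Signed deflection angles in radians.
#' @export
scatter_hg <- function(n = 1, g = 0.94) {
  if (abs(g) >= 1) abort("`g` must lie strictly inside (-1, 1).")
  ct <- hg_cos_sample(n, g)
  acos(ct) * sample(c(-1, 1), n, replace = TRUE)
}

hg_cos_sample <- function(n, g) {
  u <- runif(n)
  if (abs(g) < 1e-12) return(2 * u - 1)
  f <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - f^2) / (2 * g)))
}

# Henyey-Greenstein density of cos(theta)
hg_density <- function(ct, g) {
  (1 - g^2) / (2 * (1 + g^2 - 2 * g * ct)^1.5)
}

#' Bend a ray through a graded-index field
#'
#' First-order integration of the eikonal ray equation
#' \eqn{\mathrm{d}(n \mathbf{u})/\mathrm{d}s = \nabla n}:
#' the direction receives a transverse kick
#' \eqn{u_x \leftarrow u_x + (\Delta s / n)\,\partial n/\partial x},
#' is renormalised, and the position advances `step` along the bent ray.
#'
#' @param packet List with `position` (c(x, z), um), `direction`
#'   (unit vector c(ux, uz)) and `weight`.
#' @param index An `ri_field`.
#' @param step Step length in um, at most the field cell size.
#' @return The advanced packet; `packet$exited` is set when it leaves
#'   the grid.
#' @export
bend_ray <- function(packet, index, step) {
  stopifnot(inherits(index, "ri_field"))
  if (step > min(index$dx, index$dz) + 1e-9) {
    abort("`step` must not exceed the cell size.")
  }
  x <- packet$position[1]; z <- packet$position[2]
  u <- packet$direction
  nx <- nrow(index$values); nz <- ncol(index$values)
  ix <- floor((x - index$x[1]) / index$dx) + 1
  iz <- floor(z / index$dz) + 1
  if (ix < 1 || ix > nx || iz < 1 || iz > nz) {
    packet$exited <- TRUE
    return(packet)
  }
  # gradient linearly interpolated between cell centres
  f <- (x - index$x[ix]) / index$dx
  ix2 <- min(nx, max(1, ix + ifelse(f >= 0, 1L, -1L)))
  wt <- abs(f)
  dndx <- (1 - wt) * index$dndx[ix, iz] + wt * index$dndx[ix2, iz]
  n_here <- (1 - wt) * index$values[ix, iz] + wt * index$values[ix2, iz]
  u[1] <- u[1] + step / n_here * dndx
  u <- u / sqrt(sum(u^2))
  packet$position <- packet$position + step * u
  packet$direction <- u
  packet$exited <- FALSE
  packet
}

#' Run the photon-packet Monte Carlo simulation
#'
#' Transports `source$photons` packets through the `grid`: free optical
#' depths are drawn as \eqn{-\ln\xi}, trajectories bend continuously
#' through the graded index (eikonal substeps of one cell), optical
#' depth \eqn{\int \mu_s \mathrm{d}s} accumulates along the bent ray,
#' and scattering deflects the direction by a Henyey-Greenstein angle
#' with random in-plane sign. Packets leaving the entrance plane or
#' (for open walls) the sides are dropped; side walls with an index
#' step reflect by Fresnel/total internal reflection. A safety cap
#' kills packets after 10x the region length of path.
#'
#' The exit profile is normalised such that straight transport of the
#' source yields `fluence_in` at the exit plane.
#'
#' @param grid A [medium_grid()].
#' @param source An [mc_source()].
#' @param seed Integer RNG seed (fixed seed gives bit-identical output).
#' @param tally_fluence Accumulate the per-cell track-length fluence map
#'   (slower; needed only for images).
#' @return A `fluence_map` with the exit-plane `profile`
#'   ([profile1d()], J/cm^2), the never-scattered `ballistic_profile`,
#'   optional `cells` matrix, packet counts and weight bookkeeping.
#' @export
run_mc_simulation <- function(grid, source, seed = 1L,
                              tally_fluence = FALSE) {
  stopifnot(inherits(grid, "medium_grid"), inherits(source, "mc_source"))
  if (source$photons < 1) abort("Need at least one photon packet.")
  set.seed(seed)
  res <- mc_transport_cpp(grid$n, grid$dndx, grid$mus * 1e-4, grid$mua * 1e-4,
                          grid$g, grid$cell, source$length,
                          source$divergence_sigma, source$photons,
                          tally_fluence, grid$n_out)
  if (any(!is.finite(res$exit_profile))) abort("Non-finite tally encountered.")
  # energy per packet such that the input plane carries `fluence_in`
  e0 <- source$fluence_in * source$length / source$photons
  profile <- profile1d(grid$x, res$exit_profile * e0 / grid$cell)
  ballistic <- profile1d(grid$x, res$exit_ballistic * e0 / grid$cell)
  structure(
    list(profile = profile, ballistic_profile = ballistic,
         cells = if (tally_fluence) res$fluence * e0 / grid$cell^2,
         x = grid$x, z = grid$z, cell = grid$cell,
         n_launched = res$n_launched,
         n_exited_forward = res$n_exit_forward,
         n_ballistic = res$n_ballistic,
         weights = list(forward = res$w_exit_forward,
                        side = res$w_exit_side,
                        back = res$w_exit_back,
                        killed = res$w_killed,
                        absorbed = res$w_absorbed),
         seed = seed, source = source),
    class = "fluence_map"
  )
}

#' External-lens Monte Carlo scenario
#'
#' The 4 cm comparison geometry: the first half of the region is the
#' water-filled external cavity with a weak modulation, the second half
#' is the sample medium with no modulation. Scattering, when present, is
#' confined to the second half.
#'
#' @param cavity External-lens cavity (default `nA = 2e-5`; see the
#'   methods vignette for why this amplitude).
#' @param mus Scattering coefficient of the sample half, cm^-1.
#' @param total_length Full region length in um.
#' @param width,cell As in [medium_grid()].
#' @param source An [mc_source()].
#' @param seed RNG seed.
#' @param tally_fluence Accumulate the fluence map.
#' @param ... Passed to [medium_grid()].
#' @return A `fluence_map` evaluated at the far exit plane.
#' @export
run_external_lens_simulation <- function(cavity = acoustic_cavity(nA = 2e-5),
                                         mus = 0, total_length = 40000,
                                         width = 500, cell = 4,
                                         source = mc_source(),
                                         seed = 1L, tally_fluence = FALSE,
                                         ...) {
  half <- total_length / 2
  grid <- medium_grid(width = width, length = total_length, cell = cell,
                      mus = mus, cavity = cavity,
                      modulated_z = c(0, half),
                      scattering_z = c(half, total_length), ...)
  run_mc_simulation(grid, source, seed = seed, tally_fluence = tally_fluence)
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("<fluence_map> %d launched, %d exited forward (%d ballistic)\n",
              x$n_launched, x$n_exited_forward, x$n_ballistic))
  cat(sprintf("  exit FWHM = %.1f um\n",
              tryCatch(fwhm(x$profile), error = function(e) NA_real_)))
  invisible(x)
}

#' Tidy a Monte Carlo fluence map
#'
#' @param x A `fluence_map`.
#' @param ... Unused.
#' @return `tidy()`: exit profile tibble with `x`, `intensity` and the
#'   ballistic component; `glance()`: one row with the spot FWHM,
#'   focusing contrast, ballistic fraction and packet counts.
#' @export
tidy.fluence_map <- function(x, ...) {
  mutate(as_tibble(x$profile), ballistic = x$ballistic_profile$intensity)
}

#' @rdname tidy.fluence_map
#' @export
glance.fluence_map <- function(x, ...) {
  tibble(
    fwhm = tryCatch(fwhm(x$profile), error = function(e) NA_real_),
    focusing_contrast = tryCatch(focusing_contrast(x$profile),
                                 error = function(e) NA_real_),
    ballistic_fraction = x$n_ballistic / x$n_launched,
    forward_fraction = x$weights$forward / x$n_launched,
    n_launched = x$n_launched, seed = x$seed
  )
}

#' @export
autoplot.fluence_map <- function(object, ...) {
  if (!is.null(object$cells)) {
    df <- tibble(
      x = rep(object$x, times = length(object$z)),
      z = rep(object$z, each = length(object$x)),
      fluence = as.vector(object$cells)
    )
    return(ggplot(df, aes(.data$z, .data$x, fill = .data$fluence)) +
             geom_raster() + scale_fill_viridis_c(trans = "sqrt") +
             labs(x = "z (um)", y = "x (um)", fill = "J/cm^2") +
             theme_minimal())
  }
  ggplot(tidy(object), aes(.data$x, .data$intensity)) +
    geom_line() +
    labs(x = "x (um)", y = "exit fluence (J/cm^2)") +
    theme_minimal()
}
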