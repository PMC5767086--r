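## Bonded-parameter derivation from observed distributions: Boltzmann
## inversion for harmonic bonds, fourth-order polynomial fits for 3-body
## angle potentials.

#' Boltzmann inversion of a bond-length distribution
#'
#' For a harmonic bond in thermal equilibrium the length distribution is
#' Gaussian with variance kT/k, so inverting an observed distribution gives
#' r0 as the sample mean and k = kT / var. This is how CG bond potentials
#' are assigned to reproduce the bond fluctuations observed in reference
#' (atomistic) simulations.
#'
#' @param values Observed bond lengths, nm (at least 100).
#' @param kT Thermal energy of the generating ensemble, kJ/mol.
#' @return List with `k` (kJ/mol/nm^2), `r0` (nm), `n`.
#' @export
#' @examples
#' x <- stats::rnorm(1e4, 0.26, 0.01)
#' boltzmann_invert_bond(x, kT = 2.24)   # k ~ 2.24 / 1e-4
boltzmann_invert_bond <- function(values, kT = 2.24) {
  if (kT <= 0) stop("kT must be positive")
  if (length(values) < 100L)
    stop("need at least 100 samples for a bond fit")
  v <- stats::var(values)
  if (!is.finite(v) || v <= 0)
    stop("degenerate distribution: zero variance")
  list(k = kT / v, r0 = mean(values), n = length(values))
}

#' Fit a fourth-order polynomial angle potential
#'
#' Histograms the observed angles, converts occupied bins to energies via
#' U = -kT ln p, and least-squares fits U(theta) = sum c_n theta^n
#' (n = 0..4). The constant offset is chosen so that the minimum of the
#' fitted potential over the occupied range is zero; the fit is therefore
#' invariant to any constant added to the histogram energies. Empty bins
#' are excluded rather than regularized. By default the distribution is
#' fitted as observed, without the sin(theta) Jacobian correction; set
#' `jacobian = TRUE` to remove the solid-angle factor first (both
#' conventions are in use for CG angle parameterization).
#'
#' @param values Observed angles, radians, in (0, pi); at least 100.
#' @param kT Thermal energy, kJ/mol.
#' @param order Polynomial order; only 4 is supported.
#' @param n_bins Histogram bins over (0, pi).
#' @param jacobian Divide the histogram by sin(theta) before inverting.
#' @return List of class `angle_fit` with `coefficients` (c0..c4),
#'   `bin_centers`, `bin_energy` (occupied bins, offset-aligned), `rms`
#'   (kJ/mol over occupied bins), `n`.
#' @export
fit_angle_potential <- function(values, kT = 2.24, order = 4L,
                                n_bins = 90L, jacobian = FALSE) {
  if (order != 4L) stop("only fourth-order polynomial fits are supported")
  if (length(values) < 100L) stop("need at least 100 samples")
  if (any(values <= 0 | values >= pi))
    stop("angles must lie strictly inside (0, pi)")
  breaks <- seq(0, pi, length.out = n_bins + 1L)
  h <- hist(values, breaks = breaks, plot = FALSE)
  dens <- h$density
  if (jacobian) dens <- dens / sin(h$mids)
  occ <- which(dens > 0)
  if (length(occ) < order + 2L)
    stop("fit error: fewer occupied bins (", length(occ),
         ") than required (", order + 2L, ")")
  th <- h$mids[occ]
  U <- -kT * log(dens[occ])
  ## weight by counts: the variance of a log-histogram energy scales as
  ## 1/count, so sparse tail bins should not dominate the fit
  cnt <- h$counts[occ]
  fit <- stats::lm(U ~ poly(th, degree = order, raw = TRUE),
                   weights = cnt)
  cf <- unname(stats::coef(fit))
  ## shift so min of fitted U over the occupied range is zero
  grid <- seq(min(th), max(th), length.out = 500L)
  Ug <- drop(cbind(1, grid, grid^2, grid^3, grid^4) %*% cf)
  cf[1] <- cf[1] - min(Ug)
  ## histogram energies carry an arbitrary constant; align on the fit mean
  Ufit <- drop(cbind(1, th, th^2, th^3, th^4) %*% cf)
  structure(
    list(coefficients = stats::setNames(cf, paste0("c", 0:4)),
         bin_centers = th,
         bin_energy = U - mean(U) + mean(Ufit),
         rms = sqrt(mean((Ufit - (U - mean(U) + mean(Ufit)))^2)),
         n = length(values)),
    class = "angle_fit"
  )
}

#' @export
print.angle_fit <- function(x, ...) {
  cat("fourth-order angle potential fit\n")
  print(signif(x$coefficients, 5))
  cat(sprintf("RMS residual over %d occupied bins: %.3g kJ/mol\n",
              length(x$bin_centers), x$rms))
  invisible(x)
}

#' Evaluate a polynomial angle potential
#'
#' @param coefficients Numeric c0..c4.
#' @param theta Angles, radians.
#' @return Energies, kJ/mol.
#' @export
angle_potential_energy <- function(coefficients, theta) {
  drop(cbind(1, theta, theta^2, theta^3, theta^4) %*%
         as.numeric(coefficients))
}
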