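## Umbrella-sampling orchestration and free-energy estimation: window
## layout, self-consistent WHAM, split-half errors, bulk zeroing,
## symmetrization and feature extraction.

#' One umbrella window
#'
#' Holds the biased reaction-coordinate samples collected under a harmonic
#' restraint U_bias = k/2 (z - z0)^2. A window may carry several sample
#' series: with the duplicate-solute setup each window contributes one
#' series per solute copy, and the copies serve as the two halves of the
#' split-half error estimate.
#'
#' @param z0 Window center, nm.
#' @param k Bias force constant, kJ/mol/nm^2 (0 = unbiased window).
#' @param samples Numeric vector, or list of numeric series.
#' @param kT Thermal energy, kJ/mol.
#' @param burn_in Leading samples of each series excluded from analysis
#'   (equilibration; 0 for sidechain-style windows, the first 16 ns worth
#'   for peptide windows).
#' @return List of class `umbrella_window`.
#' @export
umbrella_window <- function(z0, k, samples, kT = 2.24, burn_in = 0L) {
  if (k < 0) stop("k must be non-negative")
  if (!is.list(samples)) samples <- list(samples)
  structure(list(z0 = z0, k = k, samples = samples, kT = kT,
                 burn_in = as.integer(burn_in)),
            class = "umbrella_window")
}

window_samples <- function(w) {
  out <- lapply(w$samples, function(s)
    if (w$burn_in > 0L) s[-seq_len(min(w$burn_in, length(s)))] else s)
  unlist(out, use.names = FALSE)
}

#' Lay out umbrella windows along the membrane normal
#'
#' Window centers run from `z_min` to `z_max` inclusive at the given
#' spacing (0 to 4 nm at 0.2 nm gives the standard 21-window sidechain
#' layout). With `duplicate_offset` set, each window carries a second
#' restraint center at `center - duplicate_offset` for the duplicate solute
#' copy placed that far below the first, which doubles the data collected
#' per run.
#'
#' @param z_min,z_max First and last window center, nm.
#' @param spacing Window spacing, nm (> 0).
#' @param duplicate_offset Offset of the duplicate copy, nm, or `NULL`.
#' @param k Bias force constant, kJ/mol/nm^2.
#' @param kT Thermal energy, kJ/mol.
#' @return Data frame with columns `center`, `k`, `kT` and (if requested)
#'   `center2`.
#' @export
#' @examples
#' nrow(layout_windows(0, 4, 0.2))   # 21
layout_windows <- function(z_min, z_max, spacing, duplicate_offset = NULL,
                           k = 350, kT = 2.24) {
  if (spacing <= 0) stop("spacing must be positive")
  if (z_max < z_min) stop("z_max must be >= z_min")
  centers <- seq(z_min, z_max + spacing * 1e-9, by = spacing)
  out <- data.frame(center = centers, k = k, kT = kT)
  if (!is.null(duplicate_offset))
    out$center2 <- centers - duplicate_offset
  out
}

#' PMF profile container
#'
#' @param bin_centers Bin centers, nm.
#' @param free_energy Free energy per bin, kJ/mol (NA in unsampled bins).
#' @param error Per-bin error, kJ/mol.
#' @param kT Thermal energy, kJ/mol.
#' @param counts Per-bin sample counts.
#' @param zero_reference Description of the zeroing applied.
#' @return List of class `pmf_profile`.
#' @export
pmf_profile <- function(bin_centers, free_energy,
                        error = rep(NA_real_, length(bin_centers)),
                        kT = 2.24, counts = NULL, zero_reference = NULL) {
  stopifnot(length(bin_centers) == length(free_energy))
  structure(list(bin_centers = bin_centers, free_energy = free_energy,
                 error = error, kT = kT, counts = counts,
                 zero_reference = zero_reference),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  occ <- which(is.finite(x$free_energy))
  cat(sprintf("PMF profile: %d bins (%d occupied) on [%.3f, %.3f] nm\n",
              length(x$bin_centers), length(occ),
              min(x$bin_centers), max(x$bin_centers)))
  if (!is.null(x$zero_reference))
    cat("  zero reference:", x$zero_reference, "\n")
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  graphics::plot(x$bin_centers, x$free_energy, type = "l",
                 xlab = "z (nm)", ylab = "free energy (kJ/mol)", ...)
  if (any(is.finite(x$error))) {
    graphics::lines(x$bin_centers, x$free_energy + x$error, lty = 3)
    graphics::lines(x$bin_centers, x$free_energy - x$error, lty = 3)
  }
  invisible(x)
}

#' Weighted histogram analysis (WHAM)
#'
#' Combines the biased window histograms into one unbiased free-energy
#' profile by iterating the self-consistent equations
#' P(b) = sum_j n_j(b) / sum_j N_j exp((F_j - w_j(b)) / kT) and
#' F_j = -kT ln sum_b P(b) exp(-w_j(b) / kT) until the largest change in
#' any window free energy F_j falls below `tol`. The profile is
#' F(b) = -kT ln P(b), shifted so its minimum is zero; bins never sampled
#' are NA. A single unbiased window (k = 0) degenerates to
#' -kT ln(histogram).
#'
#' @param windows List of [umbrella_window()] objects with overlapping
#'   sampling (every interior bin reachable).
#' @param n_bins Number of bins (default 400).
#' @param tol Convergence tolerance on the window free energies, kJ/mol.
#' @param max_iter Iteration cap.
#' @param range Optional c(min, max) histogram range, nm; defaults to the
#'   sampled range.
#' @return A [pmf_profile()] with attribute `window_free_energies`.
#' @export
wham <- function(windows, n_bins = 400L, tol = 1e-8, max_iter = 100000L,
                 range = NULL) {
  stopifnot(length(windows) >= 1L)
  samples <- lapply(windows, window_samples)
  if (any(lengths(samples) == 0L))
    stop("window with no post-burn-in samples")
  kT <- unique(vapply(windows, function(w) w$kT, numeric(1)))
  if (length(kT) != 1L) stop("windows disagree on kT")
  all_s <- unlist(samples)
  if (is.null(range)) range <- base::range(all_s)
  breaks <- seq(range[1] - 1e-9, range[2] + 1e-9, length.out = n_bins + 1L)
  xc <- (breaks[-1] + breaks[-length(breaks)]) / 2
  W <- length(windows)
  counts <- t(vapply(samples, function(s)
    tabulate(findInterval(s, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = n_bins),
    numeric(n_bins)))
  Cb <- colSums(counts)
  occ <- which(Cb > 0)
  ## overlap check: adjacent windows (by center) must have overlapping
  ## sampled ranges, otherwise part of the coordinate is unreachable
  if (W > 1L) {
    ord <- order(vapply(windows, function(w) w$z0, numeric(1)))
    lo <- vapply(samples[ord], min, numeric(1))
    hi <- vapply(samples[ord], max, numeric(1))
    binw <- diff(xc[1:2])
    for (j in seq_len(W - 1L)) {
      if (hi[j] + binw < lo[j + 1L])
        stop(sprintf(
          "convergence error: no sampling between z = %.3f and z = %.3f nm",
          hi[j], lo[j + 1L]))
    }
  }
  Nj <- rowSums(counts)
  wjb <- t(vapply(windows, function(w) 0.5 * w$k * (xc - w$z0)^2,
                  numeric(n_bins)))                       # W x B bias
  Bjb <- exp(-wjb / kT)
  Fj <- numeric(W)
  P <- numeric(n_bins)
  for (it in seq_len(max_iter)) {
    denom <- colSums(Nj * exp(Fj / kT) * Bjb)
    P[] <- 0
    P[occ] <- Cb[occ] / denom[occ]
    P <- P / sum(P)
    Fn <- -kT * log(drop(Bjb %*% P))
    Fn <- Fn - Fn[1]
    if (max(abs(Fn - Fj)) < tol) {
      Fj <- Fn
      break
    }
    Fj <- Fn
    if (it == max_iter)
      warning("WHAM did not converge in ", max_iter, " iterations")
  }
  Fb <- rep(NA_real_, n_bins)
  Fb[occ] <- -kT * log(P[occ])
  Fb <- Fb - min(Fb, na.rm = TRUE)
  out <- pmf_profile(xc, Fb, kT = kT, counts = Cb)
  attr(out, "window_free_energies") <- Fj
  out
}

#' Split-half PMF error estimate
#'
#' Runs WHAM independently on two halves of the data and reports half the
#' absolute difference per bin. Windows holding two sample series (the
#' duplicate solute copies) are split copy-wise; single-series windows are
#' split into first and second time halves. Both half-profiles are zeroed
#' over a common region (the `bulk` interval if given, otherwise the
#' jointly occupied bins) before differencing.
#'
#' @param windows List of [umbrella_window()] objects (each half must be
#'   non-empty).
#' @param n_bins,range,tol,max_iter Passed to [wham()]; the range defaults
#'   to the full-data range so that both halves share bins.
#' @param bulk Optional bulk interval c(lo, hi), nm (applied to |z|).
#' @return List with `bin_centers`, `error` (kJ/mol per bin), and the two
#'   half [pmf_profile()]s.
#' @export
split_half_error <- function(windows, n_bins = 400L, range = NULL,
                             tol = 1e-8, max_iter = 100000L, bulk = NULL) {
  halves <- lapply(windows, function(w) {
    series <- lapply(w$samples, function(s)
      if (w$burn_in > 0L) s[-seq_len(min(w$burn_in, length(s)))] else s)
    if (length(series) >= 2L) {
      h1 <- unlist(series[seq(1L, length(series), by = 2L)])
      h2 <- unlist(series[seq(2L, length(series), by = 2L)])
    } else {
      s <- series[[1]]
      if (length(s) < 2L) stop("window too short to split")
      half <- floor(length(s) / 2)
      h1 <- s[seq_len(half)]
      h2 <- s[(half + 1L):length(s)]
    }
    if (!length(h1) || !length(h2)) stop("empty half in split")
    list(umbrella_window(w$z0, w$k, h1, kT = w$kT),
         umbrella_window(w$z0, w$k, h2, kT = w$kT))
  })
  if (is.null(range))
    range <- base::range(unlist(lapply(windows, window_samples)))
  p1 <- wham(lapply(halves, `[[`, 1L), n_bins = n_bins, range = range,
             tol = tol, max_iter = max_iter)
  p2 <- wham(lapply(halves, `[[`, 2L), n_bins = n_bins, range = range,
             tol = tol, max_iter = max_iter)
  if (!is.null(bulk)) {
    p1 <- zero_in_bulk(p1, bulk)
    p2 <- zero_in_bulk(p2, bulk)
  } else {
    both <- is.finite(p1$free_energy) & is.finite(p2$free_energy)
    p1$free_energy <- p1$free_energy - mean(p1$free_energy[both])
    p2$free_energy <- p2$free_energy - mean(p2$free_energy[both])
  }
  list(bin_centers = p1$bin_centers,
       error = abs(p1$free_energy - p2$free_energy) / 2,
       half1 = p1, half2 = p2)
}

#' WHAM with split-half errors
#'
#' Convenience wrapper: full-data [wham()] profile with the per-bin
#' [split_half_error()] filled into the `error` slot.
#'
#' @inheritParams split_half_error
#' @return A [pmf_profile()].
#' @export
wham_with_error <- function(windows, n_bins = 400L, range = NULL,
                            tol = 1e-8, max_iter = 100000L, bulk = NULL) {
  if (is.null(range))
    range <- base::range(unlist(lapply(windows, window_samples)))
  p <- wham(windows, n_bins = n_bins, range = range, tol = tol,
            max_iter = max_iter)
  se <- split_half_error(windows, n_bins = n_bins, range = range,
                         tol = tol, max_iter = max_iter, bulk = bulk)
  p$error <- se$error
  p
}

#' Shift a PMF to zero in bulk water
#'
#' Subtracts the mean free energy over the occupied bins whose |z| lies in
#' the bulk interval, putting the profile on the water-referenced scale
#' used for all solvation-energy comparisons. Idempotent.
#'
#' @param pmf A [pmf_profile()].
#' @param bulk Bulk interval c(lo, hi), nm, applied to |z|. The default
#'   [3.2, 3.7] nm sits beyond the head-group region within the sampled
#'   range of the sidechain windows.
#' @return The shifted [pmf_profile()].
#' @export
zero_in_bulk <- function(pmf, bulk = c(3.2, 3.7)) {
  sel <- which(abs(pmf$bin_centers) >= bulk[1] &
                 abs(pmf$bin_centers) <= bulk[2] &
                 is.finite(pmf$free_energy))
  if (!length(sel)) stop("no occupied bins in the bulk interval")
  pmf$free_energy <- pmf$free_energy - mean(pmf$free_energy[sel])
  pmf$zero_reference <- sprintf("mean over |z| in [%.2f, %.2f] nm",
                                bulk[1], bulk[2])
  pmf
}

#' Symmetrize two leaflet PMFs
#'
#' Averages the profile obtained from pulling through the upper leaflet
#' with the reflection (z to -z) of the lower-leaflet profile. Errors are
#' combined in quadrature; bins occupied in only one profile take that
#' profile's value.
#'
#' @param pmf_upper,pmf_lower [pmf_profile()]s on matching bins after
#'   reflecting the lower profile through z = 0 (profiles already on a
#'   common |z| grid are used as is).
#' @return A [pmf_profile()].
#' @export
symmetrize <- function(pmf_upper, pmf_lower) {
  tol <- 1e-9 + 1e-6 * diff(range(pmf_upper$bin_centers))
  refl <- list(bin_centers = rev(-pmf_lower$bin_centers),
               free_energy = rev(pmf_lower$free_energy),
               error = rev(pmf_lower$error))
  low <- if (length(refl$bin_centers) == length(pmf_upper$bin_centers) &&
             max(abs(refl$bin_centers - pmf_upper$bin_centers)) < tol) {
    refl
  } else if (length(pmf_lower$bin_centers) ==
               length(pmf_upper$bin_centers) &&
             max(abs(pmf_lower$bin_centers -
                       pmf_upper$bin_centers)) < tol) {
    pmf_lower
  } else stop("incompatible bins between leaflet profiles")
  f1 <- pmf_upper$free_energy
  f2 <- low$free_energy
  fm <- rowMeans(cbind(f1, f2), na.rm = TRUE)
  fm[is.nan(fm)] <- NA_real_
  e1 <- pmf_upper$error
  e2 <- low$error
  em <- sqrt(ifelse(is.na(e1), 0, e1^2) + ifelse(is.na(e2), 0, e2^2)) / 2
  em[is.na(e1) & is.na(e2)] <- NA_real_
  pmf_profile(pmf_upper$bin_centers, fm, em, kT = pmf_upper$kT,
              zero_reference = pmf_upper$zero_reference)
}

#' Extract PMF features
#'
#' Reports local minima deeper than `min_depth` (with their depths and
#' locations), the central barrier (free energy at the bin containing
#' z = 0) and the interfacial well (deepest minimum with |z| between 1.0
#' and 2.8 nm, the ester/head-group band). The profile should be
#' bulk-zeroed first so depths are water-referenced.
#'
#' @param pmf A bulk-zeroed [pmf_profile()].
#' @param min_depth Report minima below this free energy, kJ/mol.
#' @return List with `minima` (data frame `z`, `depth`), `barrier`
#'   (kJ/mol at z = 0, NA if uncovered), `interfacial_well` (one-row data
#'   frame or NULL).
#' @export
extract_features <- function(pmf, min_depth = -0.5) {
  z <- pmf$bin_centers
  F <- pmf$free_energy
  occ <- which(is.finite(F))
  minima <- data.frame(z = numeric(), depth = numeric())
  if (length(occ) >= 3L) {
    interior <- occ[occ > min(occ) & occ < max(occ)]
    for (i in interior) {
      if (is.finite(F[i - 1]) && is.finite(F[i + 1]) &&
          F[i] <= F[i - 1] && F[i] <= F[i + 1] && F[i] < min_depth &&
          (F[i] < F[i - 1] || F[i] < F[i + 1]))
        minima <- rbind(minima, data.frame(z = z[i], depth = F[i]))
    }
  }
  bin_w <- if (length(z) > 1L) stats::median(diff(z)) else Inf
  at0 <- which(abs(z) <= bin_w / 2)
  barrier <- if (length(at0) && any(is.finite(F[at0])))
    F[at0][which.min(abs(z[at0]))] else NA_real_
  iw <- minima[abs(minima$z) >= 1.0 & abs(minima$z) <= 2.8, , drop = FALSE]
  interfacial <- if (nrow(iw)) iw[which.min(iw$depth), , drop = FALSE]
                 else NULL
  list(minima = minima, barrier = barrier, interfacial_well = interfacial)
}
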