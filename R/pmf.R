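#' Potential of mean force profile
#'
#' Free-energy curve G(z) along the bilayer normal, on a strictly
#' increasing z grid (gaps are allowed — e.g. bins dropped by WHAM).
#'
#' @param z nm grid, strictly increasing.
#' @param g free energy, kJ/mol, finite.
#' @param g_sd optional per-point uncertainty, kJ/mol, >= 0.
#' @param reference_z optional nm position where the profile is zero; if
#'   set, `g` at the nearest grid point must be 0 (within 1e-9).
#' @param temperature kelvin.
#' @return An object of class `pmf_profile`.
#' @export
pmf_profile <- function(z, g, g_sd = NULL, reference_z = NULL,
                        temperature = DEFAULT_TEMPERATURE) {
  stopifnot(is.numeric(z), is.numeric(g), length(z) == length(g),
            length(z) >= 1L)
  if (any(!is.finite(z)) || any(!is.finite(g))) {
    stop("`z` and `g` must be finite", call. = FALSE)
  }
  if (length(z) > 1L && any(diff(z) <= 0)) {
    stop("`z` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(g_sd)) {
    stopifnot(is.numeric(g_sd), length(g_sd) == length(z))
    if (any(!is.finite(g_sd)) || any(g_sd < 0)) {
      stop("`g_sd` must be finite and >= 0", call. = FALSE)
    }
  }
  stopifnot_scalar(temperature, "temperature", positive = TRUE)
  if (!is.null(reference_z)) {
    stopifnot_scalar(reference_z, "reference_z")
    i <- which.min(abs(z - reference_z))
    if (abs(g[i]) > 1e-9) {
      stop("profile claims a reference but is not zero there", call. = FALSE)
    }
  }
  structure(
    list(z = z, g = g, g_sd = g_sd, reference_z = reference_z,
         temperature = temperature),
    class = "pmf_profile"
  )
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("PMF profile: %d points, z in [%.3g, %.3g] nm, G in [%.3g, %.3g] kJ/mol\n",
              length(x$z), min(x$z), max(x$z), min(x$g), max(x$g)))
  if (!is.null(x$reference_z)) {
    cat(sprintf("  referenced to zero at z = %g nm\n", x$reference_z))
  }
  invisible(x)
}

#' Sliced partition-coefficient profile
#'
#' Water-to-membrane partition coefficients per depth slice,
#' `ln K_w->m(z)`, at a stated temperature (the slice-wise output of a
#' COSMO-RS-style membrane partitioning calculation).
#'
#' @param z nm slice centers, strictly increasing.
#' @param ln_k dimensionless log partition coefficients, finite.
#' @param temperature kelvin.
#' @return An object of class `partition_profile`.
#' @export
partition_profile <- function(z, ln_k, temperature = DEFAULT_TEMPERATURE) {
  stopifnot(is.numeric(z), is.numeric(ln_k), length(z) == length(ln_k),
            length(z) >= 1L)
  if (any(!is.finite(z)) || any(!is.finite(ln_k))) {
    stop("`z` and `ln_k` must be finite", call. = FALSE)
  }
  if (length(z) > 1L && any(diff(z) <= 0)) {
    stop("`z` must be strictly increasing", call. = FALSE)
  }
  stopifnot_scalar(temperature, "temperature", positive = TRUE)
  structure(list(z = z, ln_k = ln_k, temperature = temperature),
            class = "partition_profile")
}

#' Reference a PMF to zero at a chosen position
#'
#' Subtracts the value at the grid point nearest `z_ref` (customarily a
#' bulk-water position such as z = 4 nm) from the whole profile and records
#' the reference. Idempotent.
#'
#' @param pmf a [pmf_profile()].
#' @param z_ref nm, must lie within the grid span.
#' @return The referenced `pmf_profile`.
#' @export
set_reference <- function(pmf, z_ref) {
  stopifnot(inherits(pmf, "pmf_profile"))
  stopifnot_scalar(z_ref, "z_ref")
  if (z_ref < min(pmf$z) || z_ref > max(pmf$z)) {
    stop(sprintf("`z_ref` = %g nm lies outside the grid span [%g, %g]",
                 z_ref, min(pmf$z), max(pmf$z)), call. = FALSE)
  }
  i <- which.min(abs(pmf$z - z_ref))
  pmf_profile(z = pmf$z, g = pmf$g - pmf$g[i], g_sd = pmf$g_sd,
              reference_z = z_ref, temperature = pmf$temperature)
}

#' Mean mirror asymmetry of a PMF
#'
#' A converged permeation PMF across a symmetric bilayer should be (nearly)
#' even in z. This diagnostic returns the mean of `|G(z) - G(-z)|` over all
#' grid points whose mirror image falls inside the opposite side's span,
#' with `G(-z)` obtained by linear interpolation. Zero for perfectly
#' symmetric profiles; invariant to an additive constant.
#'
#' @param pmf a [pmf_profile()] with points on both sides of z = 0.
#' @return Mean absolute mirror difference, kJ/mol.
#' @export
asymmetry_score <- function(pmf) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (min(pmf$z) >= 0 || max(pmf$z) <= 0) {
    stop(paste("profile is one-sided (all z on one side of the midplane);",
               "skip the symmetry diagnostic"), call. = FALSE)
  }
  mirror <- -pmf$z
  ok <- mirror >= min(pmf$z) & mirror <= max(pmf$z)
  g_mirror <- stats::approx(pmf$z, pmf$g, xout = mirror[ok])$y
  mean(abs(pmf$g[ok] - g_mirror))
}

# shared precondition for the headline free energies
check_referenced <- function(pmf, bulk_cutoff = 3.0, need_bulk = TRUE) {
  if (is.null(pmf$reference_z)) {
    stop("profile must be referenced first (see set_reference())", call. = FALSE)
  }
  if (need_bulk && abs(pmf$reference_z) < bulk_cutoff) {
    stop(sprintf(
      "reference at z = %g nm is not in bulk (|z| >= %g nm required)",
      pmf$reference_z, bulk_cutoff), call. = FALSE)
  }
  invisible(pmf)
}

#' Partition free energy from a referenced PMF
#'
#' `dG_par` is the free energy of moving the molecule from bulk water to
#' its preferred depth: the PMF global minimum relative to the bulk
#' reference (zero), so it simply equals the minimum of the referenced
#' profile. More negative values mean stronger membrane partitioning.
#' If the global minimum is attained at several grid points, the one with
#' the largest |z| (closest to bulk) is reported.
#'
#' @param pmf a referenced [pmf_profile()] (reference in bulk,
#'   `|reference_z| >= bulk_cutoff`).
#' @param bulk_cutoff minimum |z| in nm for a valid bulk reference.
#' @return List with `dg_par` (kJ/mol) and `z_min` (nm).
#' @export
delta_g_par <- function(pmf, bulk_cutoff = 3.0) {
  stopifnot(inherits(pmf, "pmf_profile"))
  check_referenced(pmf, bulk_cutoff)
  g_min <- min(pmf$g)
  at_min <- which(pmf$g == g_min)
  z_min <- pmf$z[at_min[which.max(abs(pmf$z[at_min]))]]
  list(dg_par = g_min, z_min = z_min)
}

#' Translocation free energy, direct rule
#'
#' `dG_trans` is the barrier to crossing the membrane: the PMF global
#' maximum (customarily at the bilayer midplane) minus the global minimum,
#' both taken over the stored grid points. Non-negative by construction.
#'
#' @param pmf a referenced [pmf_profile()].
#' @return `dG_trans` in kJ/mol.
#' @export
delta_g_trans_direct <- function(pmf) {
  stopifnot(inherits(pmf, "pmf_profile"))
  check_referenced(pmf, need_bulk = FALSE)
  max(pmf$g) - min(pmf$g)
}

# indices of the m-th..n-th closest points to z = 0 on one side
side_points <- function(pmf, side = c("negative", "positive")) {
  side <- match.arg(side)
  idx <- if (side == "negative") which(pmf$z < 0) else which(pmf$z > 0)
  idx[order(abs(pmf$z[idx]))]
}

#' Translocation free energy by plateau linear extrapolation
#'
#' Slice-wise partition calculations flatten near the bilayer midplane
#' because they cannot represent bilayer deformation, so the direct
#' midplane value underestimates the true barrier. This estimator instead
#' linearly extrapolates the steep flank of the profile to z = 0: on each
#' side of the bilayer that has at least 5 points, the 3rd, 4th and 5th
#' closest points to z = 0 (skipping the plateau points 1-2) are fit by
#' ordinary least squares and the fitted line is evaluated at z = 0. When
#' both sides qualify the two intercepts are averaged (equal-sided
#' profiles are unchanged; asymmetric ones are treated even-handedly).
#' `dG_trans` is the intercept minus the global minimum.
#'
#' @param pmf a referenced [pmf_profile()] with >= 5 points on at least one
#'   side of z = 0.
#' @return List with `dg_trans` (kJ/mol), `intercept`, and `diagnostics`
#'   (per-side slope, intercept and the points used).
#' @export
delta_g_trans_extrapolated <- function(pmf) {
  stopifnot(inherits(pmf, "pmf_profile"))
  check_referenced(pmf, need_bulk = FALSE)
  fits <- list()
  # negative side first (documented tie-break: that side leads diagnostics)
  for (side in c("negative", "positive")) {
    idx <- side_points(pmf, side)
    if (length(idx) >= 5L) {
      use <- idx[3:5]
      fit <- stats::lm.fit(cbind(1, pmf$z[use]), pmf$g[use])
      if (any(!is.finite(fit$coefficients))) {
        stop("extrapolation fit is degenerate (non-finite coefficients)",
             call. = FALSE)
      }
      fits[[side]] <- list(intercept = fit$coefficients[[1]],
                           slope = fit$coefficients[[2]],
                           z = pmf$z[use], g = pmf$g[use])
    }
  }
  if (length(fits) == 0L) {
    stop("need >= 5 grid points on at least one side of z = 0", call. = FALSE)
  }
  intercept <- mean(vapply(fits, `[[`, numeric(1), "intercept"))
  list(dg_trans = intercept - min(pmf$g), intercept = intercept,
       diagnostics = fits)
}

#' Convert a partition profile to a PMF
#'
#' Pointwise thermodynamic identity `PMF(z) = -RT ln K_w->m(z)`: a slice
#' where the molecule favours the membrane (K > 1) sits below the bulk
#' free-energy level.
#'
#' @param profile a [partition_profile()].
#' @return A [pmf_profile()] at the same temperature.
#' @export
pmf_from_partition <- function(profile) {
  stopifnot(inherits(profile, "partition_profile"))
  rt <- rt_kj(profile$temperature)
  pmf_profile(z = profile$z, g = -rt * profile$ln_k,
              temperature = profile$temperature)
}

#' Convert a PMF to a partition profile
#'
#' Inverse of [pmf_from_partition()]: `ln K(z) = -G(z)/RT`. The round trip
#' is the identity to machine precision.
#'
#' @param pmf a [pmf_profile()].
#' @return A [partition_profile()].
#' @export
partition_from_pmf <- function(pmf) {
  stopifnot(inherits(pmf, "pmf_profile"))
  rt <- rt_kj(pmf$temperature)
  partition_profile(z = pmf$z, ln_k = -pmf$g / rt,
                    temperature = pmf$temperature)
}

#' Free-energy summary of one PMF
#'
#' Bundles the headline quantities dG_par and dG_trans with their
#' uncertainties and the method used for the barrier.
#'
#' @param dg_par,dg_trans kJ/mol; `dg_trans >= 0`.
#' @param dg_par_err,dg_trans_err kJ/mol, >= 0.
#' @param trans_method `"direct_max"` or `"extrapolated"`.
#' @param z_min nm position of the PMF minimum.
#' @return An object of class `free_energy_summary`.
#' @export
free_energy_summary <- function(dg_par, dg_trans, dg_par_err = 0,
                                dg_trans_err = 0,
                                trans_method = c("direct_max", "extrapolated"),
                                z_min = NA_real_) {
  stopifnot_scalar(dg_par, "dg_par")
  stopifnot_scalar(dg_trans, "dg_trans", nonneg = TRUE)
  stopifnot_scalar(dg_par_err, "dg_par_err", nonneg = TRUE)
  stopifnot_scalar(dg_trans_err, "dg_trans_err", nonneg = TRUE)
  trans_method <- match.arg(trans_method)
  structure(
    list(dg_par = dg_par, dg_trans = dg_trans, dg_par_err = dg_par_err,
         dg_trans_err = dg_trans_err, trans_method = trans_method,
         z_min = z_min),
    class = "free_energy_summary"
  )
}

#' @export
print.free_energy_summary <- function(x, ...) {
  cat(sprintf("dG_par   = %8.3f +/- %.3f kJ/mol (minimum at z = %g nm)\n",
              x$dg_par, x$dg_par_err, x$z_min))
  cat(sprintf("dG_trans = %8.3f +/- %.3f kJ/mol (%s)\n",
              x$dg_trans, x$dg_trans_err, x$trans_method))
  invisible(x)
}

#' Summarise a referenced PMF into its headline free energies
#'
#' Convenience wrapper applying [delta_g_par()] and either
#' [delta_g_trans_direct()] or [delta_g_trans_extrapolated()].
#'
#' @param pmf a referenced [pmf_profile()].
#' @param trans_method `"direct_max"` (default) or `"extrapolated"`.
#' @param bulk_cutoff passed to [delta_g_par()].
#' @return A [free_energy_summary()].
#' @export
summarize_pmf <- function(pmf, trans_method = c("direct_max", "extrapolated"),
                          bulk_cutoff = 3.0) {
  trans_method <- match.arg(trans_method)
  par <- delta_g_par(pmf, bulk_cutoff = bulk_cutoff)
  dgt <- if (trans_method == "direct_max") delta_g_trans_direct(pmf)
         else delta_g_trans_extrapolated(pmf)$dg_trans
  err <- if (!is.null(pmf$g_sd)) {
    # propagate the per-bin spread at the minimum / extrema
    i_min <- which.min(pmf$g); i_max <- which.max(pmf$g)
    c(pmf$g_sd[i_min], sqrt(pmf$g_sd[i_min]^2 + pmf$g_sd[i_max]^2))
  } else c(0, 0)
  free_energy_summary(dg_par = par$dg_par, dg_trans = max(0, dgt),
                      dg_par_err = err[1], dg_trans_err = err[2],
                      trans_method = trans_method, z_min = par$z_min)
}

#' Combine replicate free-energy summaries
#'
#' Per-quantity mean and standard error (sample sd over sqrt(n)) across
#' independent replicate calculations. All replicates must use the same
#' barrier method — a direct and an extrapolated estimate are not
#' comparable.
#'
#' @param summaries list of >= 2 [free_energy_summary()] objects.
#' @return A [free_energy_summary()] holding means and standard errors.
#' @export
combine_replicates <- function(summaries) {
  stopifnot(is.list(summaries))
  if (length(summaries) < 2L) {
    stop("need >= 2 replicate summaries", call. = FALSE)
  }
  for (s in summaries) stopifnot(inherits(s, "free_energy_summary"))
  methods <- unique(vapply(summaries, `[[`, character(1), "trans_method"))
  if (length(methods) != 1L) {
    stop(sprintf("mixed trans_method values (%s) are not comparable",
                 paste(methods, collapse = ", ")), call. = FALSE)
  }
  n <- length(summaries)
  se <- function(x) stats::sd(x) / sqrt(n)
  par_v <- vapply(summaries, `[[`, numeric(1), "dg_par")
  trans_v <- vapply(summaries, `[[`, numeric(1), "dg_trans")
  zmin_v <- vapply(summaries, `[[`, numeric(1), "z_min")
  free_energy_summary(
    dg_par = mean(par_v), dg_trans = mean(trans_v),
    dg_par_err = se(par_v), dg_trans_err = se(trans_v),
    trans_method = methods, z_min = mean(zmin_v)
  )
}
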