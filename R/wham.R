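#' Biased umbrella-sampling ensemble
#'
#' Container for per-window reaction-coordinate samples with their harmonic
#' bias parameters, all sharing one temperature.
#'
#' @param windows list of windows, each a list with fields `center` (nm),
#'   `force_constant` (kJ mol^-1 nm^-2) and `samples` (numeric, nm, nonempty).
#' @param temperature kelvin (> 0).
#' @param equilibration_fraction fraction of each window's samples treated
#'   as equilibration by block analyses (in [0, 1)).
#' @return An object of class `biased_ensemble`.
#' @export
biased_ensemble <- function(windows, temperature = DEFAULT_TEMPERATURE,
                            equilibration_fraction = 0) {
  if (!is.list(windows) || length(windows) == 0L) {
    stop("`windows` must be a nonempty list", call. = FALSE)
  }
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (!is.list(w) || !all(c("center", "force_constant", "samples") %in% names(w))) {
      stop(sprintf("window %d must have fields center, force_constant, samples", i),
           call. = FALSE)
    }
    stopifnot_scalar(w$center, sprintf("windows[[%d]]$center", i))
    stopifnot_scalar(w$force_constant, sprintf("windows[[%d]]$force_constant", i),
                     nonneg = TRUE)
    if (!is.numeric(w$samples) || length(w$samples) == 0L ||
        any(!is.finite(w$samples))) {
      stop(sprintf("window %d has empty or non-finite samples", i), call. = FALSE)
    }
  }
  stopifnot_scalar(temperature, "temperature", positive = TRUE)
  stopifnot_scalar(equilibration_fraction, "equilibration_fraction", nonneg = TRUE)
  if (equilibration_fraction >= 1) {
    stop("`equilibration_fraction` must be < 1", call. = FALSE)
  }
  structure(
    list(windows = windows, temperature = temperature,
         equilibration_fraction = equilibration_fraction),
    class = "biased_ensemble"
  )
}

#' @export
print.biased_ensemble <- function(x, ...) {
  ns <- vapply(x$windows, function(w) length(w$samples), integer(1))
  cat(sprintf("Biased ensemble: %d windows, %d-%d samples each, T = %g K\n",
              length(x$windows), min(ns), max(ns), x$temperature))
  invisible(x)
}

#' Histogram umbrella windows on a shared grid
#'
#' Bins every window's samples on one common grid of width `bin_width`
#' covering `range` (by default the span of all samples, expanded to whole
#' bins). Samples falling outside an explicit `range` are clipped: their
#' counts are reported per window, a warning is raised above 1% clipped
#' overall and an error above 10%. Windows are canonically ordered by
#' center (ties by force constant) so downstream WHAM results do not depend
#' on the order windows were supplied in.
#'
#' @param ensemble a [biased_ensemble()].
#' @param bin_width bin width in nm (> 0); the default 0.05 nm is half the
#'   customary 0.1 nm window spacing.
#' @param range optional length-2 numeric histogram range in nm.
#' @return Object of class `wham_histograms`: `bin_centers`, `counts`
#'   (windows x bins matrix), `centers`, `force_constants`, `n_samples`,
#'   `clipped` (per window), `temperature`.
#' @export
histogram_windows <- function(ensemble, bin_width = 0.05, range = NULL) {
  stopifnot(inherits(ensemble, "biased_ensemble"))
  stopifnot_scalar(bin_width, "bin_width", positive = TRUE)
  ord <- order(vapply(ensemble$windows, `[[`, numeric(1), "center"),
               vapply(ensemble$windows, `[[`, numeric(1), "force_constant"))
  windows <- ensemble$windows[ord]
  all_z <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(range)) {
    lo <- floor(min(all_z) / bin_width) * bin_width
    hi <- ceiling(max(all_z) / bin_width) * bin_width
  } else {
    stopifnot(is.numeric(range), length(range) == 2L, range[1] < range[2])
    lo <- range[1]; hi <- range[2]
  }
  n_bins <- max(1L, as.integer(ceiling((hi - lo) / bin_width - 1e-9)))
  breaks <- lo + (0:n_bins) * bin_width
  bin_centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- matrix(0, nrow = length(windows), ncol = n_bins)
  clipped <- integer(length(windows))
  for (i in seq_along(windows)) {
    z <- windows[[i]]$samples
    inside <- z >= lo & z <= hi
    clipped[i] <- sum(!inside)
    idx <- pmin(n_bins, floor((z[inside] - lo) / bin_width) + 1L)
    counts[i, ] <- tabulate(idx, nbins = n_bins)
  }
  frac_clip <- sum(clipped) / length(all_z)
  if (frac_clip > 0.10) {
    stop(sprintf("%.1f%% of samples fall outside the histogram range", 100 * frac_clip),
         call. = FALSE)
  }
  if (frac_clip > 0.01) {
    warning(sprintf("%.1f%% of samples clipped by the histogram range", 100 * frac_clip),
            call. = FALSE)
  }
  structure(
    list(bin_centers = bin_centers, counts = counts,
         centers = vapply(windows, `[[`, numeric(1), "center"),
         force_constants = vapply(windows, `[[`, numeric(1), "force_constant"),
         n_samples = vapply(windows, function(w) length(w$samples), integer(1)),
         clipped = clipped, bin_width = bin_width,
         temperature = ensemble$temperature),
    class = "wham_histograms"
  )
}

# Harmonic bias energies u_i(z_b) in kJ/mol, windows x bins.
harmonic_bias_matrix <- function(histograms) {
  outer(seq_along(histograms$centers), seq_along(histograms$bin_centers),
        function(i, b) {
          0.5 * histograms$force_constants[i] *
            (histograms$bin_centers[b] - histograms$centers[i])^2
        })
}

# Connected components of the window-overlap graph: windows are linked when
# they both have counts in some bin. Used to diagnose disconnected islands.
window_components <- function(counts) {
  n <- nrow(counts)
  occ <- counts > 0
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      i <- queue[[1]]; queue <- queue[-1]
      shared <- which(comp == 0L &
                        (occ %*% occ[i, ])[, 1] > 0)
      comp[shared] <- cur
      queue <- c(queue, shared)
    }
  }
  comp
}

#' Solve the WHAM self-consistent equations
#'
#' Iterates the standard one-dimensional WHAM fixed point for the unbiased
#' density rho and the per-window free-energy shifts f_i:
#' \deqn{\rho_b = \frac{\sum_i n_{ib}}{\sum_i N_i e^{(f_i - u_i(z_b))/RT}},
#'   \qquad f_i = -RT \ln \sum_b \rho_b \, e^{-u_i(z_b)/RT},}
#' until the spread (max minus min) of the per-window changes in f_i
#' between successive iterations falls below `tolerance`. The spread is
#' gauge-invariant and non-increasing for this positive scaling iteration
#' (the update is Sinkhorn-like, a contraction in the Hilbert projective
#' metric), and it bounds the anchored per-window change from above. The
#' gauge is fixed by holding `f_1 = 0` during the iteration; the returned
#' PMF is `-RT ln rho` up to an additive constant
#' (referencing is a separate step, see [set_reference()]). Bins with zero
#' total count carry no information and are excluded (`NA` in `pmf_values`).
#'
#' @param histograms a `wham_histograms` from [histogram_windows()].
#' @param temperature kelvin; defaults to the ensemble temperature.
#' @param tolerance convergence threshold on max |delta f_i|, kJ/mol (> 0).
#' @param max_iter iteration cap; exceeding it returns `converged = FALSE`.
#' @param bias optional windows x bins matrix of bias energies u_i(z_b) in
#'   kJ/mol, overriding the harmonic biases implied by the histogram metadata
#'   (used e.g. to verify gauge invariance).
#' @return Object of class `wham_solution`: `bin_centers`, `pmf_values`
#'   (kJ/mol, `NA` on empty bins), `density`, `window_free_energies`,
#'   `n_iterations`, `converged`, `max_residual`, `residual_trace`,
#'   `total_counts`, `temperature`.
#' @references Kumar, S. et al. The weighted histogram analysis method for
#'   free-energy calculations on biomolecules. J. Comput. Chem. 13,
#'   1011-1021 (1992).
#' @export
solve_wham <- function(histograms, temperature = NULL, tolerance = 1e-7,
                       max_iter = 1e5, bias = NULL) {
  stopifnot(inherits(histograms, "wham_histograms"))
  if (is.null(temperature)) temperature <- histograms$temperature
  stopifnot_scalar(tolerance, "tolerance", positive = TRUE)
  stopifnot_scalar(max_iter, "max_iter", positive = TRUE)
  rt <- rt_kj(temperature)
  counts <- histograms$counts
  n_win <- nrow(counts)
  if (is.null(bias)) {
    bias <- harmonic_bias_matrix(histograms)
  } else {
    stopifnot(is.matrix(bias), all(dim(bias) == dim(counts)))
  }
  comp <- window_components(counts)
  if (max(comp) > 1L) {
    groups <- split(seq_len(n_win), comp)
    stop(sprintf(
      "windows form %d disconnected groups with no shared occupied bins: %s",
      length(groups),
      paste(vapply(groups, function(g) paste0("{", paste(g, collapse = ","), "}"),
                   character(1)), collapse = " ")), call. = FALSE)
  }
  n_i <- histograms$n_samples - histograms$clipped
  total_b <- colSums(counts)
  occupied <- total_b > 0
  # Boltzmann factors of the biases; zero where the bias is astronomically
  # large, which correctly removes that window's weight from the bin
  boltz <- exp(-bias / rt)            # windows x bins
  f <- numeric(n_win)
  resid <- Inf
  trace <- numeric(0)
  iter <- 0L
  rho <- rep(0, ncol(counts))
  while (iter < max_iter && resid > tolerance) {
    iter <- iter + 1L
    a_i <- exp(f / rt)                       # e^{f_i/RT}
    denom <- colSums((n_i * a_i) * boltz)    # sum_i N_i e^{(f_i - u_ib)/RT}
    rho <- ifelse(occupied & denom > 0, total_b / denom, 0)
    zsum <- as.vector(boltz %*% rho)         # sum_b rho_b e^{-u_ib/RT}
    f_new <- -rt * log(zsum)
    df <- f_new - f
    resid <- max(df) - min(df)               # gauge-invariant spread
    trace <- c(trace, resid)
    f <- f_new - f_new[1]                    # gauge: f_1 = 0
  }
  pmf <- rep(NA_real_, ncol(counts))
  pmf[occupied] <- -rt * log(rho[occupied])
  structure(
    list(bin_centers = histograms$bin_centers, pmf_values = pmf,
         density = rho, window_free_energies = f,
         n_iterations = iter, converged = resid <= tolerance,
         max_residual = resid, residual_trace = trace,
         total_counts = total_b, temperature = temperature),
    class = "wham_solution"
  )
}

#' @export
print.wham_solution <- function(x, ...) {
  cat(sprintf(
    "WHAM solution: %d bins (%d occupied), %d windows, %s in %d iterations (max residual %.3g kJ/mol)\n",
    length(x$bin_centers), sum(!is.na(x$pmf_values)),
    length(x$window_free_energies),
    if (x$converged) "converged" else "NOT converged",
    x$n_iterations, x$max_residual))
  invisible(x)
}

#' Extract the PMF from a WHAM solution as a profile object
#'
#' Drops empty bins and optionally references the profile.
#'
#' @param solution a `wham_solution`.
#' @param reference_z optional nm position passed to [set_reference()].
#' @return A [pmf_profile()].
#' @export
wham_pmf <- function(solution, reference_z = NULL) {
  stopifnot(inherits(solution, "wham_solution"))
  keep <- !is.na(solution$pmf_values)
  prof <- pmf_profile(z = solution$bin_centers[keep],
                      g = solution$pmf_values[keep],
                      temperature = solution$temperature)
  if (!is.null(reference_z)) prof <- set_reference(prof, reference_z)
  prof
}

# Post-equilibration samples of one window under the documented rule:
# drop floor(frac * n) leading samples.
post_equilibration <- function(samples, frac) {
  n_drop <- floor(frac * length(samples) + 1e-9)
  if (n_drop >= length(samples)) {
    stop("equilibration fraction leaves no samples", call. = FALSE)
  }
  samples[(n_drop + 1):length(samples)]
}

#' Two-block PMF estimate with per-bin spread
#'
#' Splits every window's post-equilibration samples into two equal
#' contiguous blocks, runs WHAM independently on each block, references
#' both PMFs at the same position, and returns the per-bin mean and
#' standard deviation of the two block PMFs. This is the block-splitting
#' error protocol commonly applied to umbrella-sampling data (two
#' independent halves of the production trajectory). Windows with an odd
#' post-equilibration count drop their first sample so the blocks are
#' exactly equal — never silently unequal.
#'
#' @param ensemble a [biased_ensemble()]; every window needs >= 2
#'   post-equilibration samples.
#' @param bin_width,range,tolerance,max_iter passed to
#'   [histogram_windows()] / [solve_wham()].
#' @param reference_z nm position for common referencing; defaults to the
#'   sampled grid point farthest from the bilayer midplane.
#' @param equilibration_fraction overrides the ensemble's fraction.
#' @return List with `mean` and `sd` ([pmf_profile()] objects on the common
#'   occupied grid; the mean profile carries the sd in its `g_sd` field),
#'   plus the two `blocks` solutions.
#' @export
two_block_pmfs <- function(ensemble, bin_width = 0.05, range = NULL,
                           tolerance = 1e-7, max_iter = 1e5,
                           reference_z = NULL,
                           equilibration_fraction = NULL) {
  stopifnot(inherits(ensemble, "biased_ensemble"))
  frac <- if (is.null(equilibration_fraction)) ensemble$equilibration_fraction
          else equilibration_fraction
  halves <- lapply(1:2, function(h) {
    windows <- lapply(ensemble$windows, function(w) {
      z <- post_equilibration(w$samples, frac)
      if (length(z) < 2L) {
        stop("every window needs >= 2 post-equilibration samples", call. = FALSE)
      }
      if (length(z) %% 2L == 1L) z <- z[-1]   # drop first: equal blocks
      m <- length(z) / 2L
      block <- if (h == 1L) z[1:m] else z[(m + 1):(2 * m)]
      list(center = w$center, force_constant = w$force_constant,
           samples = block)
    })
    biased_ensemble(windows, temperature = ensemble$temperature)
  })
  if (is.null(range)) {
    all_z <- unlist(lapply(ensemble$windows, `[[`, "samples"))
    range <- c(floor(min(all_z) / bin_width) * bin_width,
               ceiling(max(all_z) / bin_width) * bin_width)
  }
  sols <- lapply(halves, function(ens) {
    solve_wham(histogram_windows(ens, bin_width = bin_width, range = range),
               tolerance = tolerance, max_iter = max_iter)
  })
  keep <- !is.na(sols[[1]]$pmf_values) & !is.na(sols[[2]]$pmf_values)
  if (!any(keep)) {
    stop("the two blocks share no occupied bins; cannot form a common PMF",
         call. = FALSE)
  }
  z <- sols[[1]]$bin_centers[keep]
  if (is.null(reference_z)) reference_z <- z[which.max(abs(z))]
  profs <- lapply(sols, function(s) {
    set_reference(
      pmf_profile(z = z, g = s$pmf_values[keep], temperature = s$temperature),
      reference_z)
  })
  g1 <- profs[[1]]$g; g2 <- profs[[2]]$g
  g_mean <- (g1 + g2) / 2
  g_sd <- abs(g1 - g2) / sqrt(2)  # sd of two observations
  list(
    mean = pmf_profile(z = z, g = g_mean, g_sd = g_sd,
                       reference_z = reference_z,
                       temperature = ensemble$temperature),
    sd = pmf_profile(z = z, g = g_sd, temperature = ensemble$temperature),
    blocks = sols
  )
}
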