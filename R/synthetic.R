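#' Construct a model bilayer free-energy landscape
#'
#' Builds a smooth, even, analytically evaluable one-dimensional potential
#' emulating the permeation free-energy profile of an amphiphile across a
#' symmetric bilayer: two equal interfacial minima at `+/- well_position`,
#' a central barrier at the midplane `z = 0`, and a bulk-water level fixed at
#' exactly zero far from the membrane. The functional form is a sum of three
#' Gaussians,
#' \deqn{U(z) = -d e^{-((z-p)/w)^2} - d e^{-((z+p)/w)^2} + b e^{-(z/w_b)^2},}
#' with depth `d`, well position `p`, well width `w`, barrier height `b` and
#' barrier width `w_b`. With the default widths the cross-terms at the well
#' are below 0.1 kJ/mol, so the evaluated minimum is `-well_depth` to within
#' 2% and the midplane value is `barrier_height` to the same accuracy.
#'
#' @param well_depth depth of the interfacial minimum in kJ/mol (> 0).
#' @param well_position |z| of the minima in nm (default 1.2).
#' @param well_width Gaussian width of the wells in nm (> 0).
#' @param barrier_height midplane barrier relative to bulk, kJ/mol (> 0).
#' @param barrier_width Gaussian width of the barrier in nm (> 0).
#' @return An object of class `model_potential`: callable via
#'   [eval_potential()], with the parameters stored as fields.
#' @seealso [sample_window()], [generate_umbrella_dataset()]
#' @examples
#' pot <- make_model_pmf(10, 1.2, 0.3, 25, 0.5)
#' eval_potential(pot, c(-4, -1.2, 0, 1.2, 4))
#' @export
make_model_pmf <- function(well_depth = 10, well_position = 1.2,
                           well_width = 0.3, barrier_height = 25,
                           barrier_width = 0.5) {
  stopifnot_scalar(well_depth, "well_depth", positive = TRUE)
  stopifnot_scalar(well_position, "well_position", nonneg = TRUE)
  stopifnot_scalar(well_width, "well_width", positive = TRUE)
  stopifnot_scalar(barrier_height, "barrier_height", positive = TRUE)
  stopifnot_scalar(barrier_width, "barrier_width", positive = TRUE)
  structure(
    list(well_depth = well_depth, well_position = well_position,
         well_width = well_width, barrier_height = barrier_height,
         barrier_width = barrier_width, bulk_level = 0),
    class = "model_potential"
  )
}

#' Evaluate a model potential
#'
#' @param potential a `model_potential` from [make_model_pmf()].
#' @param z numeric vector of positions in nm.
#' @return Potential values in kJ/mol (bulk level 0).
#' @export
eval_potential <- function(potential, z) {
  stopifnot(inherits(potential, "model_potential"), is.numeric(z))
  p <- potential
  -p$well_depth * exp(-((z - p$well_position) / p$well_width)^2) -
    p$well_depth * exp(-((z + p$well_position) / p$well_width)^2) +
    p$barrier_height * exp(-(z / p$barrier_width)^2)
}

#' @export
print.model_potential <- function(x, ...) {
  cat(sprintf(
    "Model bilayer potential: wells %.3g kJ/mol at z = +/-%.3g nm (width %.3g),\n",
    -x$well_depth, x$well_position, x$well_width))
  cat(sprintf("  midplane barrier %.3g kJ/mol (width %.3g), bulk level 0\n",
              x$barrier_height, x$barrier_width))
  invisible(x)
}

# Flat (zero) potential helper used in tests of the harmonic limit.
flat_potential <- function() {
  structure(
    list(well_depth = 1e-300, well_position = 1.2, well_width = 0.3,
         barrier_height = 1e-300, barrier_width = 0.5, bulk_level = 0),
    class = "model_potential"
  )
}

#' Sample a biased umbrella window by Metropolis Monte Carlo
#'
#' Draws positions from the Boltzmann distribution of
#' `U(z) + k/2 (z - center)^2` at the given temperature using a
#' single-particle Metropolis chain (Gaussian proposals, sd `proposal_sd`).
#' The chain starts at the window center, runs `burn_in` unrecorded steps,
#' then records `n` positions, advancing `stride` Metropolis steps between
#' recordings to thin the random-walk autocorrelation (rejected moves
#' repeat the current position, as required for detailed balance).
#'
#' @param potential a `model_potential`.
#' @param center harmonic restraint center in nm.
#' @param force_constant harmonic force constant in kJ mol^-1 nm^-2 (> 0).
#' @param n number of recorded samples (> 0).
#' @param temperature kelvin (> 0).
#' @param seed integer RNG seed; identical arguments give identical samples.
#' @param proposal_sd Metropolis proposal standard deviation in nm.
#' @param burn_in unrecorded equilibration steps before sampling.
#' @param stride Metropolis steps advanced per recorded sample (>= 1);
#'   thinning decorrelates successive recorded positions.
#' @param support optional length-2 numeric: proposals outside this interval
#'   are rejected, confining the chain (the stationary density becomes the
#'   Boltzmann density truncated to the interval).
#' @return Numeric vector of `n` positions in nm.
#' @examples
#' pot <- make_model_pmf()
#' z <- sample_window(pot, center = -1.2, force_constant = 500, n = 1000,
#'                    temperature = 310.15, seed = 1)
#' @export
sample_window <- function(potential, center, force_constant, n,
                          temperature = DEFAULT_TEMPERATURE, seed,
                          proposal_sd = 0.05, burn_in = 1000L,
                          stride = 10L, support = NULL) {
  stopifnot(inherits(potential, "model_potential"))
  stopifnot_scalar(center, "center")
  stopifnot_scalar(force_constant, "force_constant", nonneg = TRUE)
  stopifnot_scalar(n, "n", positive = TRUE)
  stopifnot_scalar(temperature, "temperature", positive = TRUE)
  stopifnot_scalar(proposal_sd, "proposal_sd", positive = TRUE)
  n <- as.integer(n)
  burn_in <- as.integer(burn_in)
  stopifnot_scalar(stride, "stride", positive = TRUE)
  stride <- as.integer(stride)
  if (!is.null(support)) {
    stopifnot(is.numeric(support), length(support) == 2L, support[1] < support[2])
  }
  beta <- 1 / rt_kj(temperature)
  d <- potential$well_depth; p <- potential$well_position
  w <- potential$well_width; b <- potential$barrier_height
  wb <- potential$barrier_width
  k <- force_constant; z0 <- center
  energy <- function(z) {
    -d * exp(-((z - p) / w)^2) - d * exp(-((z + p) / w)^2) +
      b * exp(-(z / wb)^2) + 0.5 * k * (z - z0)^2
  }
  with_seed(seed, {
    total <- burn_in + n * stride
    dz <- rnorm(total, sd = proposal_sd)
    logu <- log(runif(total))
    out <- numeric(n)
    z <- z0
    e <- energy(z)
    for (i in seq_len(total)) {
      zp <- z + dz[i]
      if (is.null(support) || (zp >= support[1] && zp <= support[2])) {
        ep <- energy(zp)
        if (logu[i] < -beta * (ep - e)) {
          z <- zp
          e <- ep
        }
      }
      if (i > burn_in && (i - burn_in) %% stride == 0L) {
        out[(i - burn_in) %/% stride] <- z
      }
    }
    out
  })
}

#' Umbrella-sampling window layout
#'
#' Describes a ladder of harmonic windows along the bilayer normal z:
#' centers at `z_start + i * spacing` up to `z_stop` inclusive, one force
#' constant per window (a scalar is recycled). The default spacing of
#' 0.1 nm and force constants in the 200-1500 kJ mol^-1 nm^-2 range are
#' typical of atomistic membrane permeation studies; the default
#' `equilibration_fraction` of 5/32 mirrors discarding a 5 ns equilibration
#' period out of a 32 ns window trajectory.
#'
#' @param z_start,z_stop first and last window centers, nm (`z_start < z_stop`).
#' @param spacing window spacing in nm (> 0, default 0.1).
#' @param force_constants force constant(s), kJ mol^-1 nm^-2, scalar or one
#'   per window.
#' @param samples_per_window recorded samples per window (> 0).
#' @param equilibration_fraction fraction of each window's samples discarded
#'   as equilibration before block analysis (in [0, 1)).
#' @return An object of class `umbrella_layout` with a `centers` field.
#' @examples
#' umbrella_layout(-4, 1.2)$centers  # 53 windows
#' @export
umbrella_layout <- function(z_start, z_stop, spacing = 0.1,
                            force_constants = 500,
                            samples_per_window = 5000,
                            equilibration_fraction = 5 / 32) {
  stopifnot_scalar(z_start, "z_start")
  stopifnot_scalar(z_stop, "z_stop")
  stopifnot_scalar(spacing, "spacing", positive = TRUE)
  if (z_start >= z_stop) stop("`z_start` must be < `z_stop`", call. = FALSE)
  stopifnot_scalar(samples_per_window, "samples_per_window", positive = TRUE)
  stopifnot_scalar(equilibration_fraction, "equilibration_fraction",
                   nonneg = TRUE)
  if (equilibration_fraction >= 1) {
    stop("`equilibration_fraction` must be < 1", call. = FALSE)
  }
  # centers up to z_stop inclusive within half a spacing
  n_win <- floor((z_stop - z_start) / spacing + 0.5) + 1L
  centers <- z_start + (seq_len(n_win) - 1L) * spacing
  centers <- centers[centers <= z_stop + spacing / 2]
  if (!is.numeric(force_constants) || any(!is.finite(force_constants)) ||
      any(force_constants <= 0)) {
    stop("all `force_constants` must be positive and finite", call. = FALSE)
  }
  if (length(force_constants) == 1L) {
    force_constants <- rep(force_constants, length(centers))
  }
  if (length(force_constants) != length(centers)) {
    stop(sprintf("`force_constants` must have length 1 or %d (one per window)",
                 length(centers)), call. = FALSE)
  }
  structure(
    list(z_start = z_start, z_stop = z_stop, spacing = spacing,
         centers = centers, force_constants = force_constants,
         samples_per_window = as.integer(samples_per_window),
         equilibration_fraction = equilibration_fraction),
    class = "umbrella_layout"
  )
}

#' Generate a full biased umbrella-sampling dataset
#'
#' Runs one Metropolis chain per window of the layout on the given model
#' potential and collects the samples into a [biased_ensemble()]. Per-window
#' chains use seeds derived deterministically from `seed`, so the dataset is
#' reproducible and windows are statistically independent.
#'
#' @param potential a `model_potential`.
#' @param layout an `umbrella_layout`.
#' @param temperature kelvin.
#' @param seed integer seed.
#' @return A `biased_ensemble` (see [biased_ensemble()]).
#' @examples
#' pot <- make_model_pmf()
#' lay <- umbrella_layout(0, 0.2, samples_per_window = 200)
#' ens <- generate_umbrella_dataset(pot, lay, seed = 1)
#' length(ens$windows)  # 3
#' @export
generate_umbrella_dataset <- function(potential, layout,
                                      temperature = DEFAULT_TEMPERATURE,
                                      seed) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(layout, "umbrella_layout"))
  if (length(layout$centers) == 0L) {
    stop("umbrella layout has no windows", call. = FALSE)
  }
  windows <- vector("list", length(layout$centers))
  for (i in seq_along(layout$centers)) {
    windows[[i]] <- list(
      center = layout$centers[i],
      force_constant = layout$force_constants[i],
      samples = sample_window(
        potential, layout$centers[i], layout$force_constants[i],
        n = layout$samples_per_window, temperature = temperature,
        seed = (as.numeric(seed) * 1000) %% 2147483647 + i
      )
    )
  }
  biased_ensemble(windows, temperature = temperature,
                  equilibration_fraction = layout$equilibration_fraction)
}

#' Generate a sliced water-membrane partition-coefficient profile
#'
#' Emulates the output of slice-wise partition-coefficient calculations
#' (COSMO-RS-style membrane slicing): `n_slices` slice centers spanning the
#' membrane, each carrying `ln K_w->m(z) = -PMF(z)/RT`. Such calculations
#' cannot resolve the bilayer-deformation barrier at the midplane, so the
#' underlying PMF is flattened to its value at `|z| = plateau_halfwidth`
#' for all `|z| < plateau_halfwidth`, reproducing the characteristic
#' midplane plateau. Independent Gaussian noise of sd `noise_sd` (in energy
#' units, i.e. `noise_sd / RT` on the ln K scale) is added per slice.
#'
#' @param potential a `model_potential` providing the true PMF.
#' @param n_slices number of slices (>= 5); the default 20 gives ~0.2 nm
#'   spacing over a typical bilayer span.
#' @param temperature kelvin.
#' @param noise_sd per-slice noise, kJ/mol (>= 0).
#' @param plateau_halfwidth nm; 0 disables the plateau.
#' @param z_span half-width of the sliced region in nm (slices span
#'   `[-z_span, z_span]`).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return A [partition_profile()] object.
#' @examples
#' pp <- generate_partition_profile(make_model_pmf(), n_slices = 20,
#'                                  noise_sd = 0, plateau_halfwidth = 0.4,
#'                                  seed = 1)
#' @export
generate_partition_profile <- function(potential, n_slices = 20,
                                       temperature = DEFAULT_TEMPERATURE,
                                       noise_sd = 0, plateau_halfwidth = 0.4,
                                       z_span = 2.0, seed = 1) {
  stopifnot(inherits(potential, "model_potential"))
  stopifnot_scalar(n_slices, "n_slices", positive = TRUE)
  if (n_slices < 5) stop("`n_slices` must be >= 5", call. = FALSE)
  stopifnot_scalar(temperature, "temperature", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(plateau_halfwidth, "plateau_halfwidth", nonneg = TRUE)
  stopifnot_scalar(z_span, "z_span", positive = TRUE)
  z <- seq(-z_span, z_span, length.out = as.integer(n_slices))
  g <- eval_potential(potential, z)
  if (plateau_halfwidth > 0) {
    g_plateau <- eval_potential(potential, plateau_halfwidth)
    g[abs(z) < plateau_halfwidth] <- g_plateau
  }
  rt <- rt_kj(temperature)
  ln_k <- -g / rt
  if (noise_sd > 0) {
    ln_k <- ln_k + with_seed(seed, rnorm(length(z), sd = noise_sd / rt))
  }
  partition_profile(z = z, ln_k = ln_k, temperature = temperature)
}

#' Generate a synthetic screening panel of quorum-sensing modulators
#'
#' Builds a panel of molecules spanning the four screening categories (AHL,
#' AHT, oxo-C12 derivatives, miscellaneous) together with matched potency
#' records, under a known ground-truth model:
#' \deqn{\Delta G_{par} = a + s \cdot n_{tail} + o \cdot [3oxo] + \epsilon,}
#' with tail slope `s < 0` (longer acyl tails partition more favourably),
#' a positive 3-oxo head-group offset `o` (the polar ketone weakens
#' partitioning by ~5 kJ/mol), and Gaussian noise.  Translocation barriers
#' are generated as a positive-intercept linear function of dG_par so the
#' two free energies are moderately positively correlated.  Every molecule
#' appears in both bilayers (DOPC and POPE/POPG) with only noise-level
#' differences.  Potency follows the hinge rule
#' \deqn{\log_{10} C = a_c + b_c \max(0, \Delta G_{par} - t) + \epsilon_c,}
#' so molecules partitioning more weakly than the threshold `t` need higher
#' concentrations (larger EC50/IC50) to modulate quorum sensing.
#'
#' @param n_per_category molecules per category (>= 1).
#' @param tail_slope kJ/mol per tail carbon (< 0).
#' @param oxo_offset kJ/mol added to dG_par by a 3-oxo group (>= 0).
#' @param potency_threshold hinge location for the potency rule, kJ/mol.
#' @param noise_sd sd of the dG_par noise, kJ/mol (>= 0).
#' @param seed integer seed.
#' @param intercept dG_par at zero tail carbons, kJ/mol.
#' @param activity_slope hinge slope `b_c` in log10(uM) per kJ/mol (>= 0);
#'   set 0 to disable the partitioning-potency link.
#' @param activity_intercept baseline log10 concentration (log10 uM).
#' @param activity_noise_sd sd of the potency noise on the log10 scale.
#' @return A list with elements `panel` (a [screening_panel()]) and
#'   `activity` (a data.frame of activity records; see [activity_records()]).
#' @examples
#' gp <- generate_screening_panel(n_per_category = 5, noise_sd = 0, seed = 1)
#' head(gp$panel)
#' @export
generate_screening_panel <- function(n_per_category = 10, tail_slope = -1.5,
                                     oxo_offset = 5, potency_threshold = -10,
                                     noise_sd = 1, seed,
                                     intercept = 3,
                                     activity_slope = 0.2,
                                     activity_intercept = 0.5,
                                     activity_noise_sd = 0.3) {
  stopifnot_scalar(n_per_category, "n_per_category", positive = TRUE)
  if (n_per_category < 1) stop("`n_per_category` must be >= 1", call. = FALSE)
  stopifnot_scalar(tail_slope, "tail_slope")
  if (tail_slope >= 0) {
    stop("`tail_slope` must be < 0: longer tails must partition more strongly",
         call. = FALSE)
  }
  stopifnot_scalar(oxo_offset, "oxo_offset", nonneg = TRUE)
  stopifnot_scalar(potency_threshold, "potency_threshold")
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(activity_slope, "activity_slope", nonneg = TRUE)
  n_per_category <- as.integer(n_per_category)

  categories <- c("AHL", "AHT", "oxoC12_derivative", "misc")
  tail_pool <- c(4L, 6L, 8L, 10L, 12L, 14L, 16L)
  mols <- do.call(rbind, lapply(categories, function(cat) {
    idx <- seq_len(n_per_category)
    # alternate the 3-oxo flag along repeated tail lengths so matched
    # (tail, category) pairs differing only in the head group exist
    tails <- tail_pool[((idx - 1L) %/% 2L) %% length(tail_pool) + 1L]
    oxo <- if (cat == "oxoC12_derivative") rep(TRUE, n_per_category) else idx %% 2L == 0L
    if (cat == "oxoC12_derivative") tails <- rep(12L, n_per_category)
    data.frame(
      qsm_id = sprintf("%s_%02d", cat, idx),
      category = cat, tail_carbons = tails, has_3oxo = oxo,
      stringsAsFactors = FALSE
    )
  }))

  with_seed(seed, {
    dg_base <- intercept + tail_slope * mols$tail_carbons +
      oxo_offset * as.numeric(mols$has_3oxo)
    bilayers <- c("DOPC", "POPE_POPG")
    rows <- do.call(rbind, lapply(bilayers, function(bl) {
      df <- mols
      df$bilayer <- bl
      df$dg_par <- dg_base + if (noise_sd > 0) rnorm(nrow(mols), sd = noise_sd) else 0
      df
    }))
    # moderate positive dG_par/dG_trans coupling, floored at 0 by construction
    rows$dg_trans <- pmax(
      0, 30 + 0.5 * rows$dg_par +
        if (noise_sd > 0) rnorm(nrow(rows), sd = noise_sd) else 0)
    rows$dg_par_err <- rep(if (noise_sd > 0) noise_sd else 0, nrow(rows))
    rows$dg_trans_err <- rows$dg_par_err
    panel <- screening_panel(rows)

    # one activity record per molecule; potency from the DOPC dG_par
    dopc <- rows[rows$bilayer == "DOPC", ]
    assay <- ifelse(seq_len(nrow(dopc)) %% 2L == 0L, "IC50", "EC50")
    organism <- ifelse(seq_len(nrow(dopc)) %% 4L < 2L, "E_coli", "P_aeruginosa")
    log_c <- activity_intercept +
      activity_slope * pmax(0, dopc$dg_par - potency_threshold) +
      if (activity_noise_sd > 0) rnorm(nrow(dopc), sd = activity_noise_sd) else 0
    activity <- activity_records(data.frame(
      qsm_id = dopc$qsm_id, assay = assay, organism = organism,
      concentration_uM = 10^log_c, source = "synthetic",
      stringsAsFactors = FALSE
    ))
    list(panel = panel, activity = activity)
  })
}
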