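test_that("histogramming conserves counts on a shared grid and reports clipping", {
  ens <- biased_ensemble(list(
    list(center = 0.15, force_constant = 100, samples = c(0.11, 0.19)),
    list(center = 0.15, force_constant = 200, samples = c(0.12, 0.18, 0.31))
  ))
  # one-bin capture
  h1 <- histogram_windows(
    biased_ensemble(list(list(center = 0.15, force_constant = 100,
                              samples = c(0.11, 0.19)))),
    bin_width = 0.1, range = c(0.1, 0.2))
  expect_equal(ncol(h1$counts), 1L)
  expect_equal(as.vector(h1$counts), 2)
  # shared bin centers and conservation incl. clipping
  expect_error(
    h <- histogram_windows(ens, bin_width = 0.1, range = c(0.1, 0.3)),
    "outside the histogram range")   # 1 of 5 samples clipped (20% > 10%)
  h2 <- histogram_windows(ens, bin_width = 0.1)
  expect_equal(sum(h2$counts) + sum(h2$clipped), 5)
  expect_equal(nrow(h2$counts), 2L)
  # random data conservation
  ens2 <- flat_ensemble(c(-0.2, 0.2), n = 500)
  h3 <- histogram_windows(ens2, bin_width = 0.05)
  expect_equal(sum(h3$counts) + sum(h3$clipped), 1000)
})

test_that("single unbiased window yields PMF = -RT ln(counts) + const exactly", {
  z <- sample_window(mempart:::flat_potential(), 0, 50, n = 3000, seed = 2)
  ens <- biased_ensemble(list(
    list(center = 0, force_constant = 0, samples = z)))
  sol <- solve_wham(histogram_windows(ens, bin_width = 0.05))
  expect_true(sol$converged)
  occ <- sol$total_counts > 0
  expected <- -rt_kj(310.15) * log(sol$total_counts[occ])
  diffs <- sol$pmf_values[occ] - expected
  expect_lt(max(diffs) - min(diffs), 1e-9)
})

test_that("flat landscape is reconstructed flat", {
  ens <- flat_ensemble(c(-0.1, 0.1), k = 500, n = 20000, seed = 31)
  sol <- solve_wham(histogram_windows(ens, bin_width = 0.05))
  # judge flatness over the well-sampled core between the window centers
  keep <- !is.na(sol$pmf_values) & abs(sol$bin_centers) <= 0.2
  g <- sol$pmf_values[keep]
  expect_lt(max(g) - min(g), 0.3)
})

test_that("WHAM matches an independent brute-force fixed point on a discrete toy", {
  # 3 bins, 2 windows, fixed integer counts
  counts <- rbind(c(30L, 15L, 5L), c(4L, 16L, 30L))
  bc <- c(0.0, 0.1, 0.2)
  centers <- c(0.05, 0.15)
  k <- c(400, 400)
  rt <- rt_kj(310.15)
  h <- structure(list(
    bin_centers = bc, counts = counts, centers = centers,
    force_constants = k, n_samples = rowSums(counts),
    clipped = c(0L, 0L), bin_width = 0.1, temperature = 310.15),
    class = "wham_histograms")
  sol <- solve_wham(h, tolerance = 1e-12)

  # oracle: scalar-loop naive fixed-point iteration at 1e-14
  u <- matrix(0, 2, 3)
  for (i in 1:2) for (b in 1:3) u[i, b] <- 0.5 * k[i] * (bc[b] - centers[i])^2
  f <- c(0, 0)
  Ni <- rowSums(counts)
  for (it in 1:200000) {
    rho <- numeric(3)
    for (b in 1:3) {
      den <- 0
      for (i in 1:2) den <- den + Ni[i] * exp((f[i] - u[i, b]) / rt)
      rho[b] <- sum(counts[, b]) / den
    }
    fn <- numeric(2)
    for (i in 1:2) {
      s <- 0
      for (b in 1:3) s <- s + rho[b] * exp(-u[i, b] / rt)
      fn[i] <- -rt * log(s)
    }
    fn <- fn - fn[1]
    if (max(abs(fn - f)) < 1e-14) { f <- fn; break }
    f <- fn
  }
  rho_o <- numeric(3)
  for (b in 1:3) {
    den <- 0
    for (i in 1:2) den <- den + Ni[i] * exp((f[i] - u[i, b]) / rt)
    rho_o[b] <- sum(counts[, b]) / den
  }
  expect_lt(max(abs(sol$window_free_energies - f)), 1e-10)
  expect_lt(max(abs(sol$density - rho_o)), 1e-10)
})

test_that("adding a constant to all biases shifts f_i and leaves the referenced PMF unchanged", {
  ens <- flat_ensemble(c(-0.2, 0, 0.2), k = 300, n = 3000, seed = 41)
  h <- histogram_windows(ens, bin_width = 0.05)
  base_bias <- mempart:::harmonic_bias_matrix(h)
  s0 <- solve_wham(h, tolerance = 1e-10)
  s1 <- solve_wham(h, tolerance = 1e-10, bias = base_bias + 7.5)
  # f_i shift by the constant (up to the f_1 = 0 gauge both shift identically)
  expect_lt(max(abs(s1$window_free_energies - s0$window_free_energies)), 1e-9)
  p0 <- wham_pmf(s0, reference_z = 0)
  p1 <- wham_pmf(s1, reference_z = 0)
  expect_lt(max(abs(p0$g - p1$g)), 1e-9)
})

test_that("window order does not change the solution", {
  ens <- flat_ensemble(c(-0.2, 0, 0.2), k = 300, n = 2000, seed = 51)
  perm <- biased_ensemble(ens$windows[c(3, 1, 2)])
  s1 <- solve_wham(histogram_windows(ens, bin_width = 0.05))
  s2 <- solve_wham(histogram_windows(perm, bin_width = 0.05))
  expect_identical(s1$pmf_values, s2$pmf_values)
  expect_identical(s1$window_free_energies, s2$window_free_energies)
})

test_that("disconnected window islands raise a diagnostic naming the groups", {
  ens <- biased_ensemble(list(
    list(center = -3, force_constant = 5000,
         samples = rnorm(200, -3, 0.02)),
    list(center = 3, force_constant = 5000,
         samples = rnorm(200, 3, 0.02))
  ))
  expect_error(solve_wham(histogram_windows(ens, bin_width = 0.05)),
               "disconnected")
})

test_that("convergence residual is non-increasing and reaching max_iter flags non-convergence", {
  pot <- make_model_pmf()
  lay <- umbrella_layout(-1.5, 0, spacing = 0.1, samples_per_window = 1000)
  ens <- generate_umbrella_dataset(pot, lay, seed = 61)
  h <- histogram_windows(ens, bin_width = 0.05)
  sol <- solve_wham(h)
  expect_true(sol$converged)
  expect_true(all(diff(sol$residual_trace) <= 0))
  capped <- solve_wham(h, max_iter = 5)
  expect_false(capped$converged)
  expect_equal(capped$n_iterations, 5L)
  expect_gt(capped$max_residual, 1e-7)
})

test_that("two-block split follows the documented equilibration arithmetic", {
  # 32 samples, equilibration fraction 5/32: drop 5, then 27 is odd so the
  # first post-equilibration sample is dropped, leaving blocks of 13 + 13
  z <- 0.1 + (seq_len(32) %% 4) / 100  # both blocks occupy the same bins
  ens <- biased_ensemble(list(list(center = 0.11, force_constant = 10,
                                   samples = z)),
                         equilibration_fraction = 5 / 32)
  post <- mempart:::post_equilibration(z, 5 / 32)
  expect_length(post, 27)
  tb <- two_block_pmfs(ens, bin_width = 0.05)
  n_used <- vapply(tb$blocks, function(s) sum(s$total_counts), numeric(1))
  expect_equal(unname(n_used), c(13, 13))
})

test_that("identical blocks give zero spread and mean equal to either block", {
  z <- sample_window(mempart:::flat_potential(), 0, 300, n = 400, seed = 71)
  dup <- c(z, z)  # two identical contiguous halves
  ens <- biased_ensemble(list(list(center = 0, force_constant = 300,
                                   samples = dup)))
  tb <- two_block_pmfs(ens, bin_width = 0.05, reference_z = 0)
  expect_true(all(abs(tb$sd$g) < 1e-12))
  one <- wham_pmf(tb$blocks[[1]], reference_z = 0)
  expect_equal(tb$mean$g, one$g, tolerance = 1e-12)
})

test_that("WHAM recovers the model landscape from a production-style window ladder", {
  pot <- make_model_pmf()
  lay <- umbrella_layout(-2, 0, spacing = 0.1, force_constants = 500,
                         samples_per_window = 3000)
  ens <- generate_umbrella_dataset(pot, lay, seed = 81)
  pmf <- wham_pmf(solve_wham(histogram_windows(ens, bin_width = 0.05)),
                  reference_z = -2)
  iref <- which.min(abs(pmf$z + 2))
  true_g <- eval_potential(pot, pmf$z) - eval_potential(pot, pmf$z)[iref]
  expect_lt(sqrt(mean((pmf$g - true_g)^2)), 1.0)
})
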