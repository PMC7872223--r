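test_that("referencing subtracts the nearest-point value and is idempotent", {
  p <- pmf_profile(z = c(3.8, 3.9, 4.0), g = c(5, 7, 9))
  r <- set_reference(p, 4.0)
  expect_equal(r$g, c(-4, -2, 0))
  expect_equal(r$reference_z, 4.0)
  # idempotent
  expect_equal(set_reference(r, 4.0)$g, r$g)
  # nearest-point rule: 3.96 snaps to the 4.0 grid point
  r2 <- set_reference(p, 3.96)
  expect_equal(r2$g, c(-4, -2, 0))
  expect_error(set_reference(p, 5.0), "outside")
})

test_that("asymmetry score measures mean mirror deviation", {
  z <- c(-1.5, -1.0, -0.5, 0.5, 1.0, 1.5)
  even <- pmf_profile(z, z^2)
  expect_equal(asymmetry_score(even), 0, tolerance = 1e-12)
  odd <- pmf_profile(c(-1, 1), c(-1, 1))
  expect_equal(asymmetry_score(odd), 2)
  # invariant to an additive constant
  shifted <- pmf_profile(c(-1, 1), c(-1, 1) + 13)
  expect_equal(asymmetry_score(shifted), 2)
  one_sided <- pmf_profile(c(0.5, 1), c(0, 1))
  expect_error(asymmetry_score(one_sided), "one-sided")
})

test_that("dG_par is the referenced PMF minimum, at the reported location", {
  # headline partition free energies pass through unchanged
  for (gmin in c(-23.16, -6.36)) {
    prof <- profile_with_min(gmin)
    res <- delta_g_par(prof)
    expect_equal(res$dg_par, min(prof$g))
    expect_lt(abs(res$dg_par - gmin) / abs(gmin), 0.02)
    expect_lt(abs(abs(res$z_min) - 1.2), 0.1)
  }
  # monotone non-negative profile: minimum 0 at the reference
  flat <- set_reference(pmf_profile(z = seq(0, 4, 0.5), g = rep(3, 9)), 4)
  expect_equal(delta_g_par(flat)$dg_par, 0)
  # unreferenced or non-bulk reference errors
  expect_error(delta_g_par(pmf_profile(1:3, c(1, 2, 3))), "referenced")
  near <- set_reference(pmf_profile(z = seq(-2, 2, 0.5), g = rep(1, 9)), 2)
  expect_error(delta_g_par(near), "bulk")
})

test_that("degenerate multiple minima report the location closest to bulk", {
  z <- c(-4, -1.2, 0, 1.0, 2, 4)
  g <- c(0, -5, 10, -5, 3, 0)
  prof <- set_reference(pmf_profile(z, g), -4)
  # |z| = 1.2 beats |z| = 1.0; with an exact |z| tie the negative side leads
  expect_equal(delta_g_par(prof)$z_min, -1.2)
  tie <- set_reference(pmf_profile(c(-4, -1.2, 0, 1.2, 4),
                                   c(0, -5, 10, -5, 0)), -4)
  expect_equal(delta_g_par(tie)$z_min, -1.2)
})

test_that("direct dG_trans is max minus min over the stored grid", {
  p1 <- set_reference(pmf_profile(c(-4, -1.2, 0), c(0, -6.36, 22.27)), -4)
  expect_equal(delta_g_trans_direct(p1), 28.63)
  p2 <- set_reference(pmf_profile(c(-4, -1.2, 0), c(0, -5, 30.18)), -4)
  expect_equal(delta_g_trans_direct(p2), 35.18)
  const <- set_reference(pmf_profile(seq(-4, 0, 1), rep(0, 5)), -4)
  expect_equal(delta_g_trans_direct(const), 0)
})

test_that("plateau extrapolation fits the 3rd-5th closest points and averages sides", {
  # one-sided collinear toy: line through (0.5,28),(0.7,24),(0.9,20) has
  # intercept 38; with minimum -5 the barrier is 43
  z <- c(0.1, 0.3, 0.5, 0.7, 0.9, 1.2, 4)
  g <- c(30, 30, 28, 24, 20, -5, 0)
  prof <- set_reference(pmf_profile(z, g), 4)
  res <- delta_g_trans_extrapolated(prof)
  expect_equal(res$intercept, 38, tolerance = 1e-9)
  expect_equal(res$dg_trans, 43, tolerance = 1e-9)
  expect_equal(res$diagnostics$positive$z, c(0.5, 0.7, 0.9))
  expect_equal(unname(res$diagnostics$positive$slope), -20, tolerance = 1e-9)

  # flat plateau: all candidate points equal -> extrapolated == direct
  zf <- c(0.1, 0.3, 0.5, 0.7, 0.9, 1.2, 4)
  gf <- c(7, 7, 7, 7, 7, -5, 0)
  pf <- set_reference(pmf_profile(zf, gf), 4)
  expect_equal(delta_g_trans_extrapolated(pf)$dg_trans,
               delta_g_trans_direct(pf), tolerance = 1e-9)

  # symmetric profile: both side intercepts equal, averaging changes nothing
  zs <- c(-rev(z), z)
  gs <- c(rev(g), g)
  ps <- set_reference(pmf_profile(zs, gs), 4)
  rs <- delta_g_trans_extrapolated(ps)
  expect_equal(rs$diagnostics$negative$intercept,
               rs$diagnostics$positive$intercept, tolerance = 1e-9)
  expect_equal(rs$dg_trans, 43, tolerance = 1e-9)

  # too few points on both sides
  short <- set_reference(pmf_profile(c(0.5, 1, 4), c(3, -2, 0)), 4)
  expect_error(delta_g_trans_extrapolated(short), ">= 5")
})

test_that("extrapolation can only raise a plateau estimate when the flank falls toward z = 0", {
  pot <- make_model_pmf()
  pp <- generate_partition_profile(pot, n_slices = 21, noise_sd = 0,
                                   plateau_halfwidth = 0.5, seed = 1)
  prof <- set_reference(pmf_from_partition(pp), -2)
  # reference is not bulk here; only the barrier is examined
  res <- delta_g_trans_extrapolated(prof)
  # the PMF falls away from the midplane on both flanks, so both one-sided
  # fits must point uphill toward z = 0 and the intercept must sit at or
  # above the plateau value
  expect_lt(res$diagnostics$positive$slope, 0)
  expect_gt(res$diagnostics$negative$slope, 0)
  g0 <- prof$g[which.min(abs(prof$z))]
  expect_gte(res$dg_trans + 1e-9, g0 - min(prof$g))
})

test_that("PMF and partition-coefficient conversions invert each other", {
  rt <- rt_kj(310.15)
  pp <- partition_profile(z = c(-1, 0, 1), ln_k = c(0, 2, 3.878),
                          temperature = 310.15)
  pmf <- pmf_from_partition(pp)
  expect_equal(pmf$g[1], 0)
  expect_equal(pmf$g[2], -5.157, tolerance = 1e-3)
  expect_equal(pmf$g[3], -10.0, tolerance = 1e-3)
  # round trip on random finite profiles
  set.seed(8)
  for (i in 1:5) {
    z <- sort(runif(20, -3, 3))
    lnk <- rnorm(20, sd = 4)
    back <- partition_from_pmf(pmf_from_partition(
      partition_profile(z, lnk, temperature = 250 + 50 * i)))
    expect_lt(max(abs(back$ln_k - lnk)), 1e-12)
    expect_equal(back$temperature, 250 + 50 * i)
  }
  expect_equal(partition_from_pmf(pmf_profile(0, 0))$ln_k, 0)
})

test_that("noiseless plateau-free partition profile recovers the well depth", {
  pot <- make_model_pmf(well_depth = 12)
  pp <- generate_partition_profile(pot, n_slices = 101, noise_sd = 0,
                                   plateau_halfwidth = 0, z_span = 4, seed = 1)
  prof <- set_reference(pmf_from_partition(pp), 4)
  got <- delta_g_par(prof)$dg_par
  true_min <- min(eval_potential(pot, seq(-4, 4, 0.001)))
  expect_lt(abs(got - true_min), 0.15)  # grid-resolution error only
})

test_that("gauge invariance: constants added before referencing change nothing downstream", {
  prof <- profile_with_min(-9)
  raw <- pmf_profile(prof$z, prof$g + 42)
  ref <- set_reference(raw, 4)
  expect_equal(ref$g, prof$g, tolerance = 1e-12)
  expect_equal(delta_g_par(ref)$dg_par, delta_g_par(prof)$dg_par)
  expect_equal(delta_g_trans_direct(ref), delta_g_trans_direct(prof))
})

test_that("extrapolated and direct barrier estimates agree strongly across a synthetic panel", {
  depths <- seq(6, 16, length.out = 12)
  barriers <- seq(15, 35, length.out = 12)
  direct <- extrap <- numeric(12)
  for (i in 1:12) {
    pot <- make_model_pmf(well_depth = depths[i], barrier_height = barriers[i])
    pp <- generate_partition_profile(pot, n_slices = 21, noise_sd = 0.3,
                                     plateau_halfwidth = 0.45, seed = 100 + i)
    prof <- set_reference(pmf_from_partition(pp), -2)
    # midplane-difference rule vs flank extrapolation
    direct[i] <- prof$g[which.min(abs(prof$z))] - min(prof$g)
    extrap[i] <- delta_g_trans_extrapolated(prof)$dg_trans
  }
  expect_gt(cor(direct, extrap), 0.9)
})

test_that("replicate combination returns means and standard errors", {
  mk <- function(par, trans) free_energy_summary(par, trans,
                                                 trans_method = "direct_max")
  out <- combine_replicates(list(mk(1, 10), mk(2, 11), mk(3, 12)))
  expect_equal(out$dg_par, 2)
  expect_equal(out$dg_par_err, sd(1:3) / sqrt(3), tolerance = 1e-12)
  expect_equal(out$dg_par_err, 0.577, tolerance = 1e-3)
  two <- combine_replicates(list(mk(5, 10), mk(7, 10)))
  expect_equal(two$dg_par, 6)
  expect_equal(two$dg_par_err, 1.0)
  same <- combine_replicates(list(mk(4, 9), mk(4, 9), mk(4, 9)))
  expect_equal(same$dg_par_err, 0)
  expect_equal(same$dg_trans_err, 0)
  mixed <- list(mk(1, 10),
                free_energy_summary(2, 11, trans_method = "extrapolated"))
  expect_error(combine_replicates(mixed), "trans_method")
  expect_error(combine_replicates(list(mk(1, 1))), ">= 2")
})
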