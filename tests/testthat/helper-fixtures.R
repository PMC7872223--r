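# shared tiny fixtures built in code

# referenced profile with prescribed minimum, bulk reference at z = 4
profile_with_min <- function(g_min, g_max = g_min + 30) {
  z <- seq(-4, 4, 0.2)
  g <- g_max * exp(-(z / 0.5)^2) + g_min * exp(-((z - 1.2) / 0.3)^2) +
    g_min * exp(-((z + 1.2) / 0.3)^2)
  prof <- pmf_profile(z, g)
  set_reference(prof, 4)
}

# minimal valid screening panel rows
panel_row <- function(qsm_id, tail = 8L, oxo = FALSE, bilayer = "DOPC",
                      dg_par = -10, dg_trans = 25, category = "AHL") {
  data.frame(qsm_id = qsm_id, category = category, tail_carbons = tail,
             has_3oxo = oxo, bilayer = bilayer, dg_par = dg_par,
             dg_trans = dg_trans, dg_par_err = 0.5, dg_trans_err = 0.5,
             stringsAsFactors = FALSE)
}

# small biased ensemble on a flat landscape
flat_ensemble <- function(centers, k = 500, n = 2000, seed = 1) {
  windows <- lapply(seq_along(centers), function(i) {
    list(center = centers[i], force_constant = k,
         samples = sample_window(mempart:::flat_potential(), centers[i], k,
                                 n = n, seed = seed + i))
  })
  biased_ensemble(windows)
}
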