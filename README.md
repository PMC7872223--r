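# mempart

Membrane partitioning and translocation free-energy analysis for small
amphiphiles — quorum-sensing modulators (QSMs) such as N-acyl homoserine
lactones (AHLs) — with a fully synthetic, ground-truth-known test bed.

## What it computes

The interaction of an amphiphile with a lipid bilayer is summarised by its
potential of mean force (PMF) `G(z)` along the bilayer normal `z`
(distance from the midplane, nm; energies in kJ/mol), referenced to zero
in bulk water:

- **ΔG_par** — partition free energy: the PMF global minimum (near the
  headgroup/tail interface, |z| ≈ 1.2 nm). More negative = stronger
  membrane accumulation.
- **ΔG_trans** — translocation free energy: PMF maximum (at the midplane)
  minus minimum; the barrier to crossing the membrane.

`mempart` implements the chain that produces and consumes these numbers:

1. **Synthetic data** with known truth: a Gaussian model landscape
   (`make_model_pmf`), Metropolis sampling of harmonically biased umbrella
   windows (`sample_window`, `generate_umbrella_dataset`), sliced
   water–membrane partition-coefficient profiles with a midplane plateau
   (`generate_partition_profile`), and a screening panel with
   tail-length-dependent ΔG_par, a ~5 kJ/mol 3-oxo head-group offset and a
   potency threshold (`generate_screening_panel`).
2. **WHAM** — the weighted histogram analysis method
   (`histogram_windows`, `solve_wham`): self-consistent reconstruction
   `ρ_b = Σᵢ n_ib / Σᵢ Nᵢ e^{(fᵢ − uᵢ(z_b))/RT}`,
   `fᵢ = −RT ln Σ_b ρ_b e^{−uᵢ(z_b)/RT}`, `PMF = −RT ln ρ` — plus the
   two-block error protocol (`two_block_pmfs`).
3. **Features** (`set_reference`, `delta_g_par`, `delta_g_trans_direct`,
   `delta_g_trans_extrapolated`, `pmf_from_partition` /
   `partition_from_pmf` via `PMF(z) = −RT ln K_{w→m}(z)`,
   `combine_replicates`, `asymmetry_score`). The extrapolated barrier rule
   fits the 3rd–5th closest points to `z = 0` and uses the line's
   intercept — correcting the midplane plateau of slice-based
   partition-coefficient profiles.
4. **Screening statistics** (`tail_length_trend`, `oxo_offset`,
   `bilayer_contrast`, `correlate_par_trans`) and **potency association**
   (`merge_activity`, `rank_correlation`, `threshold_split`) against
   EC50/IC50 panels, including the −10 kJ/mol partitioning threshold
   comparison.
5. **I/O and pipeline**: xvg-like window tables, TSV panels, JSON
   summaries, a flat key–value config, and `run_pipeline()` chaining
   simulate → wham → features → screen → associate deterministically
   (byte-identical reruns). A thin CLI lives at
   `inst/scripts/mempart.R`.

## Worked example

```r
library(mempart)

# true landscape: wells -10 kJ/mol at +/-1.2 nm, +25 kJ/mol midplane barrier
pot <- make_model_pmf()

# 53 umbrella windows every 0.1 nm from z = -4 to 1.2 nm, k = 500 kJ/mol/nm^2
lay <- umbrella_layout(-4, 1.2, spacing = 0.1, force_constants = 500,
                       samples_per_window = 2000)
ens <- generate_umbrella_dataset(pot, lay, seed = 7)

# two-block WHAM with common bulk reference, then the headline free energies
tb <- two_block_pmfs(ens, reference_z = -4)
summarize_pmf(tb$mean, bulk_cutoff = 3)
#> dG_par   =   -9.077 +/- 1.643 kJ/mol (minimum at z = 1.175 nm)
#> dG_trans =   35.034 +/- 2.008 kJ/mol (direct_max)
```

The true values on this landscape are ΔG_par = −9.92 and
ΔG_trans = 34.92 kJ/mol: the reconstruction is within one error bar of
both at this modest sampling. The screening layer recovers its generating
parameters the same way:

```r
gp <- generate_screening_panel(n_per_category = 10, seed = 8)
tail_length_trend(gp$panel, oxo = FALSE)   # slope -1.53 +/- 0.08, r = -0.962
oxo_offset(gp$panel)                       # +4.76 +/- 0.28 kJ/mol, 30 pairs

j <- merge_activity(gp$panel, gp$activity)
threshold_split(j, cutoff = -10)
#> median log10 concentration 1.35 (weak partitioners, dG_par > -10)
#> vs 0.52 (strong partitioners), exact rank-sum p = 6.1e-05
```

Weakly partitioning molecules need ~7× higher concentrations to modulate
quorum sensing — the generator's threshold rule, recovered by the test.

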