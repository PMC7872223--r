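#' Read a two-column whitespace xy table
#'
#' Parses the xvg-like dialect used for per-window reaction-coordinate
#' time series: lines beginning with `#` or `@` are skipped, every other
#' nonempty line must carry at least two whitespace-separated numeric
#' fields (time index and z in nm). Parse failures report the offending
#' line number.
#'
#' @param path file to read.
#' @return List with numeric vectors `x` and `y` and the row count `n`.
#' @export
read_xy_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  x <- numeric(0); y <- numeric(0)
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (nchar(ln) == 0L || startsWith(ln, "#") || startsWith(ln, "@")) next
    fields <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(fields) < 2L) {
      stop(sprintf("%s: line %d has fewer than 2 columns", path, i),
           call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (any(is.na(vals))) {
      stop(sprintf("%s: line %d has a non-numeric cell ('%s')", path, i, ln),
           call. = FALSE)
    }
    x <- c(x, vals[1]); y <- c(y, vals[2])
  }
  list(x = x, y = y, n = length(x))
}

#' Write one umbrella window's samples as an xy table
#'
#' @param samples numeric z samples in nm.
#' @param path output file.
#' @param header character vector of comment lines (written with a leading
#'   `#`).
#' @return `path`, invisibly.
#' @export
write_window_file <- function(samples, path, header = character(0)) {
  stopifnot(is.numeric(samples))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste("#", h), con)
  writeLines(sprintf("%d %.17g", seq_along(samples), samples), con)
  invisible(path)
}

#' Write a biased ensemble to a directory of window files
#'
#' One xy file per window plus a `windows.tsv` metadata table with columns
#' `file`, `center_nm`, `k_kJ_mol_nm2`.
#'
#' @param ensemble a [biased_ensemble()].
#' @param dir output directory (created if needed).
#' @param meta_header extra comment lines for the files.
#' @return Path of the metadata table, invisibly.
#' @export
write_ensemble <- function(ensemble, dir, meta_header = character(0)) {
  stopifnot(inherits(ensemble, "biased_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(
    file = sprintf("window_%03d.xvg", seq_along(ensemble$windows)),
    center_nm = vapply(ensemble$windows, `[[`, numeric(1), "center"),
    k_kJ_mol_nm2 = vapply(ensemble$windows, `[[`, numeric(1), "force_constant")
  )
  for (i in seq_along(ensemble$windows)) {
    write_window_file(
      ensemble$windows[[i]]$samples, file.path(dir, meta$file[i]),
      header = c(meta_header,
                 sprintf("center_nm %.17g k_kJ_mol_nm2 %.17g temperature_K %.17g",
                         meta$center_nm[i], meta$k_kJ_mol_nm2[i],
                         ensemble$temperature)))
  }
  meta_path <- file.path(dir, "windows.tsv")
  write_tsv_with_header(meta, meta_path, meta_header)
  invisible(meta_path)
}

#' Read a biased ensemble from a directory of window files
#'
#' @param dir directory containing the window files.
#' @param meta path to the metadata TSV (default `dir/windows.tsv`).
#' @param temperature kelvin.
#' @param equilibration_fraction stored on the ensemble.
#' @return A [biased_ensemble()].
#' @export
read_ensemble <- function(dir, meta = file.path(dir, "windows.tsv"),
                          temperature = DEFAULT_TEMPERATURE,
                          equilibration_fraction = 0) {
  tbl <- read_tsv_table(meta, c("file", "center_nm", "k_kJ_mol_nm2"))
  windows <- lapply(seq_len(nrow(tbl)), function(i) {
    xy <- read_xy_table(file.path(dir, tbl$file[i]))
    if (xy$n == 0L) {
      stop(sprintf("window file %s holds no samples", tbl$file[i]),
           call. = FALSE)
    }
    list(center = tbl$center_nm[i], force_constant = tbl$k_kJ_mol_nm2[i],
         samples = xy$y)
  })
  biased_ensemble(windows, temperature = temperature,
                  equilibration_fraction = equilibration_fraction)
}

# TSV helpers: header row, full-precision numbers, optional '#' comments.
write_tsv_with_header <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in comments) writeLines(paste("#", h), con)
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

read_tsv_table <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write a PMF profile as a TSV table
#'
#' Columns `z_nm`, `pmf_kJ_mol`, `sd_kJ_mol`, `total_counts`; numbers are
#' written with 17 significant digits so a read-back round-trips exactly.
#'
#' @param pmf a [pmf_profile()].
#' @param path output file.
#' @param total_counts optional per-bin counts column.
#' @param comments extra `#` comment lines (e.g. config hash, seed).
#' @return `path`, invisibly.
#' @export
write_pmf_table <- function(pmf, path, total_counts = NULL,
                            comments = character(0)) {
  stopifnot(inherits(pmf, "pmf_profile"))
  df <- data.frame(
    z_nm = pmf$z, pmf_kJ_mol = pmf$g,
    sd_kJ_mol = if (is.null(pmf$g_sd)) rep(0, length(pmf$z)) else pmf$g_sd,
    total_counts = if (is.null(total_counts)) rep(NA_real_, length(pmf$z))
                   else total_counts
  )
  write_tsv_with_header(df, path, comments)
}

#' Read a PMF profile from a TSV table
#'
#' @param path file written by [write_pmf_table()].
#' @param reference_z optional reference position recorded on the profile
#'   (the values are assumed already referenced there).
#' @param temperature kelvin.
#' @return A [pmf_profile()].
#' @export
read_pmf_table <- function(path, reference_z = NULL,
                           temperature = DEFAULT_TEMPERATURE) {
  df <- read_tsv_table(path, c("z_nm", "pmf_kJ_mol", "sd_kJ_mol"))
  pmf_profile(z = df$z_nm, g = df$pmf_kJ_mol, g_sd = df$sd_kJ_mol,
              reference_z = reference_z, temperature = temperature)
}

#' Write a screening panel to TSV
#' @param panel a [screening_panel()].
#' @param path output file.
#' @param comments `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, comments = character(0)) {
  stopifnot(inherits(panel, "screening_panel"))
  write_tsv_with_header(as.data.frame(panel), path, comments)
}

#' Read a screening panel from TSV
#' @param path file with the panel columns (see [screening_panel()]).
#' @return A [screening_panel()].
#' @export
read_panel <- function(path) {
  df <- read_tsv_table(path, c("qsm_id", "category", "tail_carbons",
                               "has_3oxo", "bilayer", "dg_par", "dg_trans",
                               "dg_par_err", "dg_trans_err"))
  df$has_3oxo <- as.logical(df$has_3oxo)
  for (col in c("dg_par", "dg_trans", "dg_par_err", "dg_trans_err")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$tail_carbons <- as.integer(df$tail_carbons)
  screening_panel(df)
}

#' Write activity records to TSV
#' @param activity an [activity_records()] data.frame.
#' @param path output file.
#' @param comments `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_activity <- function(activity, path, comments = character(0)) {
  stopifnot(inherits(activity, "activity_records"))
  write_tsv_with_header(as.data.frame(activity), path, comments)
}

#' Read activity records from TSV
#' @param path file with columns qsm_id, assay, organism, concentration_uM,
#'   source.
#' @return An [activity_records()] data.frame.
#' @export
read_activity <- function(path) {
  df <- read_tsv_table(
    path, c("qsm_id", "assay", "organism", "concentration_uM", "source"))
  df$concentration_uM <- as.numeric(df$concentration_uM)
  activity_records(df)
}

SUMMARY_KEYS <- c("dg_par", "dg_trans", "dg_par_err", "dg_trans_err",
                  "trans_method", "z_min")

#' Write a free-energy summary as JSON
#'
#' Numbers are serialized at full precision; non-finite fields are
#' rejected at write time.
#'
#' @param summary a [free_energy_summary()] (extra fields such as an
#'   asymmetry score may be attached as attributes via `extra`).
#' @param path output file.
#' @param extra named list of additional scalar fields to include.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, extra = list()) {
  stopifnot(inherits(summary, "free_energy_summary"))
  payload <- c(unclass(summary), extra)
  for (k in setdiff(names(payload), "trans_method")) {
    v <- payload[[k]]
    if (is.numeric(v) && any(!is.finite(v))) {
      stop(sprintf("refusing to write non-finite field '%s'", k), call. = FALSE)
    }
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a free-energy summary from JSON
#'
#' @param path file written by [write_summary()].
#' @return A [free_energy_summary()]; extra fields are kept as an
#'   `"extra"` attribute.
#' @export
read_summary <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing_keys <- setdiff(SUMMARY_KEYS, names(payload))
  if (length(missing_keys) > 0L) {
    stop(sprintf("summary file %s is missing key(s): %s", path,
                 paste(missing_keys, collapse = ", ")), call. = FALSE)
  }
  out <- free_energy_summary(
    dg_par = payload$dg_par, dg_trans = payload$dg_trans,
    dg_par_err = payload$dg_par_err, dg_trans_err = payload$dg_trans_err,
    trans_method = payload$trans_method, z_min = payload$z_min)
  attr(out, "extra") <- payload[setdiff(names(payload), SUMMARY_KEYS)]
  out
}

#' Read a flat key-value run configuration
#'
#' One `key = value` (or `key: value`) pair per line; `#` comments and
#' blank lines ignored. Unknown keys are rejected; numeric values are
#' range-checked. See [default_config()] for the recognised keys.
#'
#' @param path config file.
#' @return A validated named list of class `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (nchar(ln) == 0L) next
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)[[:space:]]*[=:][[:space:]]*(.*)$", ln))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("%s: line %d is not 'key = value'", path, i), call. = FALSE)
    }
    kv[[m[2]]] <- m[3]
  }
  run_config(kv)
}

#' Default pipeline configuration
#'
#' @return A `run_config` list with all defaults (a small demonstration-
#'   scale umbrella layout: full window ladder, modest per-window sampling).
#' @export
default_config <- function() {
  run_config(list())
}

CONFIG_SPEC <- list(
  seed               = list(default = 1,       min = 0,    max = 2^31 - 1),
  temperature        = list(default = 310.15,  min = 1,    max = 1000),
  well_depth         = list(default = 10,      min = 1e-6, max = 1000),
  well_position      = list(default = 1.2,     min = 0,    max = 10),
  well_width         = list(default = 0.3,     min = 1e-3, max = 10),
  barrier_height     = list(default = 25,      min = 1e-6, max = 1000),
  barrier_width      = list(default = 0.5,     min = 1e-3, max = 10),
  z_start            = list(default = -4,      min = -100, max = 100),
  z_stop             = list(default = 1.2,     min = -100, max = 100),
  spacing            = list(default = 0.1,     min = 1e-4, max = 10),
  force_constant     = list(default = 500,     min = 1e-6, max = 1e6),
  samples_per_window = list(default = 1000,    min = 2,    max = 1e8),
  equilibration_fraction = list(default = 5 / 32, min = 0, max = 0.999),
  bin_width          = list(default = 0.05,    min = 1e-5, max = 10),
  tolerance          = list(default = 1e-7,    min = 1e-15, max = 1),
  max_iter           = list(default = 1e5,     min = 1,    max = 1e9),
  reference_z        = list(default = -4,      min = -100, max = 100),
  bulk_cutoff        = list(default = 3.0,     min = 0,    max = 100),
  trans_method       = list(default = "direct_max",
                            choices = c("direct_max", "extrapolated")),
  n_per_category     = list(default = 10,      min = 1,    max = 1e5),
  tail_slope         = list(default = -1.5,    min = -100, max = -1e-9),
  oxo_offset         = list(default = 5,       min = 0,    max = 100),
  potency_threshold  = list(default = -10,     min = -1000, max = 1000),
  panel_noise_sd     = list(default = 1,       min = 0,    max = 100),
  activity_cutoff    = list(default = -10,     min = -1000, max = 1000),
  assay              = list(default = "all",
                            choices = c("all", "EC50", "IC50"))
)

run_config <- function(kv) {
  unknown <- setdiff(names(kv), names(CONFIG_SPEC))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- list()
  for (key in names(CONFIG_SPEC)) {
    spec <- CONFIG_SPEC[[key]]
    if (!is.null(kv[[key]])) {
      raw <- kv[[key]]
      if (!is.null(spec$choices)) {
        val <- as.character(raw)
        if (!val %in% spec$choices) {
          stop(sprintf("config key '%s' must be one of %s (got '%s')",
                       key, paste(spec$choices, collapse = ", "), val),
               call. = FALSE)
        }
      } else {
        val <- suppressWarnings(as.numeric(raw))
        if (is.na(val)) {
          stop(sprintf("config key '%s' is not numeric ('%s')", key, raw),
               call. = FALSE)
        }
        if (val < spec$min || val > spec$max) {
          stop(sprintf("config key '%s' = %g outside valid range [%g, %g]",
                       key, val, spec$min, spec$max), call. = FALSE)
        }
      }
    } else {
      val <- spec$default
    }
    cfg[[key]] <- val
  }
  if (cfg$z_start >= cfg$z_stop) {
    stop("config requires z_start < z_stop", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

# canonical text used for the configuration fingerprint
config_text <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  paste(vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s=%s", k, if (is.numeric(v)) sprintf("%.17g", v) else v)
  }, character(1)), collapse = "\n")
}

#' Fingerprint of a run configuration
#'
#' 8-hex-digit FNV-1a hash of the canonical config text, stamped into all
#' pipeline output headers together with the seed.
#'
#' @param cfg a `run_config`.
#' @return Character scalar.
#' @export
config_hash <- function(cfg) {
  fnv1a32(config_text(cfg))
}
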