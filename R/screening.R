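QSM_CATEGORIES <- c("AHL", "AHT", "oxoC12_derivative", "misc")
QSM_BILAYERS <- c("DOPC", "POPE_POPG")

#' Screening panel of quorum-sensing modulators
#'
#' Validates and classes a data.frame joining molecular descriptors with
#' partitioning/translocation free energies: columns `qsm_id`, `category`
#' (one of AHL, AHT, oxoC12_derivative, misc), `tail_carbons` (integer
#' >= 0), `has_3oxo` (logical), `bilayer` (DOPC or POPE_POPG), `dg_par`,
#' `dg_trans` (>= 0), `dg_par_err`, `dg_trans_err` (>= 0), all energies in
#' kJ/mol. Each molecule may appear once per bilayer.
#'
#' @param records a data.frame with the columns above.
#' @return The validated data.frame with class `screening_panel`.
#' @export
screening_panel <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("qsm_id", "category", "tail_carbons", "has_3oxo", "bilayer",
              "dg_par", "dg_trans", "dg_par_err", "dg_trans_err")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop(sprintf("panel is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad_cat <- setdiff(unique(records$category), QSM_CATEGORIES)
  if (length(bad_cat) > 0L) {
    stop(sprintf("unknown category label(s): %s (allowed: %s)",
                 paste(bad_cat, collapse = ", "),
                 paste(QSM_CATEGORIES, collapse = ", ")), call. = FALSE)
  }
  bad_bl <- setdiff(unique(records$bilayer), QSM_BILAYERS)
  if (length(bad_bl) > 0L) {
    stop(sprintf("unknown bilayer label(s): %s", paste(bad_bl, collapse = ", ")),
         call. = FALSE)
  }
  if (any(records$tail_carbons < 0) ||
      any(records$tail_carbons != round(records$tail_carbons))) {
    stop("`tail_carbons` must be non-negative integers", call. = FALSE)
  }
  if (!is.logical(records$has_3oxo)) {
    stop("`has_3oxo` must be logical", call. = FALSE)
  }
  if (any(records$dg_trans < 0)) {
    stop("`dg_trans` must be >= 0 (it is a max - min)", call. = FALSE)
  }
  if (any(records$dg_par_err < 0) || any(records$dg_trans_err < 0)) {
    stop("free-energy errors must be >= 0", call. = FALSE)
  }
  key <- paste(records$qsm_id, records$bilayer)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (qsm_id, bilayer) entries: %s",
                 paste(unique(key[duplicated(key)]), collapse = ", ")),
         call. = FALSE)
  }
  class(records) <- c("screening_panel", "data.frame")
  records
}

#' Tail-length dependence of the partition free energy
#'
#' Ordinary least-squares fit of `dg_par` on `tail_carbons`, optionally
#' within one category and/or bilayer. The expected physics is a negative
#' slope: each additional tail carbon strengthens hydrophobic partitioning
#' into the bilayer core.
#'
#' @param panel a [screening_panel()].
#' @param category optional category filter.
#' @param bilayer optional bilayer filter.
#' @param oxo optional logical filter on the 3-oxo flag; fitting the
#'   non-oxo records isolates the pure tail-length dependence from the
#'   head-group offset.
#' @return List with `slope` (kJ/mol per carbon), `slope_se`, `intercept`,
#'   `r` (Pearson correlation), `n`.
#' @export
tail_length_trend <- function(panel, category = NULL, bilayer = NULL,
                              oxo = NULL) {
  stopifnot(inherits(panel, "screening_panel"))
  df <- panel
  if (!is.null(category)) df <- df[df$category %in% category, ]
  if (!is.null(bilayer)) df <- df[df$bilayer %in% bilayer, ]
  if (!is.null(oxo)) df <- df[df$has_3oxo == oxo, ]
  if (length(unique(df$tail_carbons)) < 3L) {
    stop("need >= 3 records with distinct tail_carbons for a trend fit",
         call. = FALSE)
  }
  fit <- stats::lm(dg_par ~ tail_carbons, data = df)
  r <- if (stats::sd(df$dg_par) == 0) 0 else
    stats::cor(df$tail_carbons, df$dg_par)
  # slope standard error computed directly (avoids summary.lm() warnings on
  # noise-free panels where the fit is exact)
  n <- nrow(df)
  sxx <- sum((df$tail_carbons - mean(df$tail_carbons))^2)
  sigma2 <- sum(stats::residuals(fit)^2) / (n - 2)
  list(slope = unname(stats::coef(fit)[2]),
       slope_se = sqrt(sigma2 / sxx),
       intercept = unname(stats::coef(fit)[1]),
       r = r, n = n)
}

#' Systematic 3-oxo head-group offset
#'
#' Mean difference in `dg_par` over molecule pairs matched on
#' (tail_carbons, bilayer, category) that differ only in the 3-oxo flag.
#' A positive offset means the polar 3-oxo ketone weakens partitioning.
#' All oxo/non-oxo combinations within a matched cell are paired.
#'
#' @param panel a [screening_panel()].
#' @return List with `offset` (mean kJ/mol), `n_pairs`, `offset_se`
#'   (sd of the pair differences over sqrt(n_pairs)), and the per-pair
#'   differences.
#' @export
oxo_offset <- function(panel) {
  stopifnot(inherits(panel, "screening_panel"))
  key <- interaction(panel$tail_carbons, panel$bilayer, panel$category,
                     drop = TRUE)
  diffs <- numeric(0)
  for (cell in split(seq_len(nrow(panel)), key)) {
    oxo <- cell[panel$has_3oxo[cell]]
    non <- cell[!panel$has_3oxo[cell]]
    if (length(oxo) > 0L && length(non) > 0L) {
      diffs <- c(diffs, as.vector(outer(panel$dg_par[oxo], panel$dg_par[non], `-`)))
    }
  }
  if (length(diffs) == 0L) {
    stop(sprintf(
      "no matched oxo/non-oxo pairs; unmatched records: %s",
      paste(panel$qsm_id, collapse = ", ")), call. = FALSE)
  }
  list(offset = mean(diffs), n_pairs = length(diffs),
       offset_se = if (length(diffs) > 1L)
         stats::sd(diffs) / sqrt(length(diffs)) else 0,
       differences = diffs)
}

#' Paired bilayer contrast
#'
#' For every molecule present in both bilayers, the difference (DOPC minus
#' POPE/POPG) in `dg_par` and `dg_trans`, with mean and standard error
#' across molecules. Near-zero contrasts indicate the free energies are
#' insensitive to the head-group composition of the two membranes.
#'
#' @param panel a [screening_panel()].
#' @return List with `per_molecule` (data.frame of paired differences) and
#'   `summary` (mean and se of each difference).
#' @export
bilayer_contrast <- function(panel) {
  stopifnot(inherits(panel, "screening_panel"))
  a <- panel[panel$bilayer == "DOPC", ]
  b <- panel[panel$bilayer == "POPE_POPG", ]
  shared <- intersect(a$qsm_id, b$qsm_id)
  if (length(shared) == 0L) {
    stop("no molecules present in both bilayers", call. = FALSE)
  }
  a <- a[match(shared, a$qsm_id), ]
  b <- b[match(shared, b$qsm_id), ]
  per <- data.frame(
    qsm_id = shared,
    d_dg_par = a$dg_par - b$dg_par,
    d_dg_trans = a$dg_trans - b$dg_trans,
    stringsAsFactors = FALSE
  )
  n <- nrow(per)
  se <- function(x) if (n > 1L) stats::sd(x) / sqrt(n) else 0
  list(per_molecule = per,
       summary = list(
         dg_par_mean = mean(per$d_dg_par), dg_par_se = se(per$d_dg_par),
         dg_trans_mean = mean(per$d_dg_trans), dg_trans_se = se(per$d_dg_trans),
         n = n))
}

#' Correlation between partitioning and translocation free energies
#'
#' Pearson correlation and OLS slope of `dg_trans` on `dg_par` across the
#' panel.
#'
#' @param panel a [screening_panel()].
#' @return List with `r`, `slope`, `n`.
#' @export
correlate_par_trans <- function(panel) {
  stopifnot(inherits(panel, "screening_panel"))
  if (nrow(panel) < 3L) stop("need >= 3 records", call. = FALSE)
  if (stats::sd(panel$dg_par) == 0 || stats::sd(panel$dg_trans) == 0) {
    stop("zero variance in dg_par or dg_trans", call. = FALSE)
  }
  r <- stats::cor(panel$dg_par, panel$dg_trans)
  slope <- stats::cov(panel$dg_par, panel$dg_trans) / stats::var(panel$dg_par)
  list(r = r, slope = slope, n = nrow(panel))
}
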