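QSM_ASSAYS <- c("EC50", "IC50")
QSM_ORGANISMS <- c("E_coli", "P_aeruginosa")

#' Activity (potency) records
#'
#' Validates a data.frame of potency measurements: `qsm_id`, `assay`
#' (EC50 or IC50), `organism` (E_coli or P_aeruginosa),
#' `concentration_uM` (> 0) and `source`. One row per
#' (qsm_id, assay, organism).
#'
#' @param records a data.frame with the columns above.
#' @return The validated data.frame with class `activity_records`.
#' @export
activity_records <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("qsm_id", "assay", "organism", "concentration_uM", "source")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop(sprintf("activity table is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!all(records$assay %in% QSM_ASSAYS)) {
    stop(sprintf("assay must be one of %s", paste(QSM_ASSAYS, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(records$organism %in% QSM_ORGANISMS)) {
    stop(sprintf("organism must be one of %s",
                 paste(QSM_ORGANISMS, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(records$concentration_uM)) ||
      any(records$concentration_uM <= 0)) {
    stop("`concentration_uM` must be finite and > 0", call. = FALSE)
  }
  key <- paste(records$qsm_id, records$assay, records$organism)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (qsm_id, assay, organism) rows: %s",
                 paste(unique(key[duplicated(key)]), collapse = "; ")),
         call. = FALSE)
  }
  class(records) <- c("activity_records", "data.frame")
  records
}

#' Join a screening panel with activity records
#'
#' Inner join on `qsm_id`, carrying `dg_par` from one chosen bilayer
#' (default DOPC) and the log10-transformed concentration. Panel molecules
#' without activity data and activity rows without panel entries are
#' reported in the `orphans` attribute rather than silently dropped.
#'
#' @param panel a [screening_panel()].
#' @param activities an [activity_records()] data.frame.
#' @param bilayer which bilayer's dg_par to carry (default `"DOPC"`).
#' @return A data.frame of class `activity_join` with columns `qsm_id`,
#'   `assay`, `organism`, `log10_concentration_uM`, `dg_par`; attribute
#'   `orphans` lists unmatched ids on both sides.
#' @export
merge_activity <- function(panel, activities, bilayer = "DOPC") {
  stopifnot(inherits(panel, "screening_panel"))
  if (!inherits(activities, "activity_records")) {
    activities <- activity_records(activities)
  }
  sub <- panel[panel$bilayer == bilayer, c("qsm_id", "dg_par")]
  joined <- merge(as.data.frame(activities), sub, by = "qsm_id")
  if (nrow(joined) == 0L) {
    stop(sprintf(
      "no shared qsm_id between panel {%s} and activities {%s}",
      paste(unique(sub$qsm_id), collapse = ", "),
      paste(unique(activities$qsm_id), collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    qsm_id = joined$qsm_id, assay = joined$assay, organism = joined$organism,
    log10_concentration_uM = log10(joined$concentration_uM),
    dg_par = joined$dg_par, stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$dg_par)) || any(!is.finite(out$log10_concentration_uM))) {
    stop("joined table contains non-finite values", call. = FALSE)
  }
  attr(out, "orphans") <- list(
    panel_only = setdiff(sub$qsm_id, activities$qsm_id),
    activity_only = setdiff(activities$qsm_id, sub$qsm_id)
  )
  class(out) <- c("activity_join", "data.frame")
  out
}

#' Spearman rank association between dG_par and potency
#'
#' Spearman's rho between the partition free energy and log10
#' concentration, with a permutation p-value: the potency labels are
#' permuted `n_perm` times under a fixed seed and the two-sided p is
#' `(1 + #{|rho*| >= |rho|}) / (n_perm + 1)`. A positive rho means weaker
#' partitioning (less negative dG_par) goes with higher EC50/IC50, i.e.
#' lower potency.
#'
#' @param join an `activity_join` from [merge_activity()].
#' @param assay optional filter: `"EC50"`, `"IC50"` or `"all"` (default:
#'   pool both).
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed for the permutations.
#' @return List with `rho`, `p`, `n`, `n_perm`.
#' @export
rank_correlation <- function(join, assay = "all", n_perm = 1e4, seed = 1) {
  stopifnot(inherits(join, "activity_join"))
  if (!identical(assay, "all")) join <- join[join$assay %in% assay, ]
  n <- nrow(join)
  if (n < 4L) stop("need >= 4 joined rows", call. = FALSE)
  x <- join$dg_par; y <- join$log10_concentration_uM
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("all values tied; rank correlation undefined", call. = FALSE)
  }
  stopifnot_scalar(n_perm, "n_perm", positive = TRUE)
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  n_perm <- as.integer(n_perm)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  exceed <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (abs(stats::cor(rx, sample(ry))) >= abs(rho_obs) - 1e-12) {
        hits <- hits + 1L
      }
    }
    hits
  })
  list(rho = rho_obs, p = (1 + exceed) / (n_perm + 1), n = n,
       n_perm = n_perm)
}

#' Threshold split of potency by partition free energy
#'
#' Splits the joined records at a dG_par cutoff (default -10 kJ/mol) and
#' compares the log10 concentrations of the two groups with a two-sided
#' Wilcoxon rank-sum test — exact when both groups are small (< 50) and
#' tie-free, normal approximation otherwise (the method used is reported).
#' Molecules partitioning more weakly than the cutoff are expected to need
#' higher concentrations to act.
#'
#' @param join an `activity_join`.
#' @param cutoff dG_par cutoff in kJ/mol (default -10).
#' @param assay optional assay filter as in [rank_correlation()].
#' @return List with `median_above`, `median_below` (log10 uM),
#'   `statistic` (rank-sum W), `p`, `method`, `n_above`, `n_below`.
#' @export
threshold_split <- function(join, cutoff = -10, assay = "all") {
  stopifnot(inherits(join, "activity_join"))
  stopifnot_scalar(cutoff, "cutoff")
  if (!identical(assay, "all")) join <- join[join$assay %in% assay, ]
  above <- join$log10_concentration_uM[join$dg_par > cutoff]
  below <- join$log10_concentration_uM[join$dg_par <= cutoff]
  if (length(above) == 0L || length(below) == 0L) {
    stop(sprintf(
      "cutoff %g kJ/mol leaves an empty group (%d above, %d below)",
      cutoff, length(above), length(below)), call. = FALSE)
  }
  exact <- length(above) < 50L && length(below) < 50L &&
    !anyDuplicated(c(above, below))
  wt <- suppressWarnings(
    stats::wilcox.test(above, below, exact = exact, correct = !exact))
  list(median_above = stats::median(above),
       median_below = stats::median(below),
       statistic = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approximation",
       n_above = length(above), n_below = length(below))
}
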