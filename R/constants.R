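#' Gas constant in kJ mol^-1 K^-1
#'
#' CODATA value of the molar gas constant expressed in the energy units used
#' throughout the package (kJ/mol). At the default physiological temperature
#' of 310.15 K, `RT = 2.5787 kJ/mol`.
#'
#' @format A length-one numeric.
#' @export
GAS_CONSTANT_KJ <- 8.314462618e-3

#' Default temperature in kelvin
#'
#' Physiological temperature used as the default for all thermodynamic
#' conversions and samplers.
#'
#' @format A length-one numeric.
#' @export
DEFAULT_TEMPERATURE <- 310.15

#' Thermal energy RT in kJ/mol
#'
#' @param temperature temperature in kelvin (> 0).
#' @return `R * T` in kJ/mol.
#' @examples
#' rt_kj(310.15)  # 2.5787
#' @export
rt_kj <- function(temperature = DEFAULT_TEMPERATURE) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive finite number (kelvin)",
         call. = FALSE)
  }
  GAS_CONSTANT_KJ * temperature
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so generators do not perturb user sessions.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0 (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

# 32-bit FNV-1a hash of a character scalar, returned as 8 hex digits.
# Used to stamp output files with a fingerprint of the run configuration.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte since b < 256; keep h a double so the
    # 32-bit modular multiply stays exact (< 2^53)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
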