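#' @keywords internal
"_PACKAGE"

#' @importFrom stats prcomp rnorm runif sd var predict setNames t.test dist
#' @importFrom utils read.csv write.csv modifyList
#' @importFrom rlang .data hash
NULL

# Canonical ETDRS sector codes: central disc, then inner ring (1) and outer
# ring (2) quadrants in nasal/superior/temporal/inferior order.
ETDRS_SECTORS <- c("C", "N1", "S1", "T1", "I1", "N2", "S2", "T2", "I2")

FLIO_CHANNELS <- c("SSC", "LSC")

# The 15 canonical OCT-A en-face segmentation slabs.
OCTA_SLAB_NAMES <- c(
  "Full", "Vitreoretinal interface", "Retina", "SVC", "NFLVP", "SVP",
  "DVC", "ICP", "DCP", "Avascular complex", "CC", "Choroid", "HL",
  "ILMtoBM40", "SL"
)

SMOKING_LEVELS <- c("non_smoker", "light_smoker", "heavy_smoker")

#' Canonical FLIO feature names
#'
#' The fixed ordering of the 36 per-sector features: modality (mean lifetime
#' first, then intensity), spectral channel (SSC, LSC), then ETDRS sector
#' (C, N1, S1, T1, I1, N2, S2, T2, I2).
#'
#' @return Character vector of length 36.
#' @export
flio_feature_names <- function() {
  as.vector(vapply(c("tau", "intensity"), function(kind) {
    vapply(FLIO_CHANNELS, function(ch) paste(kind, ch, ETDRS_SECTORS, sep = "_"),
           character(length(ETDRS_SECTORS)))
  }, matrix(character(1), length(ETDRS_SECTORS), length(FLIO_CHANNELS))))
}

# Round half away from zero to `digits` decimals (printed-table convention;
# base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic 31-bit seed derived from a base seed and arbitrary mix-in
# values (integers or strings). Plain multiply-add hash modulo a Mersenne
# prime; keeps every derived seed a valid 32-bit R seed.
derive_seed <- function(...) {
  h <- 17
  mix <- function(h, x) (h * 7919 + (x %% 2147483647)) %% 2147483647
  for (p in list(...)) {
    if (is.character(p)) {
      # fold characters one by one: permuted ids ("H01" vs "H10") must differ
      for (cp in utf8ToInt(paste(p, collapse = "|"))) h <- mix(h, cp)
    } else {
      for (x in as.numeric(p)) h <- mix(h, abs(x))
    }
  }
  as.integer(h %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
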