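# Shared fixtures. Cohort generation is the expensive step, so extracted
# feature tables (small) are cached per seed; the bulky image data is
# discarded immediately.

.fixture_cache <- new.env(parent = emptyenv())

# Default-design FLIO cohort (26/14/14 subjects): feature table plus sample
# counts, cached per seed.
cached_flio_features <- function(seed = 11) {
  key <- paste0("flio", seed)
  if (is.null(.fixture_cache[[key]])) {
    gen <- generate_cohort(synthetic_config(seed = seed), modalities = "flio")
    .fixture_cache[[key]] <- list(
      features = extract_cohort_features(gen$cohort),
      n_subjects = length(gen$cohort$subjects),
      n_flio = length(gen$cohort$flio),
      ground_truth = gen$ground_truth$subjects)
  }
  .fixture_cache[[key]]
}

# Small OCT-A cohort (4 non-smokers + 4 heavy smokers, one SVC slab per eye),
# cached per seed.
cached_octa_cohort <- function(seed = 1) {
  key <- paste0("octa", seed)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- synthetic_config(n_non_smokers = 4, n_light = 0, n_heavy = 4,
                            octa_slabs = "SVC", seed = seed)
    .fixture_cache[[key]] <- generate_cohort(cfg, modalities = "octa")$cohort
  }
  .fixture_cache[[key]]
}

# A constant-valued FLIO measurement.
constant_measurement <- function(tau = 250, intensity = 100, n = 64,
                                 subject_id = "S1", eye = "OD") {
  m <- function(v) matrix(v, n, n)
  flio_measurement(subject_id, eye,
                   tau_m = list(SSC = m(tau), LSC = m(tau)),
                   intensity = list(SSC = m(intensity), LSC = m(intensity)))
}

# Brute-force per-pixel ETDRS sector means, written from the geometric
# definition (independent of build_masks): ring by Euclidean mm radius,
# quadrant by |dx| vs |dy| with ties to the horizontal quadrants,
# nasal/temporal by laterality (OD temporal = image left).
brute_force_sector_means <- function(mat, laterality = "OD",
                                     field_of_view_deg = 30, mm_per_degree = 0.3) {
  n <- nrow(mat)
  pitch <- field_of_view_deg * mm_per_degree / n
  ctr <- (n + 1) / 2
  sums <- setNames(numeric(9), c("C", "N1", "S1", "T1", "I1", "N2", "S2", "T2", "I2"))
  cnts <- sums
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dx <- (j - ctr) * pitch
    dy <- (ctr - i) * pitch
    r <- sqrt(dx^2 + dy^2)
    if (r > 3.0) next
    sector <- if (r <= 0.5) "C" else {
      ring <- if (r <= 1.5) "1" else "2"
      quad <- if (dy > abs(dx)) "S" else if (-dy > abs(dx)) "I" else {
        left <- dx < 0
        temporal_left <- (laterality == "OD")
        if (left == temporal_left) "T" else "N"
      }
      paste0(quad, ring)
    }
    v <- mat[i, j]
    if (!is.na(v)) { sums[sector] <- sums[sector] + v; cnts[sector] <- cnts[sector] + 1 }
  }
  ifelse(cnts > 0, sums / cnts, NA_real_)
}
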