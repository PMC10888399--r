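# Synthetic cohort generator. Emulates the statistical design of the
# clinical study (26 non-smokers, 14 light and 14 heavy smokers, two eyes
# each) so that every downstream stage can be exercised and tested without
# patient data. Smoking effects are injected in retinal-mm coordinates from
# the grid geometry's first principles — not by painting the extractor's own
# sector masks — so extractor bugs remain detectable.

#' Synthetic cohort configuration
#'
#' Defaults emulate the clinical design: group sizes 26/14/14, mean-lifetime
#' baselines 240 ps (SSC) and 280 ps (LSC) so typical pixels fall in the
#' 190-350 ps display range, a dose-dependent lifetime increase in the
#' inner-ring SSC and decrease in the outer-ring LSC (linear in cumulative
#' packs, saturating at `dose_saturation_packs`), and intensity fields that
#' carry no group signal. Effect magnitudes in ps are stand-ins (the
#' clinical study reports none); the defaults target a sector-level
#' standardized difference of about 1.2 for fully dosed heavy smokers.
#'
#' @param n_non_smokers,n_light,n_heavy Group sizes (default 26/14/14).
#' @param tau_baseline_ps Named per-channel mean lifetime, ps.
#' @param tau_between_subject_sd_ps Between-subject SD of the shared (both
#'   eyes) lifetime offset, ps.
#' @param tau_spatial_sd_ps SD of the smooth spatial lifetime field, ps.
#' @param spatial_correlation_px Gaussian blur radius of the spatial field.
#' @param eye_noise_sd_ps SD of the per-eye scalar lifetime offset, ps.
#' @param effect_ir_ssc_ps Maximum (fully dosed) smoker increase of
#'   inner-ring SSC lifetime, ps.
#' @param effect_or_lsc_ps Maximum smoker change of outer-ring LSC lifetime,
#'   ps (negative = shortening).
#' @param dose_saturation_packs Cumulative packs at which the dose factor
#'   saturates at 1.
#' @param intensity_mean_counts,intensity_sd_counts Intensity baseline and
#'   total SD (split 0.6/0.75/0.28 between subject, spatial and eye
#'   components in quadrature).
#' @param octa_vessel_density Target foreground fraction of OCT-A vessel
#'   masks.
#' @param octa_effect Per-slab density delta applied as `octa_effect * dose`
#'   (default 0: OCT-A carries no group signal, matching the study's
#'   negative OCT-A result).
#' @param octa_slabs Slab names to generate per eye (default SVC and DCP,
#'   the two slabs the downstream analyses use; any of the 15 canonical
#'   names may be requested).
#' @param foveal_dip_ps Optional central lifetime dip (0 = off).
#' @param seed Base RNG seed; every subject/eye stream is derived from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_non_smokers = 26, n_light = 14, n_heavy = 14,
                             tau_baseline_ps = c(SSC = 240, LSC = 280),
                             tau_between_subject_sd_ps = 12,
                             tau_spatial_sd_ps = 10,
                             spatial_correlation_px = 8,
                             eye_noise_sd_ps = 4,
                             effect_ir_ssc_ps = 15,
                             effect_or_lsc_ps = -15,
                             dose_saturation_packs = 5000,
                             intensity_mean_counts = 300,
                             intensity_sd_counts = 60,
                             octa_vessel_density = 0.12,
                             octa_effect = 0,
                             octa_slabs = c("SVC", "DCP"),
                             foveal_dip_ps = 0,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_non_smokers < 0 || cfg$n_light < 0 || cfg$n_heavy < 0)
    stop("synthetic_config: group sizes must be >= 0")
  stopifnot(tau_between_subject_sd_ps >= 0, tau_spatial_sd_ps >= 0,
            eye_noise_sd_ps >= 0, intensity_sd_counts >= 0,
            intensity_mean_counts >= 0, octa_vessel_density >= 0,
            all(octa_slabs %in% OCTA_SLAB_NAMES))
  structure(cfg, class = "synthetic_config")
}

subject_dose <- function(cumulative_packs, config) {
  pmin(cumulative_packs / config$dose_saturation_packs, 1)
}

# Subject-level latent parameters, shared by both eyes (derived
# deterministically from the cohort seed + subject id).
subject_latents <- function(subject, config) {
  withr::with_seed(derive_seed(config$seed, subject$subject_id, "subject"), {
    list(tau_offset = rnorm(2, 0, config$tau_between_subject_sd_ps),
         int_offset = rnorm(2, 0, 0.6 * config$intensity_sd_counts))
  })
}

smooth_field <- function(n, sigma, target_sd) {
  z <- matrix(rnorm(n * n), n, n)
  if (sigma > 0) z <- EBImage::gblur(z, sigma = sigma)
  s <- sd(as.vector(z))
  if (s > 0) z <- z / s * target_sd
  z
}

# Effect annuli computed from first principles in retinal mm (30 deg FOV,
# 0.3 mm/deg): deliberately an independent code path from build_masks().
effect_annuli <- function(n) {
  pitch <- 30 * 0.3 / n
  d <- (seq_len(n) - (n + 1) / 2) * pitch
  r <- sqrt(outer(d^2, d^2, `+`))
  list(inner = r > 0.5 & r <= 1.5, outer = r > 1.5 & r <= 3.0, r = r)
}

#' Generate one eye's synthetic FLIO measurement
#'
#' Each lifetime field is `baseline + subject offset + smooth spatial field +
#' eye offset + dose effect`, the effect adding `dose * effect_ir_ssc_ps`
#' inside the inner-ring annulus (SSC only) and `dose * effect_or_lsc_ps`
#' inside the outer-ring annulus (LSC only). Intensity fields share the
#' structure but carry no dose term. Deterministic given the config seed,
#' subject id and eye.
#'
#' @param subject A [subject_record()].
#' @param eye `"OD"` or `"OS"`.
#' @param config A [synthetic_config()].
#' @param n Image side length (default 256).
#' @return A [flio_measurement()].
#' @export
generate_flio <- function(subject, eye, config = synthetic_config(), n = 256) {
  lat <- subject_latents(subject, config)
  dose <- subject_dose(subject$cumulative_packs, config)
  ann <- effect_annuli(n)
  int_spatial_sd <- 0.75 * config$intensity_sd_counts
  int_eye_sd <- 0.28 * config$intensity_sd_counts
  withr::with_seed(derive_seed(config$seed, subject$subject_id, eye, "flio"), {
    tau <- list(); intensity <- list()
    for (i in seq_along(FLIO_CHANNELS)) {
      ch <- FLIO_CHANNELS[i]
      f <- config$tau_baseline_ps[[ch]] + lat$tau_offset[i] +
        smooth_field(n, config$spatial_correlation_px, config$tau_spatial_sd_ps) +
        rnorm(1, 0, config$eye_noise_sd_ps)
      if (ch == "SSC") f <- f + dose * config$effect_ir_ssc_ps * ann$inner
      if (ch == "LSC") f <- f + dose * config$effect_or_lsc_ps * ann$outer
      if (config$foveal_dip_ps != 0)
        f <- f - config$foveal_dip_ps * exp(-(ann$r / 0.4)^2)
      tau[[ch]] <- pmin(pmax(f, 1), 4999)
      g <- config$intensity_mean_counts + lat$int_offset[i] +
        smooth_field(n, config$spatial_correlation_px, int_spatial_sd) +
        rnorm(1, 0, int_eye_sd)
      intensity[[ch]] <- pmax(g, 0)
    }
    flio_measurement(subject$subject_id, eye, tau, intensity)
  })
}

#' Generate one eye's synthetic OCT-A slab stack
#'
#' Each slab is a rasterized stochastic branching vessel tree: biased random
#' walks started at random border points, branching with small probability,
#' stroke widths 1-4 px, grown until the binary mask reaches the target
#' density, then Gaussian-blurred and quantized to \[0, 255\]. When
#' `octa_effect` is non-zero the target density is shifted by
#' `octa_effect * dose`.
#'
#' @inheritParams generate_flio
#' @param n Image side length (default 512).
#' @return An [octa_slab_stack()].
#' @export
generate_octa <- function(subject, eye, config = synthetic_config(), n = 512) {
  dose <- subject_dose(subject$cumulative_packs, config)
  target <- max(0, min(0.6, config$octa_vessel_density + config$octa_effect * dose))
  slabs <- list()
  for (slab in config$octa_slabs) {
    slabs[[slab]] <- withr::with_seed(
      derive_seed(config$seed, subject$subject_id, eye, "octa", slab),
      rasterize_vessel_tree(n, target))
  }
  octa_slab_stack(subject$subject_id, eye, slabs)
}

# Stamp biased branching random walks onto an n x n mask until `target`
# foreground fraction is reached, then blur + quantize to 8 bits.
rasterize_vessel_tree <- function(n, target) {
  mask <- matrix(FALSE, n, n)
  if (target <= 0) return(matrix(0L, n, n))
  npx <- n * n
  disc_offsets <- function(w) {
    r <- (w - 1) / 2
    g <- expand.grid(dr = -ceiling(r):ceiling(r), dc = -ceiling(r):ceiling(r))
    g[g$dr^2 + g$dc^2 <= r^2 + 0.25, ]
  }
  discs <- lapply(1:4, disc_offsets)
  covered <- 0
  guard <- 0
  while (covered / npx < target && guard < 5000) {
    guard <- guard + 1
    # seed on a random border point, heading inward
    side <- sample.int(4, 1)
    pos <- switch(side,
                  c(1, runif(1, 1, n)), c(n, runif(1, 1, n)),
                  c(runif(1, 1, n), 1), c(runif(1, 1, n), n))
    ang <- atan2((n / 2 - pos[1]), (n / 2 - pos[2])) + rnorm(1, 0, 0.5)
    width <- sample(1:4, 1, prob = c(0.35, 0.35, 0.2, 0.1))
    stack <- list(list(pos = pos, ang = ang, width = width, len = 0))
    while (length(stack) && covered / npx < target) {
      b <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      pos <- b$pos; ang <- b$ang; width <- b$width
      for (step in seq_len(400 - b$len)) {
        pos <- pos + c(sin(ang), cos(ang))
        if (any(pos < 1) || any(pos > n)) break
        ang <- ang + rnorm(1, 0, 0.22)
        d <- discs[[width]]
        rr <- round(pos[1]) + d$dr; cc <- round(pos[2]) + d$dc
        ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
        idx <- cbind(rr[ok], cc[ok])
        new <- !mask[idx]
        if (any(new)) {
          mask[idx[new, , drop = FALSE]] <- TRUE
          covered <- covered + sum(new)
        }
        if (runif(1) < 0.025) {
          stack[[length(stack) + 1]] <- list(
            pos = pos, ang = ang + sample(c(-1, 1), 1) * runif(1, 0.5, 1.1),
            width = max(1, width - sample(0:1, 1)), len = b$len + step)
        }
      }
    }
  }
  img <- EBImage::gblur(mask * 1, sigma = 1)
  img <- pmax(img, 0)
  if (max(img) > 0) img <- img / max(img)
  out <- matrix(as.integer(round(img * 255)), n, n)
  # foreground fraction of the pre-blur binary mask, kept for auditing
  attr(out, "mask_density") <- covered / npx
  out
}

#' Generate a synthetic cohort
#'
#' Builds `n_non_smokers + n_light + n_heavy` subjects with two eyes each.
#' Light smokers' cumulative consumption is sampled uniformly in
#' (500, 2500] packs, heavy smokers' in (2500, 8000]. Deterministic given
#' the config seed (every subject/eye RNG stream is derived from it).
#'
#' @param config A [synthetic_config()].
#' @param modalities Which modalities to generate: subset of
#'   `c("flio", "octa")`.
#' @return List with `cohort` (a [cohort_dataset()]) and `ground_truth`
#'   (per-subject dose factors and injected effects).
#' @export
generate_cohort <- function(config = synthetic_config(),
                            modalities = c("flio", "octa")) {
  stopifnot(inherits(config, "synthetic_config"))
  modalities <- match.arg(modalities, several.ok = TRUE)
  groups <- rep(c("non", "light", "heavy"),
                c(config$n_non_smokers, config$n_light, config$n_heavy))
  ids <- sprintf("%s%02d", toupper(substr(groups, 1, 1)),
                 unlist(lapply(split(seq_along(groups), groups)[unique(groups)], seq_along)))
  subjects <- withr::with_seed(derive_seed(config$seed, "subjects"), {
    lapply(seq_along(groups), function(i) {
      packs <- switch(groups[i], non = 0,
                      light = runif(1, 500, 2500),
                      heavy = runif(1, 2500, 8000))
      if (groups[i] == "light") packs <- max(packs, 500 + 1e-6)
      years <- if (groups[i] == "non") 0 else runif(1, 2, 20)
      subject_record(ids[i], age = round(runif(1, 20, 40)),
                     sex = sample(c("F", "M"), 1), years_smoked = years,
                     cumulative_packs = packs)
    })
  })
  flio <- list(); octa <- list()
  for (s in subjects) {
    for (eye in c("OD", "OS")) {
      if ("flio" %in% modalities)
        flio[[length(flio) + 1]] <- generate_flio(s, eye, config)
      if ("octa" %in% modalities && length(config$octa_slabs))
        octa[[length(octa) + 1]] <- generate_octa(s, eye, config)
    }
  }
  gt <- data.frame(
    subject_id = ids, group = groups,
    cumulative_packs = vapply(subjects, `[[`, numeric(1), "cumulative_packs"),
    stringsAsFactors = FALSE)
  gt$dose <- subject_dose(gt$cumulative_packs, config)
  gt$effect_ir_ssc_ps <- gt$dose * config$effect_ir_ssc_ps
  gt$effect_or_lsc_ps <- gt$dose * config$effect_or_lsc_ps
  list(cohort = cohort_dataset(subjects, flio, octa),
       ground_truth = list(subjects = gt, seed = config$seed,
                           config = unclass(config)))
}
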