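test_that("the default design yields 54 subjects and 108 FLIO samples", {
  fx <- cached_flio_features()
  expect_equal(fx$n_subjects, 54)
  expect_equal(fx$n_flio, 108)
  st <- table(fx$ground_truth$group)
  expect_equal(unname(st[c("non", "light", "heavy")]), c(26L, 14L, 14L),
               ignore_attr = TRUE)
  # light in (500, 2500], heavy in (2500, 8000], dose in [0, 1], non-smokers 0
  gt <- fx$ground_truth
  expect_true(all(gt$cumulative_packs[gt$group == "light"] > 500 &
                    gt$cumulative_packs[gt$group == "light"] <= 2500))
  expect_true(all(gt$cumulative_packs[gt$group == "heavy"] > 2500 &
                    gt$cumulative_packs[gt$group == "heavy"] <= 8000))
  expect_true(all(gt$dose >= 0 & gt$dose <= 1))
  expect_true(all(gt$dose[gt$group == "non"] == 0))
})

test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(n_non_smokers = 2, n_light = 1, n_heavy = 1,
                          octa_slabs = "SVC", seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort$flio, b$cohort$flio)
  expect_identical(a$cohort$octa, b$cohort$octa)
  expect_identical(a$ground_truth$subjects, b$ground_truth$subjects)
  c2 <- generate_cohort(synthetic_config(n_non_smokers = 2, n_light = 1,
                                         n_heavy = 1, octa_slabs = "SVC",
                                         seed = 78))
  expect_false(identical(a$cohort$flio[[1]]$tau_m$SSC, c2$cohort$flio[[1]]$tau_m$SSC))
})

test_that("per-subject and per-eye RNG streams never collide in a default cohort", {
  cfg <- synthetic_config()
  groups <- rep(c("N", "L", "H"), c(26, 14, 14))
  ids <- sprintf("%s%02d", groups, c(1:26, 1:14, 1:14))
  seeds <- c(
    vapply(ids, function(id) fliopipe:::derive_seed(cfg$seed, id, "subject"), integer(1)),
    vapply(ids, function(id) fliopipe:::derive_seed(cfg$seed, id, "OD", "flio"), integer(1)),
    vapply(ids, function(id) fliopipe:::derive_seed(cfg$seed, id, "OS", "flio"), integer(1)))
  expect_equal(anyDuplicated(seeds), 0)
})

test_that("non-smokers have no lifetime effect; saturated heavy smokers have the full one", {
  cfg <- synthetic_config(seed = 21)
  masks <- build_masks(grid_geometry())
  ir_ssc_mean <- function(m) {
    mean(vapply(c("N1", "S1", "T1", "I1"),
                function(s) mean(m$tau_m$SSC[masks[[s]]]), numeric(1)))
  }
  # Monte-Carlo over 100 independent eyes per group
  non <- subject_record("MCnon", 30, "F", 0, 0)
  sat <- subject_record("MCsat", 30, "F", 20, 6000)  # dose saturates at 5000
  reps <- 100
  vals <- vapply(seq_len(reps), function(i) {
    cfg_i <- synthetic_config(seed = 1000 + i)
    c(ir_ssc_mean(generate_flio(non, "OD", cfg_i)),
      ir_ssc_mean(generate_flio(sat, "OD", cfg_i)))
  }, numeric(2))
  se <- sd(vals[1, ]) / sqrt(reps)
  expect_lt(abs(mean(vals[1, ]) - 240), 3 * se + 1e-9)          # baseline, no effect
  se2 <- sd(vals[2, ] - vals[1, ]) / sqrt(reps)
  expect_lt(abs(mean(vals[2, ] - vals[1, ]) - 15), 3 * se2)     # full +15 ps effect
})

test_that("effects are local to IR-SSC and OR-LSC and dose-monotone", {
  fx <- cached_flio_features()
  ft <- fx$features
  gt <- fx$ground_truth
  dose <- setNames(gt$dose, gt$subject_id)[ft$subject_id]
  grp_diff <- function(col) {
    mean(ft[[col]][ft$label == "heavy_smoker"]) -
      mean(ft[[col]][ft$label == "non_smoker"])
  }
  effect_cols <- c(paste0("tau_SSC_", c("N1", "S1", "T1", "I1")),
                   paste0("tau_LSC_", c("N2", "S2", "T2", "I2")))
  null_cols <- setdiff(grep("^tau_", flio_feature_names(), value = TRUE), effect_cols)
  # mean |difference| outside the effect regions well below the injected size
  expect_lt(mean(abs(vapply(null_cols, grp_diff, numeric(1)))), 0.4 * 15)
  expect_gt(mean(vapply(effect_cols[1:4], grp_diff, numeric(1))), 5)   # IR-SSC up
  expect_lt(mean(vapply(effect_cols[5:8], grp_diff, numeric(1))), -5)  # OR-LSC down
  # dose monotonicity of the IR-SSC sector mean: holding the subject's RNG
  # streams fixed and sweeping only cumulative packs isolates the dose term
  cfg <- synthetic_config(seed = 40)
  masks <- build_masks(grid_geometry())
  ir_mean <- function(packs) {
    s <- subject_record("SWEEP", 30, "F", max(packs > 0) * 10, packs)
    m <- generate_flio(s, "OD", cfg)
    mean(vapply(c("N1", "S1", "T1", "I1"),
                function(x) mean(m$tau_m$SSC[masks[[x]]]), numeric(1)))
  }
  sweep_vals <- vapply(c(0, 1000, 2500, 4000, 5000, 7000), ir_mean, numeric(1))
  expect_true(all(diff(sweep_vals) >= -1e-9))
  expect_equal(sweep_vals[6], sweep_vals[5])          # saturated at 5000 packs
  expect_equal(sweep_vals[5] - sweep_vals[1], 15)     # full effect size
})

test_that("two eyes of a subject are more alike than eyes of different subjects", {
  fx <- cached_flio_features()
  ft <- fx$features
  feats <- scale(as.matrix(as.data.frame(ft)[, flio_feature_names()]))
  within <- c(); between <- c()
  ids <- unique(ft$subject_id)
  for (id in ids) {
    rows <- which(ft$subject_id == id)
    if (length(rows) == 2)
      within <- c(within, sqrt(sum((feats[rows[1], ] - feats[rows[2], ])^2)))
  }
  set.seed(2)
  for (i in 1:200) {
    pair <- sample(nrow(feats), 2)
    if (ft$subject_id[pair[1]] != ft$subject_id[pair[2]])
      between <- c(between, sqrt(sum((feats[pair[1], ] - feats[pair[2], ])^2)))
  }
  expect_lt(mean(within), mean(between))
})

test_that("intensity features carry no group signal", {
  ps <- unlist(lapply(11:13, function(seed) {
    fx <- cached_flio_features(seed)
    ft <- fx$features[fx$features$label != "light_smoker", ]
    vapply(grep("^intensity_", flio_feature_names(), value = TRUE), function(col)
      t.test(ft[[col]][ft$label == "heavy_smoker"],
             ft[[col]][ft$label == "non_smoker"], var.equal = TRUE)$p.value,
      numeric(1))
  }))
  # features within a cohort are correlated (shared subject offsets), so
  # judge the fraction across three independent cohorts loosely
  expect_gt(mean(ps > 0.01), 0.7)
})

test_that("vessel masks hit the target density and zero density gives a blank slab", {
  s <- subject_record("T1", 30, "F", 10, 3000)
  st <- generate_octa(s, "OD", synthetic_config(octa_slabs = "SVC", seed = 31))
  expect_lt(abs(attr(st$slabs$SVC, "mask_density") - 0.12), 0.03)
  expect_true(all(st$slabs$SVC >= 0 & st$slabs$SVC <= 255))

  blank <- generate_octa(s, "OD", synthetic_config(octa_slabs = "SVC",
                                                   octa_vessel_density = 0, seed = 31))
  expect_true(all(blank$slabs$SVC == 0))
})

test_that("with zero OCT-A effect, slab statistics are independent of group", {
  pvals <- vapply(1:5, function(seed) {
    cohort <- cached_octa_cohort(seed)
    means <- vapply(cohort$octa, function(m) mean(m$slabs$SVC), numeric(1))
    heavy <- vapply(cohort$octa, function(m)
      grepl("^H", m$subject_id), logical(1))
    t.test(means[heavy], means[!heavy], var.equal = TRUE)$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.05), 4)
})
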