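test_that("sector masks partition the grid disc with near-ideal areas", {
  g <- grid_geometry()
  masks <- build_masks(g)
  overlap <- Reduce(`+`, lapply(masks, as.numeric))
  expect_lte(max(overlap), 1)  # pairwise disjoint
  r_mm <- fliopipe:::grid_polar(g)$r
  expect_equal(sum(overlap), sum(r_mm <= 3.0))  # union == disc, exactly

  # pixel counts within 1% of the ideal ring areas (pi r^2 in px^2)
  r_px <- c(0.5, 1.5, 3.0) / g$mm_per_px
  ideal <- pi * r_px^2
  expect_lt(abs(sum(masks$C) - ideal[1]) / ideal[1], 0.01)
  inner <- sum(masks$N1) + sum(masks$S1) + sum(masks$T1) + sum(masks$I1)
  outer <- sum(masks$N2) + sum(masks$S2) + sum(masks$T2) + sum(masks$I2)
  expect_lt(abs(inner - (ideal[2] - ideal[1])) / (ideal[2] - ideal[1]), 0.01)
  expect_lt(abs(outer - (ideal[3] - ideal[2])) / (ideal[3] - ideal[2]), 0.01)

  # centre pixels carry the central sector
  expect_true(masks$C[128, 128] && masks$C[129, 129])
})

test_that("OD and OS grids are exact mirrors: N and T swap, S/I/C identical", {
  od <- build_masks(grid_geometry(laterality = "OD"))
  os <- build_masks(grid_geometry(laterality = "OS"))
  for (ring in c("1", "2")) {
    expect_identical(od[[paste0("N", ring)]], os[[paste0("T", ring)]])
    expect_identical(od[[paste0("T", ring)]], os[[paste0("N", ring)]])
    expect_identical(od[[paste0("S", ring)]], os[[paste0("S", ring)]])
    expect_identical(od[[paste0("I", ring)]], os[[paste0("I", ring)]])
  }
  expect_identical(od$C, os$C)
})

test_that("a grid larger than the field of view is rejected", {
  # 15 deg at 0.3 mm/deg spans 4.5 mm; the 6 mm grid cannot fit
  expect_error(grid_geometry(field_of_view_deg = 15), "exceeds")
})

test_that("sector means match a per-pixel brute-force oracle", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(rnorm(256 * 256, 250, 40), 256, 256)
    for (lat in c("OD", "OS")) {
      got <- sector_mean(m, build_masks(grid_geometry(laterality = lat)))
      ref <- brute_force_sector_means(m, laterality = lat)
      expect_equal(got, ref, tolerance = 1e-12)
    }
  }
})

test_that("sector means are missing-aware", {
  g <- grid_geometry(image_shape = c(64, 64), field_of_view_deg = 30)
  masks <- build_masks(g)
  m <- matrix(5, 64, 64)
  expect_equal(unname(sector_mean(m, masks)), rep(5, 9))

  # NA over half of C: mean over the valid half only
  c_idx <- which(masks$C)
  m[c_idx[seq_len(length(c_idx) %/% 2)]] <- NA
  m[masks$C & !is.na(m)] <- 7
  expect_equal(unname(sector_mean(m, masks)["C"]), 7)

  # fully-NA sector -> NA
  m[masks$C] <- NA
  expect_true(is.na(sector_mean(m, masks)["C"]))

  expect_error(sector_mean(matrix(1, 32, 32), masks), "shape")
})

test_that("extracting from an OS eye equals extracting its mirrored image as OD", {
  set.seed(9)
  mk <- function(eye) {
    mats <- replicate(4, matrix(rnorm(256^2, 260, 30), 256), simplify = FALSE)
    flio_measurement("s", eye, tau_m = list(SSC = mats[[1]], LSC = mats[[2]]),
                     intensity = list(SSC = mats[[3]], LSC = mats[[4]]))
  }
  m_os <- mk("OS")
  mirror <- function(x) x[, ncol(x):1]
  m_od <- flio_measurement("s", "OD",
                           tau_m = lapply(m_os$tau_m, mirror),
                           intensity = lapply(m_os$intensity, mirror))
  expect_equal(extract_features(m_os), extract_features(m_od), tolerance = 1e-14)
})

test_that("feature vectors have 36 canonically ordered values", {
  m <- constant_measurement(tau = 250, intensity = 100)
  v <- extract_features(m)
  expect_length(v, 36)
  expect_identical(names(v), flio_feature_names())
  expect_equal(unname(v[grep("^tau_", names(v))]), rep(250, 18))
  expect_equal(unname(v[grep("^intensity_", names(v))]), rep(100, 18))
})

test_that("named subsets have the published cardinalities and contents", {
  expected_n <- c(all = 36, intensity = 18, tau_m = 18, tau_ssc = 9, tau_lsc = 9,
                  tau_ir = 8, tau_or = 8, tau_ir_ssc_or_lsc = 8,
                  tau_or_ssc_ir_lsc = 8)
  for (nm in names(expected_n))
    expect_length(fliopipe:::flio_subset_columns(nm), expected_n[[nm]])
  expect_setequal(fliopipe:::flio_subset_columns("tau_ir_ssc_or_lsc"),
                  c(paste0("tau_SSC_", c("N1", "S1", "T1", "I1")),
                    paste0("tau_LSC_", c("N2", "S2", "T2", "I2"))))
  expect_false(any(grepl("_C$", fliopipe:::flio_subset_columns("tau_ir"))))
  expect_error(fliopipe:::flio_subset_columns("bogus"), "unknown feature subset")
})

test_that("select_subset filters columns and keeps identifier columns", {
  fx <- cached_flio_features()
  sel <- select_subset(fx$features, "tau_lsc")
  expect_identical(feature_names(sel), fliopipe:::flio_subset_columns("tau_lsc"))
  expect_identical(select_subset(fx$features, "all")[, flio_feature_names()],
                   fx$features[, flio_feature_names()])
  top3 <- select_subset(fx$features, "ttest_top3",
                        labels = ifelse(fx$features$label == "non_smoker", "n", "s"))
  expect_length(feature_names(top3), 3)
  expect_true(all(grepl("^tau_", feature_names(top3))))
  expect_error(select_subset(fx$features, c("tau_SSC_C", "nope")), "unknown feature column")
})

test_that("t-test ranking matches the pooled-variance closed form", {
  df <- feature_table(data.frame(
    subject_id = sprintf("s%d", 1:6), eye = "OD",
    label = rep(c("A", "B"), each = 3), f = c(1, 2, 3, 4, 5, 6),
    stringsAsFactors = FALSE))
  res <- ttest_rank(df, labels = df$label)
  # t = (2 - 5) / (1 * sqrt(1/3 + 1/3)) = -3.674, df = 4
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$p, 0.021312, tolerance = 1e-4)
  expect_equal(res$pooled_sd, 1)
  expect_equal(res$df, 4)

  # identical groups: t = 0, p = 1
  df$f <- rep(c(1, 2, 3), 2)
  res0 <- ttest_rank(df, labels = df$label)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  expect_error(ttest_rank(df[c(1, 4, 5), ], labels = df$label[c(1, 4, 5)]),
               "at least 2 rows")
})

test_that("t-test ranking puts true-effect sectors on top for synthetic cohorts", {
  effect_cols <- c(paste0("tau_SSC_", c("N1", "S1", "T1", "I1")),
                   paste0("tau_LSC_", c("N2", "S2", "T2", "I2")))
  hits <- 0
  for (seed in 11:13) {
    fx <- cached_flio_features(seed)
    ft <- fx$features[fx$features$label != "light_smoker", ]
    rk <- ttest_rank(ft, ft$label, features = fliopipe:::flio_subset_columns("tau_m"))
    hits <- hits + (all(rk$feature[1:3] %in% effect_cols))
  }
  expect_gte(hits, 2)
})
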