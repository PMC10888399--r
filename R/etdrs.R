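# ETDRS grid geometry and sectorization of FLIO matrices into the 36-feature
# vector, named feature subsets, and t-test feature ranking.

#' ETDRS grid geometry
#'
#' Describes how the standard ETDRS macular grid (1 / 3 / 6 mm ring
#' diameters around the fovea, rings split into nasal / superior / temporal /
#' inferior quadrants) maps onto a square fundus image. The fovea is taken as
#' the image centre. Pixel pitch follows the emmetropic approximation
#' `field_of_view_deg * mm_per_degree / image extent` (30 deg ~ 9.0 mm for
#' FLIO, so ~0.035 mm per pixel at 256 x 256).
#'
#' @param image_shape Integer c(rows, cols); must be square here.
#' @param field_of_view_deg Field of view in degrees (FLIO: 30; OCT-A: 20).
#' @param mm_per_degree Retinal scale, mm per degree (default 0.3).
#' @param ring_diameters_mm Strictly increasing c(central, inner, outer)
#'   diameters in mm; default c(1, 3, 6).
#' @param laterality `"OD"` (right eye; temporal on image left) or `"OS"`
#'   (mirrored).
#' @param center Fovea position in pixel coordinates c(row, col); default the
#'   geometric image centre `(n + 1) / 2`.
#' @param temporal_side Which image side is temporal for an OD eye; `"left"`
#'   (default, fundus-photograph convention) or `"right"`. Recorded so that a
#'   different display convention relabels rather than silently corrupts the
#'   nasal/temporal features.
#' @return A `grid_geometry`.
#' @export
grid_geometry <- function(image_shape = c(256, 256), field_of_view_deg = 30,
                          mm_per_degree = 0.3, ring_diameters_mm = c(1, 3, 6),
                          laterality = c("OD", "OS"), center = NULL,
                          temporal_side = c("left", "right")) {
  laterality <- match.arg(laterality)
  temporal_side <- match.arg(temporal_side)
  stopifnot(length(image_shape) == 2, image_shape[1] == image_shape[2],
            all(diff(ring_diameters_mm) > 0), length(ring_diameters_mm) == 3)
  if (is.null(center)) center <- (image_shape + 1) / 2
  mm_per_px <- field_of_view_deg * mm_per_degree / image_shape[1]
  outer_px <- (ring_diameters_mm[3] / 2) / mm_per_px
  if (outer_px > min(image_shape) / 2 + 1e-9)
    stop(sprintf("grid_geometry: outer ring radius (%.1f px) exceeds image half-extent (%d px)",
                 outer_px, min(image_shape) %/% 2))
  structure(list(image_shape = as.integer(image_shape),
                 field_of_view_deg = field_of_view_deg,
                 mm_per_degree = mm_per_degree, mm_per_px = mm_per_px,
                 ring_diameters_mm = ring_diameters_mm, laterality = laterality,
                 center = center, temporal_side = temporal_side),
            class = "grid_geometry")
}

# Per-pixel radius (mm) and displacement components from the grid centre.
# dy is positive toward the top of the image (superior); dx positive to the
# image right.
grid_polar <- function(geometry) {
  n <- geometry$image_shape
  row <- matrix(seq_len(n[1]), n[1], n[2])
  col <- matrix(seq_len(n[2]), n[1], n[2], byrow = TRUE)
  dx <- (col - geometry$center[2]) * geometry$mm_per_px
  dy <- (geometry$center[1] - row) * geometry$mm_per_px
  list(dx = dx, dy = dy, r = sqrt(dx^2 + dy^2))
}

#' Build the nine ETDRS sector masks
#'
#' Ring membership is by Euclidean distance in mm from the centre (central
#' disc `r <= 0.5`, inner ring `0.5 < r <= 1.5`, outer ring `1.5 < r <= 3.0`
#' at the default diameters). Quadrants split on the +/-45 degree diagonals:
#' superior above, inferior below, nasal/temporal left/right resolved by
#' laterality. Pixels exactly on a diagonal join the horizontal
#' (nasal/temporal) quadrant on both sides — the unique deterministic
#' tie-break under which OD and OS grids are exact mirror images of each
#' other (see the methods vignette).
#'
#' @param geometry A [grid_geometry()].
#' @return A named list of nine disjoint logical masks
#'   (`C`, `N1`, `S1`, `T1`, `I1`, `N2`, `S2`, `T2`, `I2`) whose union is the
#'   disc of pixels within the outer ring radius.
#' @export
build_masks <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  p <- grid_polar(geometry)
  radii <- geometry$ring_diameters_mm / 2
  central <- p$r <= radii[1]
  inner <- p$r > radii[1] & p$r <= radii[2]
  outer <- p$r > radii[2] & p$r <= radii[3]
  sup <- p$dy > abs(p$dx)
  inf <- -p$dy > abs(p$dx)
  left <- p$dx < 0 & !sup & !inf
  right <- p$dx > 0 & !sup & !inf
  # pixels with dx == dy == 0 (exact centre) are in the central disc anyway
  od_temporal_left <- (geometry$temporal_side == "left")
  t_side <- if (xor(geometry$laterality == "OS", od_temporal_left)) left else right
  n_side <- if (xor(geometry$laterality == "OS", od_temporal_left)) right else left
  masks <- list(C = central,
                N1 = inner & n_side, S1 = inner & sup, T1 = inner & t_side, I1 = inner & inf,
                N2 = outer & n_side, S2 = outer & sup, T2 = outer & t_side, I2 = outer & inf)
  masks
}

#' Missing-aware sector means
#'
#' @param matrix Numeric matrix matching the mask shape.
#' @param masks Sector masks from [build_masks()].
#' @return Named numeric vector of nine means; a sector with no valid pixel
#'   is `NA`.
#' @export
sector_mean <- function(matrix, masks) {
  if (!identical(dim(matrix), dim(masks[[1]])))
    stop("sector_mean: matrix shape does not match masks")
  vapply(masks, function(m) {
    v <- matrix[m]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Extract the 36 ETDRS features from one FLIO measurement
#'
#' Applies [sector_mean()] to each of the four matrices (mean lifetime and
#' intensity, SSC and LSC) with laterality-aware grid geometry, returning
#' features in the canonical [flio_feature_names()] order.
#'
#' @param m A [flio_measurement()].
#' @param geometry Optional [grid_geometry()]; by default built for the
#'   measurement's image shape and eye.
#' @return Named numeric vector of length 36.
#' @export
extract_features <- function(m, geometry = NULL) {
  stopifnot(inherits(m, "flio_measurement"))
  if (is.null(geometry)) {
    geometry <- grid_geometry(image_shape = dim(m$tau_m$SSC), laterality = m$eye)
  } else if (geometry$laterality != m$eye) {
    geometry <- modifyList(geometry, list(laterality = m$eye))
    class(geometry) <- "grid_geometry"
  }
  masks <- build_masks(geometry)
  out <- c(vapply(FLIO_CHANNELS, function(ch) sector_mean(m$tau_m[[ch]], masks),
                  numeric(9)),
           vapply(FLIO_CHANNELS, function(ch) sector_mean(m$intensity[[ch]], masks),
                  numeric(9)))
  setNames(as.vector(out), flio_feature_names())
}

#' Extract the FLIO feature table for a whole cohort
#'
#' @param cohort A [cohort_dataset()].
#' @param geometry Optional [grid_geometry()] template (laterality is set per
#'   eye).
#' @return A [feature_table()] with one row per FLIO sample, labelled with
#'   the subject's smoking status.
#' @export
extract_cohort_features <- function(cohort, geometry = NULL) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  status <- setNames(vapply(cohort$subjects, `[[`, character(1), "smoking_status"),
                     vapply(cohort$subjects, `[[`, character(1), "subject_id"))
  rows <- lapply(cohort$flio, function(m) {
    cbind(data.frame(subject_id = m$subject_id, eye = m$eye,
                     label = unname(status[m$subject_id]), stringsAsFactors = FALSE),
          as.data.frame(as.list(extract_features(m, geometry))))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(c(list(subject_id = character(), eye = character(), label = character()),
                    setNames(rep(list(numeric()), 36), flio_feature_names())))
  feature_table(df)
}

# Named FLIO feature subsets (column-name lists). Ring subsets exclude the
# central disc; counts match the published result tables (36/18/18/9/9/8/8/8/8/3).
flio_subset_columns <- function(subset) {
  tau <- function(ch, sectors) paste("tau", ch, sectors, sep = "_")
  ir <- c("N1", "S1", "T1", "I1"); or <- c("N2", "S2", "T2", "I2")
  all36 <- flio_feature_names()
  switch(subset,
    all = all36,
    intensity = grep("^intensity_", all36, value = TRUE),
    tau_m = grep("^tau_", all36, value = TRUE),
    tau_ssc = tau("SSC", ETDRS_SECTORS),
    tau_lsc = tau("LSC", ETDRS_SECTORS),
    tau_ir = c(tau("SSC", ir), tau("LSC", ir)),
    tau_or = c(tau("SSC", or), tau("LSC", or)),
    tau_ir_ssc_or_lsc = c(tau("SSC", ir), tau("LSC", or)),
    tau_or_ssc_ir_lsc = c(tau("SSC", or), tau("LSC", ir)),
    stop("unknown feature subset '", subset, "'; valid names: ",
         paste(flio_subset_names(), collapse = ", "))
  )
}

#' Named feature subsets
#'
#' The feature subsets evaluated by the classification experiments:
#' `all` (36), `intensity` (18), `tau_m` (18), `tau_ssc`/`tau_lsc` (9 each),
#' `tau_ir`/`tau_or` (8 each; four ring quadrants x two channels, centre
#' excluded), the cross-channel combinations `tau_ir_ssc_or_lsc` /
#' `tau_or_ssc_ir_lsc` (8 each), and `ttest_top3` (the three lifetime
#' features ranked most significant by [ttest_rank()]).
#'
#' @return Character vector of valid subset names.
#' @export
flio_subset_names <- function() {
  c("all", "intensity", "tau_m", "tau_ssc", "tau_lsc", "tau_ir", "tau_or",
    "tau_ir_ssc_or_lsc", "tau_or_ssc_ir_lsc", "ttest_top3")
}

#' Select a named feature subset from a feature table
#'
#' @param table A [feature_table()].
#' @param subset A name from [flio_subset_names()], or a character vector of
#'   feature column names (custom subset).
#' @param labels Optional two-level grouping used only by `ttest_top3`
#'   (defaults to the table's own labels; see [run_cv()] for leakage-safe
#'   within-fold selection).
#' @return The column-filtered [feature_table()].
#' @export
select_subset <- function(table, subset, labels = NULL) {
  stopifnot(inherits(table, "feature_table"))
  cols <- if (length(subset) == 1 && subset %in% flio_subset_names()) {
    if (subset == "ttest_top3") {
      lab <- labels %||% table$label
      ranking <- ttest_rank(table, lab, features = flio_subset_columns("tau_m"))
      ranking$feature[1:3]
    } else flio_subset_columns(subset)
  } else subset
  missing_cols <- setdiff(cols, feature_names(table))
  if (length(missing_cols))
    stop("select_subset: unknown feature column(s): ", paste(missing_cols, collapse = ", "))
  feature_table(table[, c("subject_id", "eye", "label", cols)])
}

#' Pooled-variance two-sample t-test feature ranking
#'
#' Ranks features by the classic two-sample t statistic
#' `t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2))` with pooled SD `sp` and
#' `n1 + n2 - 2` degrees of freedom, two-sided p-values, sorted by p
#' ascending (ties broken by |t| descending, then canonical feature order).
#'
#' @param table A [feature_table()] (or plain data frame of features).
#' @param labels Vector with exactly two distinct values, one per row; the
#'   first group is the first level encountered in `unique(labels)`.
#' @param features Feature columns to rank; defaults to all feature columns.
#' @return Data frame with columns `feature`, `t`, `p`, `mean_1`, `mean_2`,
#'   `pooled_sd`, `df`, ordered by rank.
#' @export
ttest_rank <- function(table, labels = table$label, features = NULL) {
  features <- features %||% feature_names(table)
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) != 2)
    stop("ttest_rank: exactly two groups required, got ", length(groups))
  i1 <- labels == groups[1]; i2 <- labels == groups[2]
  if (sum(i1) < 2 || sum(i2) < 2)
    stop("ttest_rank: each group needs at least 2 rows")
  res <- do.call(rbind, lapply(features, function(f) {
    x <- table[[f]][i1]; y <- table[[f]][i2]
    n1 <- sum(!is.na(x)); n2 <- sum(!is.na(y))
    sp2 <- ((n1 - 1) * var(x, na.rm = TRUE) + (n2 - 1) * var(y, na.rm = TRUE)) /
      (n1 + n2 - 2)
    if (sp2 == 0) {
      tt <- if (mean(x, na.rm = TRUE) == mean(y, na.rm = TRUE)) 0 else
        sign(mean(x, na.rm = TRUE) - mean(y, na.rm = TRUE)) * Inf
      p <- if (tt == 0) 1 else 0
    } else {
      ht <- t.test(x, y, var.equal = TRUE)
      tt <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(feature = f, t = tt, p = p,
               mean_1 = mean(x, na.rm = TRUE), mean_2 = mean(y, na.rm = TRUE),
               pooled_sd = sqrt(sp2), df = n1 + n2 - 2, stringsAsFactors = FALSE)
  }))
  ord <- order(res$p, -abs(res$t), match(res$feature, features))
  res <- res[ord, ]
  rownames(res) <- NULL
  res
}

#' Export the sector masks as a label image
#'
#' Writes a PNG where each sector gets a distinct gray level (C = 1 ... I2 =
#' 9, background 0, scaled to the 8-bit range) for visual audit of the grid.
#'
#' @param geometry A [grid_geometry()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_image <- function(geometry, path) {
  masks <- build_masks(geometry)
  lab <- matrix(0, geometry$image_shape[1], geometry$image_shape[2])
  for (i in seq_along(masks)) lab[masks[[i]]] <- i
  png::writePNG(lab / 9, path)
  invisible(path)
}
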