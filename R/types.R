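# Domain types shared by every pipeline stage. All are plain S3 lists or
# data frames with validators, in the style of light-weight analysis packages.

#' Derive smoking status from cumulative lifetime consumption
#'
#' Heavy smokers are subjects whose cumulative consumption lies strictly over
#' 2500 packs (the clinical cohort's median among smokers); smokers at or
#' below the threshold are light smokers; subjects who never smoked are
#' non-smokers.
#'
#' @param cumulative_packs Numeric vector of lifetime packs smoked (>= 0).
#' @param years_smoked Numeric vector of years smoked (>= 0), same length.
#' @param threshold_packs Heavy-smoker threshold; consumption strictly above
#'   it is heavy. Default 2500.
#' @return Factor with levels `non_smoker`, `light_smoker`, `heavy_smoker`.
#' @export
smoking_status <- function(cumulative_packs, years_smoked = cumulative_packs,
                           threshold_packs = 2500) {
  stopifnot(all(cumulative_packs >= 0), all(years_smoked >= 0))
  status <- ifelse(cumulative_packs == 0 & years_smoked == 0, "non_smoker",
                   ifelse(cumulative_packs > threshold_packs,
                          "heavy_smoker", "light_smoker"))
  factor(status, levels = SMOKING_LEVELS)
}

#' Subject record
#'
#' @param subject_id Opaque identifier string.
#' @param age Age in years.
#' @param sex Category (e.g. `"F"`, `"M"`).
#' @param years_smoked Years smoked, >= 0.
#' @param cumulative_packs Lifetime packs smoked, >= 0.
#' @return A `subject_record` list with derived `smoking_status`.
#' @export
subject_record <- function(subject_id, age, sex, years_smoked, cumulative_packs) {
  stopifnot(is.character(subject_id), length(subject_id) == 1,
            years_smoked >= 0, cumulative_packs >= 0)
  structure(list(
    subject_id = subject_id, age = age, sex = sex,
    years_smoked = years_smoked, cumulative_packs = cumulative_packs,
    smoking_status = as.character(smoking_status(cumulative_packs, years_smoked))
  ), class = "subject_record")
}

#' One eye's FLIO export: four 256 x 256 matrices
#'
#' Mean fluorescence lifetime (`tau_m`, picoseconds) and photon-count
#' intensity, each for the short (SSC) and long (LSC) spectral channels.
#' Missing pixels are `NA`; all downstream sector means are missing-aware.
#'
#' @param subject_id Subject identifier.
#' @param eye `"OD"` or `"OS"`.
#' @param tau_m Named list `SSC`/`LSC` of square numeric matrices (ps).
#' @param intensity Named list `SSC`/`LSC` of matching matrices (counts).
#' @return A `flio_measurement`.
#' @export
flio_measurement <- function(subject_id, eye, tau_m, intensity) {
  eye <- match.arg(eye, c("OD", "OS"))
  mats <- c(tau_m[FLIO_CHANNELS], intensity[FLIO_CHANNELS])
  if (any(vapply(mats, is.null, logical(1))))
    stop("flio_measurement: all four matrices (tau_m and intensity, SSC and LSC) are required")
  shp <- dim(mats[[1]])
  if (shp[1] != shp[2]) stop("flio_measurement: matrices must be square")
  for (m in mats) {
    if (!identical(dim(m), shp))
      stop(sprintf("flio_measurement: inconsistent matrix shapes for %s/%s", subject_id, eye))
  }
  tau_vals <- unlist(tau_m, use.names = FALSE)
  tau_vals <- tau_vals[is.finite(tau_vals)]
  if (length(tau_vals) && (min(tau_vals) <= 0 || max(tau_vals) >= 5000))
    stop(sprintf("flio_measurement: finite tau_m values must lie in (0, 5000) ps for %s/%s",
                 subject_id, eye))
  int_vals <- unlist(intensity, use.names = FALSE)
  if (any(int_vals[is.finite(int_vals)] < 0))
    stop("flio_measurement: intensity counts must be >= 0")
  structure(list(subject_id = subject_id, eye = eye,
                 tau_m = tau_m[FLIO_CHANNELS], intensity = intensity[FLIO_CHANNELS]),
            class = "flio_measurement")
}

#' One eye's OCT-A en-face slab stack
#'
#' @param subject_id Subject identifier.
#' @param eye `"OD"` or `"OS"`.
#' @param slabs Named list of 512 x 512 integer matrices in \[0, 255\]; names
#'   must come from the 15 canonical slab names.
#' @return An `octa_slab_stack`.
#' @export
octa_slab_stack <- function(subject_id, eye, slabs) {
  eye <- match.arg(eye, c("OD", "OS"))
  bad <- setdiff(names(slabs), OCTA_SLAB_NAMES)
  if (length(bad))
    stop("octa_slab_stack: unknown slab name(s): ", paste(bad, collapse = ", "))
  for (nm in names(slabs)) {
    img <- slabs[[nm]]
    if (!identical(dim(img), c(512L, 512L)))
      stop(sprintf("octa_slab_stack: slab '%s' must be 512x512 for %s/%s", nm, subject_id, eye))
    if (min(img) < 0 || max(img) > 255 || any(img != round(img)))
      stop(sprintf("octa_slab_stack: slab '%s' must hold integers in [0, 255]", nm))
  }
  structure(list(subject_id = subject_id, eye = eye, slabs = slabs),
            class = "octa_slab_stack")
}

#' Cohort dataset
#'
#' Subjects plus per-eye FLIO measurements and OCT-A slab stacks. The unit of
#' analysis (a "sample") is one (subject, eye) pair; the two modalities are
#' independently optional per sample.
#'
#' @param subjects List of [subject_record()]s.
#' @param flio List of [flio_measurement()]s.
#' @param octa List of [octa_slab_stack()]s.
#' @return A `cohort_dataset`.
#' @export
cohort_dataset <- function(subjects = list(), flio = list(), octa = list()) {
  ids <- vapply(subjects, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("cohort_dataset: duplicate subject_id")
  for (modality in list(flio = flio, octa = octa)) NULL
  check_modality <- function(ms, what) {
    if (!length(ms)) return(invisible())
    key <- vapply(ms, function(m) paste(m$subject_id, m$eye), character(1))
    dup <- key[duplicated(key)]
    if (length(dup))
      stop(sprintf("cohort_dataset: duplicate (subject, eye) in %s: %s",
                   what, paste(unique(dup), collapse = ", ")))
    unknown <- setdiff(vapply(ms, `[[`, character(1), "subject_id"), ids)
    if (length(unknown))
      stop(sprintf("cohort_dataset: %s measurement for unknown subject(s): %s",
                   what, paste(unknown, collapse = ", ")))
    per <- table(vapply(ms, `[[`, character(1), "subject_id"))
    if (any(per > 2)) stop("cohort_dataset: more than 2 eyes for a subject in ", what)
  }
  check_modality(flio, "FLIO")
  check_modality(octa, "OCT-A")
  structure(list(subjects = subjects, flio = flio, octa = octa),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  st <- table(factor(vapply(x$subjects, `[[`, character(1), "smoking_status"),
                     levels = SMOKING_LEVELS))
  cat(sprintf("cohort_dataset: %d subjects (%s), %d FLIO samples, %d OCT-A samples\n",
              length(x$subjects),
              paste(sprintf("%d %s", as.integer(st), names(st)), collapse = ", "),
              length(x$flio), length(x$octa)))
  invisible(x)
}

#' Subject metadata of a cohort as a data frame
#'
#' @param cohort A [cohort_dataset()].
#' @return Data frame with one row per subject.
#' @export
subject_table <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s$subject_id, age = s$age, sex = s$sex,
               years_smoked = s$years_smoked, cumulative_packs = s$cumulative_packs,
               smoking_status = s$smoking_status, stringsAsFactors = FALSE)))
}

#' Feature table
#'
#' One row per (subject, eye) sample: identifier columns `subject_id`, `eye`,
#' `label` (smoking status; doubles as the grouping variable through
#' `subject_id`), then named real-valued feature columns.
#'
#' @param df Data frame with the identifier columns plus feature columns.
#' @return A `feature_table` (a validated data frame).
#' @export
feature_table <- function(df) {
  req <- c("subject_id", "eye", "label")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("feature_table: missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(names(df))) stop("feature_table: duplicate column names")
  if (nrow(df)) {
    if (anyDuplicated(df[, c("subject_id", "eye")]))
      stop("feature_table: duplicate (subject_id, eye) rows")
    if (any(is.na(df$label)) || any(!nzchar(as.character(df$label))))
      stop("feature_table: every row needs a label")
    feat <- setdiff(names(df), req)
    not_num <- feat[!vapply(df[feat], is.numeric, logical(1))]
    if (length(not_num))
      stop("feature_table: non-numeric feature column(s): ",
           paste(not_num, collapse = ", "))
  }
  df$label <- as.character(df$label)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Feature column names of a feature table
#' @param table A [feature_table()].
#' @return Character vector of feature column names (identifier columns excluded).
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("subject_id", "eye", "label"))
}

#' Cross-validation result
#'
#' Confusion-matrix summary of a repeated grouped stratified k-fold CV run:
#' mean TP/FN/FP/TN over the repeats (each repeat's cells are integer sums
#' over its k folds), derived TPR/FPR/accuracy percentages, and their SDs
#' over the per-repeat percentages.
#'
#' @param per_repeat List (one entry per repeat) of named integer vectors
#'   `c(tp=, fn=, fp=, tn=)`.
#' @param config List echoing the run configuration (subset, seeds, k, repeats).
#' @return A `cv_result`.
#' @export
cv_result <- function(per_repeat, config = list()) {
  stopifnot(length(per_repeat) >= 1)
  cells <- do.call(rbind, lapply(per_repeat, function(r) r[c("tp", "fn", "fp", "tn")]))
  P <- unique(cells[, "tp"] + cells[, "fn"])
  N <- unique(cells[, "fp"] + cells[, "tn"])
  if (length(P) != 1 || length(N) != 1)
    stop("cv_result: confusion totals differ across repeats (samples not all predicted once)")
  per_pct <- t(apply(cells, 1, function(r) confusion_metrics(r["tp"], r["fn"], r["fp"], r["tn"])))
  means <- colMeans(cells)
  m <- confusion_metrics(means["tp"], means["fn"], means["fp"], means["tn"])
  structure(list(
    mean_tp = unname(means["tp"]), mean_fn = unname(means["fn"]),
    mean_fp = unname(means["fp"]), mean_tn = unname(means["tn"]),
    tpr = unname(m["tpr"]), fpr = unname(m["fpr"]), accuracy = unname(m["accuracy"]),
    sd_tpr = unname(sd(per_pct[, "tpr"])), sd_fpr = unname(sd(per_pct[, "fpr"])),
    sd_accuracy = unname(sd(per_pct[, "accuracy"])),
    positives = unname(P), negatives = unname(N),
    per_repeat = lapply(per_repeat, function(r) as.integer(r[c("tp", "fn", "fp", "tn")])),
    config = config
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "cv_result (%d repeats): TP %.2f FN %.2f FP %.2f TN %.2f | TPR %.2f%% +/- %.2f, FPR %.2f%% +/- %.2f, accuracy %.2f%% +/- %.2f\n",
    length(x$per_repeat), x$mean_tp, x$mean_fn, x$mean_fp, x$mean_tn,
    x$tpr, x$sd_tpr, x$fpr, x$sd_fpr, x$accuracy, x$sd_accuracy))
  invisible(x)
}
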