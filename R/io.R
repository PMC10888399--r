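# Readers and writers: FLIO matrix exports (TSV/CSV), OCT-A slab images
# (PNG/TIFF), cohort manifests, feature tables, and CV result JSON.

detect_delimiter <- function(line) {
  counts <- vapply(c("\t", ",", ";"), function(d)
    lengths(regmatches(line, gregexpr(d, line, fixed = TRUE))), integer(1))
  if (all(counts == 0)) return(" ")
  c("\t", ",", ";")[which.max(counts)]
}

#' Read a FLIO matrix export
#'
#' Parses a delimited text matrix (tab, comma or semicolon; auto-detected
#' from the first line; decimal point only). Non-numeric or empty cells
#' become `NA`.
#'
#' @param path File path.
#' @param shape Expected dimensions; `NULL` disables the check. Default
#'   `c(256, 256)`, the FLIO export shape.
#' @return Numeric matrix, row-major (row 1 = top of image).
#' @export
read_matrix <- function(path, shape = c(256, 256)) {
  if (!file.exists(path)) stop("read_matrix: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_matrix: empty file: ", path)
  delim <- detect_delimiter(lines[[1]])
  cells <- if (delim == " ") strsplit(trimws(lines), "[[:space:]]+") else
    strsplit(lines, delim, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1)
    stop(sprintf("read_matrix: ragged rows in %s (row widths %s)",
                 path, paste(unique(widths), collapse = "/")))
  vals <- suppressWarnings(as.numeric(trimws(unlist(cells))))
  vals[is.nan(vals)] <- NA_real_  # NaN cells follow the missing-value convention
  m <- matrix(vals, nrow = length(lines), ncol = widths[1], byrow = TRUE)
  if (!is.null(shape) && !identical(dim(m), as.integer(shape)))
    stop(sprintf("read_matrix: %s is %dx%d, expected %dx%d",
                 path, nrow(m), ncol(m), shape[1], shape[2]))
  m
}

#' Write a matrix as a tab-separated export
#'
#' Values are written with 17 significant digits so that
#' `read_matrix(write_matrix(x))` round-trips bit-identically; `NA` cells are
#' written as `NaN`.
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  txt <- apply(m, 1, function(row) {
    s <- sprintf("%.17g", row)
    s[is.na(row)] <- "NaN"
    paste(s, collapse = "\t")
  })
  writeLines(txt, path)
  invisible(path)
}

#' Read / write an 8-bit grayscale slab image
#'
#' @param path PNG or TIFF file path.
#' @return Integer matrix in \[0, 255\].
#' @export
read_slab_image <- function(path) {
  if (!file.exists(path)) stop("read_slab_image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    as.matrix(EBImage::imageData(EBImage::readImage(path)))
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (ext %in% c("tif", "tiff")) img <- t(img)  # EBImage stores x,y
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' @rdname read_slab_image
#' @param img Integer matrix in \[0, 255\].
#' @export
write_slab_image <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Load a cohort from a manifest
#'
#' The manifest is a CSV with one row per (subject, eye) sample and columns
#' `subject_id`, `eye`, `age`, `sex`, `years_smoked`, `cumulative_packs`,
#' FLIO matrix path columns `tau_ssc`, `tau_lsc`, `intensity_ssc`,
#' `intensity_lsc`, and optional OCT-A slab path columns named
#' `octa_<slab name>`. Paths are relative to `data_dir`. Smoking status is
#' derived from `cumulative_packs`/`years_smoked`, never read. Modalities are
#' independently optional per sample (empty path cells); a missing referenced
#' file is fatal.
#'
#' @param manifest_path Manifest CSV path.
#' @param data_dir Directory that matrix/image paths are relative to.
#'   Defaults to the manifest's directory.
#' @return A [cohort_dataset()].
#' @export
load_cohort <- function(manifest_path, data_dir = dirname(manifest_path)) {
  if (!file.exists(manifest_path)) stop("load_cohort: manifest not found: ", manifest_path)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(man)) return(cohort_dataset())
  req <- c("subject_id", "eye", "age", "sex", "years_smoked", "cumulative_packs")
  missing_cols <- setdiff(req, names(man))
  if (length(missing_cols))
    stop("load_cohort: manifest missing column(s): ", paste(missing_cols, collapse = ", "))
  flio_cols <- c("tau_ssc", "tau_lsc", "intensity_ssc", "intensity_lsc")
  octa_cols <- grep("^octa_", names(man), value = TRUE)

  subj_rows <- man[!duplicated(man$subject_id), req]
  subjects <- lapply(seq_len(nrow(subj_rows)), function(i)
    subject_record(as.character(subj_rows$subject_id[i]), subj_rows$age[i],
                   subj_rows$sex[i], subj_rows$years_smoked[i],
                   subj_rows$cumulative_packs[i]))

  resolve <- function(p) if (is.na(p) || !nzchar(p)) NULL else file.path(data_dir, p)
  flio <- list(); octa <- list()
  for (i in seq_len(nrow(man))) {
    sid <- as.character(man$subject_id[i]); eye <- man$eye[i]
    if (all(flio_cols %in% names(man))) {
      paths <- lapply(man[i, flio_cols], resolve)
      if (!all(vapply(paths, is.null, logical(1)))) {
        for (p in paths) if (!is.null(p) && !file.exists(p))
          stop(sprintf("load_cohort: missing FLIO file for sample %s/%s: %s", sid, eye, p))
        if (any(vapply(paths, is.null, logical(1))))
          stop(sprintf("load_cohort: sample %s/%s has only some of the four FLIO matrices", sid, eye))
        flio[[length(flio) + 1]] <- flio_measurement(
          sid, eye,
          tau_m = list(SSC = read_matrix(paths$tau_ssc), LSC = read_matrix(paths$tau_lsc)),
          intensity = list(SSC = read_matrix(paths$intensity_ssc),
                           LSC = read_matrix(paths$intensity_lsc)))
      }
    }
    if (length(octa_cols)) {
      slabs <- list()
      for (col in octa_cols) {
        p <- resolve(man[i, col])
        if (is.null(p)) next
        if (!file.exists(p))
          stop(sprintf("load_cohort: missing OCT-A file for sample %s/%s: %s", sid, eye, p))
        slabs[[sub("^octa_", "", col)]] <- read_slab_image(p)
      }
      if (length(slabs))
        octa[[length(octa) + 1]] <- octa_slab_stack(sid, eye, slabs)
    }
  }
  cohort_dataset(subjects, flio, octa)
}

#' Write a cohort to disk in manifest form
#'
#' Inverse of [load_cohort()]: writes FLIO matrices as TSV, OCT-A slabs as
#' PNG, and a `manifest.csv` referencing them.
#'
#' @param cohort A [cohort_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subj <- subject_table(cohort)
  samples <- unique(rbind(
    do.call(rbind, lapply(cohort$flio, function(m)
      data.frame(subject_id = m$subject_id, eye = m$eye, stringsAsFactors = FALSE))),
    do.call(rbind, lapply(cohort$octa, function(m)
      data.frame(subject_id = m$subject_id, eye = m$eye, stringsAsFactors = FALSE)))))
  if (is.null(samples)) samples <- data.frame(subject_id = character(), eye = character())
  man <- merge(samples, subj[, c("subject_id", "age", "sex", "years_smoked",
                                 "cumulative_packs")], by = "subject_id")
  man <- man[order(man$subject_id, man$eye), ]
  flio_key <- vapply(cohort$flio, function(m) paste(m$subject_id, m$eye), character(1))
  octa_key <- vapply(cohort$octa, function(m) paste(m$subject_id, m$eye), character(1))
  for (col in c("tau_ssc", "tau_lsc", "intensity_ssc", "intensity_lsc")) man[[col]] <- ""
  slab_names <- unique(unlist(lapply(cohort$octa, function(m) names(m$slabs))))
  for (nm in slab_names) man[[paste0("octa_", nm)]] <- ""
  for (i in seq_len(nrow(man))) {
    key <- paste(man$subject_id[i], man$eye[i])
    stem <- sprintf("%s_%s", man$subject_id[i], man$eye[i])
    j <- match(key, flio_key)
    if (!is.na(j)) {
      m <- cohort$flio[[j]]
      files <- c(tau_ssc = sprintf("%s_tau_SSC.tsv", stem),
                 tau_lsc = sprintf("%s_tau_LSC.tsv", stem),
                 intensity_ssc = sprintf("%s_intensity_SSC.tsv", stem),
                 intensity_lsc = sprintf("%s_intensity_LSC.tsv", stem))
      write_matrix(m$tau_m$SSC, file.path(dir, files["tau_ssc"]))
      write_matrix(m$tau_m$LSC, file.path(dir, files["tau_lsc"]))
      write_matrix(m$intensity$SSC, file.path(dir, files["intensity_ssc"]))
      write_matrix(m$intensity$LSC, file.path(dir, files["intensity_lsc"]))
      man[i, names(files)] <- files
    }
    j <- match(key, octa_key)
    if (!is.na(j)) {
      for (nm in names(cohort$octa[[j]]$slabs)) {
        f <- sprintf("%s_octa_%s.png", stem, gsub("[^A-Za-z0-9]", "", nm))
        write_slab_image(cohort$octa[[j]]$slabs[[nm]], file.path(dir, f))
        man[i, paste0("octa_", nm)] <- f
      }
    }
  }
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a feature table as CSV
#'
#' Feature values are written with 15 significant digits, so a round trip
#' reproduces them to better than 1e-12 relative.
#'
#' @param table A [feature_table()].
#' @param path CSV path.
#' @return `path` (write) or the re-read [feature_table()] (read).
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table)
  for (nm in feature_names(table)) df[[nm]] <- sprintf("%.15g", df[[nm]])
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("read_feature_table: file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = c(subject_id = "character"))
  feat <- setdiff(names(df), c("subject_id", "eye", "label"))
  for (nm in feat) {
    if (nrow(df) == 0) df[[nm]] <- numeric()  # header-only file
    if (!is.numeric(df[[nm]]))
      stop("read_feature_table: unknown non-numeric column: ", nm)
  }
  if (nrow(df) == 0) for (nm in c("subject_id", "eye", "label")) df[[nm]] <- character()
  feature_table(df)
}

#' Save / load a cross-validation result as JSON
#'
#' The JSON carries every [cv_result()] field plus the run configuration
#' (feature subset, seed, k, repeats) and round-trips to identical values.
#'
#' @param result A [cv_result()].
#' @param path JSON path.
#' @return `path` (save) or the reconstructed [cv_result()] (load).
#' @export
save_cv_result <- function(result, path) {
  stopifnot(inherits(result, "cv_result"))
  out <- unclass(result)
  out$per_repeat <- out$per_repeat %||% list()
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_cv_result
#' @export
load_cv_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  per_repeat <- if (is.matrix(x$per_repeat)) {
    lapply(seq_len(nrow(x$per_repeat)), function(i)
      setNames(as.integer(x$per_repeat[i, ]), c("tp", "fn", "fp", "tn")))
  } else {
    lapply(x$per_repeat, function(r) setNames(as.integer(r), c("tp", "fn", "fp", "tn")))
  }
  if (length(per_repeat)) {
    cv_result(per_repeat, config = x$config)
  } else {
    structure(modifyList(x, list(per_repeat = list())), class = "cv_result")
  }
}
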