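# OCT-A feature encodings: pixel-value histograms, circular-grid
# sectorization, local box-counting fractal-dimension density maps, PCA
# reduction and exact t-SNE cohort embeddings.

#' Histogram encoding of an OCT-A slab
#'
#' @param image Integer matrix with values in \[0, 255\].
#' @return Integer vector of length 256; element `v + 1` counts the pixels
#'   equal to `v`. Counts sum to the pixel count.
#' @export
histogram_encode <- function(image) {
  v <- as.vector(image)
  if (any(is.na(v)) || min(v) < 0 || max(v) > 255 || any(v != round(v)))
    stop("histogram_encode: image must hold integers in [0, 255]")
  tabulate(v + 1L, nbins = 256L)
}

#' Circular-grid sectorization of an OCT-A slab
#'
#' Reuses the ETDRS machinery with OCT-A geometry: a 20 degree field at
#' 0.3 mm/degree gives a 6.0 mm extent, so the 6 mm outer ring exactly
#' inscribes the 512 x 512 image (outer radius = 256 px).
#'
#' @param image 512 x 512 (or square) numeric matrix.
#' @param laterality `"OD"` or `"OS"`.
#' @param field_of_view_deg Field of view (default 20).
#' @return Named vector of nine sector mean intensities.
#' @export
sectorize_octa <- function(image, laterality = "OD", field_of_view_deg = 20) {
  geometry <- grid_geometry(image_shape = dim(image),
                            field_of_view_deg = field_of_view_deg,
                            laterality = laterality)
  sector_mean(image, build_masks(geometry))
}

#' Box-counting fractal dimension of one binary window
#'
#' Partitions the window into boxes of each side length (anchored at the
#' window's top-left corner; edge boxes truncated), counts boxes containing
#' at least one foreground pixel, and returns the least-squares slope of
#' `log N(s)` against `log(1/s)`, clamped to \[0, 2\]. An empty window gives
#' 0.
#'
#' @param window Logical (or 0/1) matrix.
#' @param box_sizes Box side lengths.
#' @return Scalar fractal dimension in \[0, 2\].
#' @export
box_count_fd <- function(window, box_sizes = c(2, 3, 4, 6, 8, 12)) {
  window <- window > 0
  if (!any(window)) return(0)
  counts <- vapply(box_sizes, function(s) {
    starts_r <- seq(1, nrow(window), by = s)
    starts_c <- seq(1, ncol(window), by = s)
    n <- 0
    for (a in starts_r) for (b in starts_c) {
      if (any(window[a:min(a + s - 1, nrow(window)),
                     b:min(b + s - 1, ncol(window))])) n <- n + 1
    }
    n
  }, numeric(1))
  x <- log(1 / box_sizes)
  xc <- x - mean(x)
  slope <- sum(xc * log(counts)) / sum(xc^2)
  min(max(slope, 0), 2)
}

# Summed-area table with a zero top/left border row/col.
integral_image <- function(m) {
  sat <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  sat[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  sat
}

binarize_slab <- function(image, threshold) {
  if (is.numeric(threshold)) return(image > threshold)
  switch(threshold,
         otsu = {
           rng <- range(image)
           if (rng[1] == rng[2]) return(matrix(FALSE, nrow(image), ncol(image)))
           scaled <- (image - rng[1]) / (rng[2] - rng[1])
           th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
           scaled > th
         },
         mean = image > mean(image),
         stop("unknown threshold method '", threshold, "'"))
}

#' Local fractal-dimension vessel density map
#'
#' Binarizes the slab with a global threshold, then computes the
#' box-counting fractal dimension ([box_count_fd()]) of the window around
#' every pixel (symmetric reflection padding at the borders). The resulting
#' map, with values in \[0, 2\], is a pixelwise roughness measure that
#' serves as a proxy for local vessel density.
#'
#' Implemented with per-box-grid summed-area tables so the whole 512 x 512
#' map is a few hundred vectorized passes rather than a per-pixel loop.
#'
#' @param image Grayscale slab matrix.
#' @param window_size Odd window side length (default 25).
#' @param box_sizes Box side lengths (default `c(2, 3, 4, 6, 8, 12)`).
#' @param threshold `"otsu"` (default), `"mean"`, or a numeric cutoff.
#' @return A `density_map`: the FD matrix with the parameters attached as
#'   attributes.
#' @export
fractal_density_map <- function(image, window_size = 25,
                                box_sizes = c(2, 3, 4, 6, 8, 12),
                                threshold = "otsu") {
  n1 <- nrow(image); n2 <- ncol(image)
  if (window_size %% 2 == 0) stop("fractal_density_map: window_size must be odd")
  if (window_size > min(n1, n2)) stop("fractal_density_map: window larger than image")
  fg <- binarize_slab(image, threshold)
  h <- (window_size - 1) / 2
  pad_idx <- function(n) c(h:1, 1:n, n:(n - h + 1))
  padded <- fg[pad_idx(n1), pad_idx(n2)] * 1
  sat <- integral_image(padded)
  w <- window_size
  counts <- vector("list", length(box_sizes))
  for (k in seq_along(box_sizes)) {
    s <- box_sizes[k]
    starts <- seq(1, w, by = s)
    widths <- pmin(s, w - starts + 1)
    N <- matrix(0, n1, n2)
    rows <- seq_len(n1); cols <- seq_len(n2)
    for (ai in seq_along(starts)) for (aj in seq_along(starts)) {
      r1 <- rows + starts[ai] - 1; c1 <- cols + starts[aj] - 1
      r2 <- r1 + widths[ai] - 1;   c2 <- c1 + widths[aj] - 1
      blocksum <- sat[r2 + 1, c2 + 1] - sat[r1, c2 + 1] -
        sat[r2 + 1, c1] + sat[r1, c1]
      N <- N + (blocksum > 0)
    }
    counts[[k]] <- N
  }
  x <- log(1 / box_sizes)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  fd <- matrix(0, n1, n2)
  nonempty <- counts[[which.min(box_sizes)]] > 0
  for (k in seq_along(box_sizes)) {
    lk <- log(pmax(counts[[k]], 1))  # empty windows masked out below
    fd <- fd + xc[k] / denom * lk
  }
  fd[!nonempty] <- 0
  fd <- pmin(pmax(fd, 0), 2)
  structure(fd, class = c("density_map", class(fd)),
            window_size = window_size, box_sizes = box_sizes,
            threshold_method = if (is.numeric(threshold)) "fixed" else threshold)
}

#' Rescale a density map to an 8-bit image
#'
#' Linear rescale of \[0, 2\] FD values to \[0, 255\] integers, so density
#' maps can feed the histogram and sectorization encodings.
#'
#' @param dm A [fractal_density_map()] result.
#' @return Integer matrix in \[0, 255\].
#' @export
density_map_to_image <- function(dm) {
  matrix(as.integer(round(pmin(pmax(unclass(dm), 0), 2) / 2 * 255)),
         nrow(dm), ncol(dm))
}

#' Encode a cohort's OCT-A slabs into a feature table
#'
#' Optionally replaces each slab with its fractal-dimension density map,
#' then applies the chosen per-image encoding. Samples missing the requested
#' slab are skipped with a warning.
#'
#' @param cohort A [cohort_dataset()].
#' @param method `"histogram"` (256 columns), `"sectorization"` (9 columns),
#'   or a function `image -> numeric vector` (pluggable external encoder,
#'   e.g. a pretrained deep feature extractor; not bundled).
#' @param slab_name Which slab to encode (default `"SVC"`).
#' @param density_map If `TRUE`, encode the fractal density map instead of
#'   the raw slab.
#' @param ... Passed to [fractal_density_map()].
#' @return A [feature_table()].
#' @export
encode_cohort <- function(cohort, method = "histogram", slab_name = "SVC",
                          density_map = FALSE, ...) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  encoder <- if (is.function(method)) method else switch(
    match.arg(method, c("histogram", "sectorization")),
    histogram = function(img, eye) histogram_encode(img),
    sectorization = function(img, eye) sectorize_octa(img, laterality = eye))
  if (is.function(method)) {
    user_encoder <- encoder
    encoder <- function(img, eye) user_encoder(img)
  }
  status <- setNames(vapply(cohort$subjects, `[[`, character(1), "smoking_status"),
                     vapply(cohort$subjects, `[[`, character(1), "subject_id"))
  rows <- list()
  for (m in cohort$octa) {
    img <- m$slabs[[slab_name]]
    if (is.null(img)) {
      warning(sprintf("encode_cohort: sample %s/%s has no '%s' slab; skipped",
                      m$subject_id, m$eye, slab_name))
      next
    }
    if (density_map) img <- density_map_to_image(fractal_density_map(img, ...))
    v <- encoder(img, m$eye)
    if (is.null(names(v))) names(v) <- sprintf("V%03d", seq_along(v))
    rows[[length(rows) + 1]] <- cbind(
      data.frame(subject_id = m$subject_id, eye = m$eye,
                 label = unname(status[m$subject_id]), stringsAsFactors = FALSE),
      as.data.frame(as.list(v)))
  }
  if (!length(rows)) {
    warning("encode_cohort: no samples encoded")
    return(feature_table(data.frame(subject_id = character(), eye = character(),
                                    label = character())))
  }
  feature_table(do.call(rbind, rows))
}

#' PCA reduction to the most variable dimensions
#'
#' Mean-centred projection onto the top-variance principal components, with
#' each component's sign fixed so that its largest-magnitude loading is
#' positive. Inputs with fewer than `ndim` columns (or rank) keep what they
#' have; rank-deficient components beyond the data rank are zero.
#'
#' @param vectors Numeric matrix (n samples x d features).
#' @param ndim Number of components to keep (default 15).
#' @return Score matrix (n x ndim) with the rotation, centre and component
#'   SDs attached as attributes.
#' @export
pca_reduce <- function(vectors, ndim = 15) {
  X <- as.matrix(vectors)
  stopifnot(nrow(X) >= 2)
  k <- min(ndim, ncol(X))
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  avail <- sum(pr$sdev > 1e-12)
  if (avail < k)
    warning(sprintf("pca_reduce: data rank %d < %d requested components; the rest are zero",
                    avail, k))
  keep <- min(k, ncol(pr$x))
  scores <- matrix(0, nrow(X), k)
  rot <- matrix(0, ncol(X), k)
  scores[, seq_len(keep)] <- pr$x[, seq_len(keep)]
  rot[, seq_len(keep)] <- pr$rotation[, seq_len(keep)]
  for (i in seq_len(keep)) {
    j <- which.max(abs(rot[, i]))
    if (rot[j, i] < 0) { rot[, i] <- -rot[, i]; scores[, i] <- -scores[, i] }
  }
  zero <- pr$sdev[seq_len(keep)] <= 1e-12
  scores[, which(zero)] <- 0
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  structure(scores, rotation = rot, center = pr$center,
            sdev = c(pr$sdev, rep(0, max(0, k - length(pr$sdev))))[seq_len(k)])
}
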