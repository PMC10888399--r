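test_that("histogram encoding matches per-pixel counting exactly", {
  img <- matrix(7L, 512, 512)
  h <- histogram_encode(img)
  expect_length(h, 256)
  expect_equal(h[8], 512L * 512L)
  expect_equal(sum(h), 512L * 512L)

  set.seed(5)
  img2 <- matrix(sample(0:255, 128 * 128, replace = TRUE), 128)
  h2 <- histogram_encode(img2)
  ref <- vapply(0:255, function(v) sum(img2 == v), integer(1))
  expect_identical(h2, ref)
  expect_equal(sum(h2), 128L * 128L)

  expect_error(histogram_encode(matrix(-1, 2, 2)), "0, 255")
  expect_error(histogram_encode(matrix(1.5, 2, 2)), "integers")
})

test_that("OCT-A sectorization inscribes the 6 mm grid in the 512 px image", {
  g <- grid_geometry(image_shape = c(512, 512), field_of_view_deg = 20)
  expect_equal((g$ring_diameters_mm[3] / 2) / g$mm_per_px, 256)  # outer radius in px
  img <- matrix(3, 512, 512)
  expect_equal(unname(sectorize_octa(img)), rep(3, 9))

  set.seed(6)
  img2 <- matrix(runif(512^2) * 255, 512)
  got <- sectorize_octa(img2, laterality = "OS")
  ref <- brute_force_sector_means(img2, laterality = "OS", field_of_view_deg = 20)
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("box-counting slope hits the closed forms", {
  expect_equal(box_count_fd(matrix(1, 32, 32), c(2, 4, 8, 16)), 2)
  line <- matrix(0, 32, 32); line[17, ] <- 1
  expect_equal(box_count_fd(line, c(2, 4, 8, 16)), 1)
  expect_equal(box_count_fd(matrix(0, 32, 32)), 0)
  # single point: N(s) = 1 at every scale -> slope 0
  pt <- matrix(0, 32, 32); pt[5, 5] <- 1
  expect_equal(box_count_fd(pt, c(2, 4, 8, 16)), 0)
})

test_that("the density map agrees with per-window box counting and stays in [0, 2]", {
  set.seed(8)
  img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64)
  dm <- fractal_density_map(img, window_size = 7, box_sizes = c(2, 3, 4),
                            threshold = 128)
  expect_true(all(dm >= 0 & dm <= 2))
  fg <- img > 128
  h <- 3
  pidx <- function(n) c(h:1, 1:n, n:(n - h + 1))
  pad <- fg[pidx(64), pidx(64)]
  for (i in c(1, 9, 33, 64)) for (j in c(2, 20, 55, 64)) {
    expect_equal(dm[i, j], box_count_fd(pad[i:(i + 6), j:(j + 6)], c(2, 3, 4)),
                 tolerance = 1e-10)
  }
  # empty window -> 0
  dm0 <- fractal_density_map(matrix(0, 64, 64), window_size = 7,
                             box_sizes = c(2, 3, 4), threshold = 0.5)
  expect_true(all(dm0 == 0))
  expect_error(fractal_density_map(img, window_size = 8), "odd")
  expect_error(fractal_density_map(img, window_size = 65), "larger")
})

test_that("adding foreground never lowers the window's fractal dimension", {
  set.seed(10)
  w <- matrix(0, 24, 24)
  fd_prev <- 0
  for (step in 1:6) {
    w[sample(which(w == 0), 40)] <- 1
    fd <- box_count_fd(w, c(2, 3, 4, 6))
    expect_gte(fd, fd_prev - 1e-9)
    fd_prev <- fd
  }
})

test_that("PCA keeps the most variable dimensions with fixed signs", {
  set.seed(11)
  # rank-1 data: one component carries all variance
  u <- rnorm(30); v <- rnorm(20)
  X1 <- outer(u, v)
  expect_warning(s1 <- pca_reduce(X1, ndim = 5), "rank")
  expect_equal(ncol(s1), 5)
  expect_equal(unname(s1[, 2:5]), matrix(0, 30, 4))
  expect_gt(var(s1[, 1]), 0)

  X <- matrix(rnorm(60 * 256), 60)
  s <- pca_reduce(X, ndim = 15)
  expect_equal(dim(s), c(60L, 15L))
  rot <- attr(s, "rotation")
  expect_equal(t(rot) %*% rot, diag(15), tolerance = 1e-10)
  # largest-magnitude loading of each component is positive
  expect_true(all(vapply(1:15, function(i) rot[which.max(abs(rot[, i])), i] > 0,
                         logical(1))))
  # reconstruction error from 15 components equals the eigenvalue tail sum
  ctr <- sweep(X, 2, colMeans(X))
  recon <- s[, 1:15] %*% t(rot)
  err <- sum((ctr - recon)^2)
  ev <- attr(s, "sdev")^2 * (nrow(X) - 1)
  full_ev <- prcomp(X)$sdev^2 * (nrow(X) - 1)
  expect_equal(err, sum(full_ev) - sum(ev), tolerance = 1e-8)
})

test_that("t-SNE preserves separation, is deterministic, and survives degeneracy", {
  set.seed(12)
  X <- rbind(matrix(rnorm(30 * 15), 30), matrix(rnorm(30 * 15, mean = 10), 30))
  lab <- rep(c("a", "b"), each = 30)
  emb <- tsne_embed(X, lab, embedding_config(max_iter = 400))
  sil <- cluster::silhouette(as.integer(factor(emb$label)),
                             dist(cbind(emb$dim1, emb$dim2)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  emb2 <- tsne_embed(X, lab, embedding_config(max_iter = 400))
  expect_identical(emb$dim1, emb2$dim1)

  summ <- embedding_group_summary(emb)
  expect_equal(nrow(summ), 2)
  expect_true(all(c("mean1", "mean2", "sd1", "sd2") %in% names(summ)))

  # identical points: finite coordinates, coincident group means
  embd <- tsne_embed(matrix(1, 10, 5), rep(c("a", "b"), 5))
  expect_true(all(is.finite(embd$dim1)) && all(is.finite(embd$dim2)))
  sd2 <- embedding_group_summary(embd)
  expect_lt(abs(sd2$mean1[1] - sd2$mean1[2]), 1e-6)

  expect_error(tsne_embed(matrix(1, 4, 3), rep("a", 4)), "at least 5")
})

test_that("null OCT-A cohorts show no separable group structure in the embedding", {
  # labels are permuted at the subject level: both eyes of a subject are one
  # exchangeable unit, mirroring the grouped CV protocol
  nonsep <- vapply(1:5, function(seed) {
    cohort <- cached_octa_cohort(seed)
    tab <- encode_cohort(cohort, method = "histogram", slab_name = "SVC")
    X <- pca_reduce(as.matrix(as.data.frame(tab)[, feature_names(tab)]), ndim = 5)
    emb <- tsne_embed(unclass(X), tab$label, embedding_config(max_iter = 300))
    embedding_separation_test(emb, n_perm = 499, seed = seed,
                              groups = tab$subject_id)$p_value > 0.05
  }, logical(1))
  expect_gte(sum(nonsep), 4)
})

test_that("cohort encoding produces the expected table shapes and skips missing slabs", {
  cohort <- cached_octa_cohort(1)
  tab <- encode_cohort(cohort, method = "histogram", slab_name = "SVC")
  expect_equal(nrow(tab), 16)
  expect_length(feature_names(tab), 256)
  tab9 <- encode_cohort(cohort, method = "sectorization", slab_name = "SVC")
  expect_length(feature_names(tab9), 9)
  # custom pluggable encoder
  tabf <- encode_cohort(cohort, method = function(img) c(m = mean(img), s = sd(img)),
                        slab_name = "SVC")
  expect_identical(feature_names(tabf), c("m", "s"))
  w <- capture_warnings(tab0 <- encode_cohort(cohort, method = "histogram",
                                              slab_name = "DCP"))
  expect_true(any(grepl("no 'DCP' slab", w)))
  expect_equal(nrow(tab0), 0)
})

test_that("density-map encoding composes with sectorization", {
  cohort <- cached_octa_cohort(1)
  small <- cohort_dataset(cohort$subjects[1:2], octa = cohort$octa[1:2])
  tab <- encode_cohort(small, method = "sectorization", slab_name = "SVC",
                       density_map = TRUE)
  expect_equal(nrow(tab), 2)
  vals <- as.matrix(as.data.frame(tab)[, feature_names(tab)])
  expect_true(all(vals >= 0 & vals <= 255))
})
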