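# Exact t-distributed stochastic neighbor embedding. Written for cohort
# sizes of ~100 samples, where the O(n^2) exact gradient is cheap; PCA
# initialisation makes runs fully deterministic.

#' Embedding configuration
#'
#' @param pca_dims Dimensions kept by the upstream PCA (default 15).
#' @param tsne_dims Embedding dimensionality (fixed at 2).
#' @param perplexity Target perplexity; automatically reduced below
#'   `(n - 1) / 3` for small cohorts.
#' @param max_iter Gradient-descent iterations (default 600).
#' @param seed Seed recorded with the embedding (the optimisation itself is
#'   deterministic through PCA initialisation).
#' @return An `embedding_config`.
#' @export
embedding_config <- function(pca_dims = 15, tsne_dims = 2, perplexity = 30,
                             max_iter = 600, seed = 1L) {
  stopifnot(tsne_dims == 2, perplexity > 0, pca_dims >= 1)
  structure(list(pca_dims = pca_dims, tsne_dims = tsne_dims,
                 perplexity = perplexity, max_iter = max_iter, seed = seed),
            class = "embedding_config")
}

# Row-wise conditional affinities at a given perplexity (bisection on the
# Gaussian precision, 50 steps).
tsne_affinities <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; bmin <- -Inf; bmax <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0 } else {
        H <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    w <- exp(-di * beta)
    sw <- sum(w)
    P[i, -i] <- if (sw > 0) w / sw else 1 / (n - 1)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Embed samples in 2-D with exact t-SNE
#'
#' Minimizes the Kullback-Leibler divergence between Gaussian input
#' affinities (perplexity-calibrated) and Student-t output affinities by
#' momentum gradient descent with early exaggeration, starting from the
#' (deterministic) 2-D PCA layout scaled to SD 1e-4. Identical inputs and
#' configuration therefore give identical coordinates.
#'
#' @param vectors Numeric matrix (n x d), typically PCA-reduced.
#' @param labels Group label per row.
#' @param config An [embedding_config()].
#' @return An `embedding`: data frame of coordinates (`dim1`, `dim2`,
#'   `label`) with a `group_summary` attribute (per-group mean point and
#'   per-axis SD, the "+ and ovals" summary).
#' @export
tsne_embed <- function(vectors, labels, config = embedding_config()) {
  X <- as.matrix(vectors)
  n <- nrow(X)
  if (n < 5) stop("tsne_embed: need at least 5 samples, got ", n)
  stopifnot(length(labels) == n)
  perplexity <- min(config$perplexity, (n - 1) / 3 - 1e-9)
  perplexity <- max(perplexity, 2)
  D2 <- as.matrix(dist(X))^2
  P <- tsne_affinities(D2, perplexity)
  Y <- if (sum(apply(X, 2, var)) > 0) {
    sc <- pca_reduce(X, ndim = 2)
    s <- sd(as.vector(sc))
    if (s > 0) sc / s * 1e-4 else sc
  } else matrix(0, n, 2)
  Y <- unclass(Y)[, 1:2, drop = FALSE]
  vel <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  exaggeration_until <- min(250, config$max_iter %/% 2)
  eta <- 200
  for (iter in seq_len(config$max_iter)) {
    Pit <- if (iter <= exaggeration_until) P * 12 else P
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    momentum <- if (iter <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(vel), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    vel <- momentum * vel - eta * gains * grad
    Y <- Y + vel
    Y <- sweep(Y, 2, colMeans(Y))
  }
  out <- data.frame(dim1 = Y[, 1], dim2 = Y[, 2],
                    label = as.character(labels), stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(out, out$label), function(g)
    data.frame(label = g$label[1], mean1 = mean(g$dim1), mean2 = mean(g$dim2),
               sd1 = sd(g$dim1), sd2 = sd(g$dim2), n = nrow(g),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(out, class = c("embedding", "data.frame"),
            group_summary = summ, perplexity = perplexity, config = config)
}

#' Per-group summary of an embedding
#' @param embedding A [tsne_embed()] result.
#' @return Data frame of per-group mean coordinates and per-axis SDs.
#' @export
embedding_group_summary <- function(embedding) attr(embedding, "group_summary")

#' Permutation test for group separation in an embedding
#'
#' Tests whether the distance between the two group mean points is larger
#' than expected under random relabelling. A non-significant result means
#' the groups are not separable in the embedding.
#'
#' @param embedding A [tsne_embed()] result with exactly two label values.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param groups Optional grouping vector (e.g. subject ids): labels are
#'   permuted at the group level, so both eyes of a subject keep a common
#'   label — the exchangeable unit for paired-eye cohorts.
#' @return List with `observed` (group-mean distance) and `p_value`.
#' @export
embedding_separation_test <- function(embedding, n_perm = 999, seed = 1L,
                                      groups = NULL) {
  labs <- embedding$label
  classes <- unique(labs)
  stopifnot(length(classes) == 2)
  Y <- cbind(embedding$dim1, embedding$dim2)
  mean_dist <- function(l) {
    m1 <- colMeans(Y[l == classes[1], , drop = FALSE])
    m2 <- colMeans(Y[l == classes[2], , drop = FALSE])
    sqrt(sum((m1 - m2)^2))
  }
  obs <- mean_dist(labs)
  if (is.null(groups)) groups <- seq_along(labs)
  ug <- unique(groups)
  glab <- labs[match(ug, groups)]
  perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    shuffled <- sample(glab)
    mean_dist(shuffled[match(groups, ug)])
  }, numeric(1)))
  list(observed = obs, p_value = (1 + sum(perm >= obs)) / (n_perm + 1))
}

#' Plot an embedding with group means and SD ellipses
#'
#' Scatter of the 2-D coordinates coloured by group, with a `+` at each
#' group mean and a 1-SD axis-aligned ellipse around it.
#'
#' @param embedding A [tsne_embed()] result.
#' @param path Optional PNG path; if given, the plot is written there.
#' @return The ggplot object, invisibly.
#' @export
plot_embedding <- function(embedding, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_embedding requires ggplot2")
  summ <- embedding_group_summary(embedding)
  theta <- seq(0, 2 * pi, length.out = 120)
  ellipses <- do.call(rbind, lapply(seq_len(nrow(summ)), function(i)
    data.frame(label = summ$label[i],
               dim1 = summ$mean1[i] + summ$sd1[i] * cos(theta),
               dim2 = summ$mean2[i] + summ$sd2[i] * sin(theta))))
  p <- ggplot2::ggplot(as.data.frame(embedding),
                       ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                    colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_path(data = ellipses, linetype = "dashed") +
    ggplot2::geom_point(data = data.frame(dim1 = summ$mean1, dim2 = summ$mean2,
                                          label = summ$label),
                        shape = 3, size = 4, stroke = 1.5) +
    ggplot2::labs(x = "Dim 1", y = "Dim 2", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 700, res = 130)
    print(p)
    grDevices::dev.off()
  }
  invisible(p)
}
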