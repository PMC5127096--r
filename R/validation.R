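#' Silhouette width of a partition
#'
#' For each sample, `s = (b - a) / max(a, b)` with `a` the mean distance to
#' its own cluster (excluding itself) and `b` the smallest mean distance to
#' another cluster; members of singleton clusters get `s = 0`.
#'
#' @param d a [stats::dist] or symmetric matrix.
#' @param labels integer cluster labels, one per sample.
#' @param per_sample return the per-sample widths instead of their mean.
#' @return mean silhouette width in `[-1, 1]`, or the per-sample vector.
#' @export
silhouette_width <- function(d, labels, per_sample = FALSE) {
  m <- as.matrix(d)
  n <- nrow(m)
  stopifnot(length(labels) == n)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop2("silhouette requires at least 2 clusters")
  sizes <- tabulate(labels, k)
  # mean distance from each sample to each cluster (including itself for own)
  sums <- t(rowsum(t(m), group = labels, reorder = TRUE))  # n x k
  s <- numeric(n)
  for (i in seq_len(n)) {
    g <- labels[i]
    if (sizes[g] == 1) { s[i] <- 0; next }
    a <- sums[i, g] / (sizes[g] - 1)
    b <- min(sums[i, -g] / sizes[-g])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  names(s) <- rownames(m)
  if (per_sample) s else mean(s)
}

#' Calinski-Harabasz index of a partition
#'
#' Variance-ratio criterion computed from distances alone: samples are
#' embedded by principal coordinates (all positive-eigenvalue axes, which
#' reproduces the original geometry exactly when the distances are
#' Euclidean) and the classic `CH = [B/(k-1)] / [W/(n-k)]` is evaluated on
#' the embedded coordinates. A medoid-based variant (within/between squared
#' distances to medoids) is available for sensitivity analysis. When the
#' within-cluster dispersion is exactly zero the index is reported as the
#' capped sentinel `1e12` so that model selection by argmax stays defined.
#'
#' @param d a [stats::dist] or symmetric matrix.
#' @param labels cluster labels (at least 2 distinct values).
#' @param variant `"pcoa"` (default) or `"medoid"`.
#' @param coords optional precomputed PCoA coordinates (internal use).
#' @return nonnegative scalar.
#' @export
ch_index <- function(d, labels, variant = c("pcoa", "medoid"), coords = NULL) {
  variant <- match.arg(variant)
  m <- as.matrix(d)
  n <- nrow(m)
  stopifnot(length(labels) == n)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop2("CH index is undefined for k = 1")
  if (any(tabulate(labels, k) == 0)) stop2("every cluster must be nonempty")
  if (variant == "medoid") {
    overall <- which.min(rowSums(m))
    w <- 0; b <- 0
    for (g in seq_len(k)) {
      idx <- which(labels == g)
      med <- idx[which.min(rowSums(m[idx, idx, drop = FALSE]))]
      w <- w + sum(m[idx, med]^2)
      b <- b + length(idx) * m[med, overall]^2
    }
    if (w <= 0) return(1e12)
    return((b / (k - 1)) / (w / (n - k)))
  }
  if (is.null(coords)) coords <- pcoa_embed(m)$coords
  centroid <- colMeans(coords)
  total <- sum(sweep(coords, 2, centroid)^2)
  w <- 0
  for (g in seq_len(k)) {
    cg <- coords[labels == g, , drop = FALSE]
    w <- w + sum(sweep(cg, 2, colMeans(cg))^2)
  }
  b <- max(total - w, 0)
  if (w <= .Machine$double.eps * total) return(1e12)
  (b / (k - 1)) / (w / (n - k))
}

# Positive-eigenvalue classical scaling embedding of a distance matrix.
pcoa_embed <- function(m) {
  n <- nrow(m)
  mds <- suppressWarnings(stats::cmdscale(m, k = n - 1, eig = TRUE))
  eig <- mds$eig
  keep <- which(eig > max(eig) * 1e-9)
  coords <- mds$points[, seq_len(min(length(keep), ncol(mds$points))), drop = FALSE]
  list(coords = coords, eig = eig, positive = eig[keep],
       negative_magnitude = sum(abs(eig[eig < 0])))
}

#' Prediction strength of a k-cluster solution
#'
#' Cross-validated cluster stability: repeatedly split the samples 50/50,
#' cluster both halves by PAM, classify each held-out sample to its nearest
#' training medoid, and score each held-out PAM cluster (with at least two
#' members) by the fraction of its pairs that the training rule co-assigns.
#' The repeat's score is the minimum over clusters (clusters with fewer
#' than two members carry no pairs and are skipped); both fold directions
#' are used and the mean over all `2 * repeats` scores is returned.
#'
#' @param d a [stats::dist] or symmetric matrix.
#' @param k number of clusters (`2 <= k <= n/2`).
#' @param repeats number of random splits (default 100).
#' @param seed integer seed; the procedure is deterministic given it.
#' @return prediction strength in `[0, 1]`.
#' @export
prediction_strength <- function(d, k, repeats = 100, seed) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (k < 2) stop2("prediction strength requires k >= 2")
  if (k > floor(n / 2)) stop2("k must not exceed half the sample count")
  with_seed(seed, {
    scores <- numeric(0)
    for (r in seq_len(repeats)) {
      perm <- sample.int(n)
      half <- list(perm[seq_len(floor(n / 2))], perm[(floor(n / 2) + 1):n])
      for (dir in 1:2) {
        train <- half[[dir]]; test <- half[[3 - dir]]
        train_fit <- pam_cluster(m[train, train, drop = FALSE], k)
        test_fit <- pam_cluster(m[test, test, drop = FALSE], k)
        # training rule applied to held-out samples: nearest training medoid
        rule <- apply(m[test, train[train_fit$medoid_index], drop = FALSE], 1, which.min)
        per_cluster <- rep(NA_real_, k)
        for (g in seq_len(k)) {
          members <- which(test_fit$clustering == g)
          sz <- length(members)
          if (sz < 2) next
          co <- sum(choose(tabulate(rule[members], k), 2))
          per_cluster[g] <- co / choose(sz, 2)
        }
        scores <- c(scores, if (all(is.na(per_cluster))) 1 else min(per_cluster, na.rm = TRUE))
      }
    }
    mean(scores)
  })
}

classify_ps <- function(ps) if (ps >= 0.9) "strong clustering" else "no strong clustering"

classify_si <- function(si) {
  if (si <= 0.25) "no substantial structure"
  else if (si <= 0.5) "weak structure"
  else if (si <= 0.75) "reasonable structure"
  else "strong structure"
}

#' Fit and validate an enterotype clustering
#'
#' The package's central model fit. Given a count or relative abundance
#' table (or a precomputed distance matrix), it computes square-root
#' Jensen-Shannon distances, fits PAM partitions over a range of cluster
#' numbers, selects `k` by the Calinski-Harabasz index (ties toward the
#' smaller `k`), and validates the selected partition by prediction
#' strength and silhouette width against the conventional thresholds:
#' clustering is "strong" when PS >= 0.9, and the silhouette bands are
#' <= 0.25 (none) / 0.5 (weak) / 0.75 (reasonable) / above (strong). The
#' partition is flagged `reliable` when PS >= 0.9 and SI > 0.25.
#'
#' @param x an [abundance_table] (counts are converted to relative
#'   abundances) or a [stats::dist] of precomputed dissimilarities.
#' @param k_range candidate cluster numbers (default `2:10`).
#' @param force_k optionally bypass CH selection and validate this `k`.
#' @param ps_repeats split-half repeats for prediction strength.
#' @param seed integer seed for the prediction-strength splits.
#' @param distance `"sqrt-jsd"` (default) or `"jsd"`; ignored when `x` is
#'   already a distance object.
#' @param ch_variant passed to [ch_index()].
#' @return an object of class `enterotype`: list with `dist`, `k_range`,
#'   `ch_by_k`, `best_k`, `partition` (a [pam_cluster()] result at
#'   `best_k`), `ps`, `si`, `ps_class`, `si_class`, `reliable`, and (when
#'   fitted from a table) `profiles`, the relative abundances used.
#' @examples
#' coh <- generate_cohort(cohort_config(n_samples = 60, seed = 7))
#' fit <- enterotype(coh$counts, k_range = 2:4, ps_repeats = 10, seed = 7)
#' summary(fit)
#' @export
enterotype <- function(x, k_range = 2:10, force_k = NULL, ps_repeats = 100,
                       seed = 1L, distance = c("sqrt-jsd", "jsd"),
                       ch_variant = c("pcoa", "medoid")) {
  distance <- match.arg(distance)
  ch_variant <- match.arg(ch_variant)
  profiles <- NULL
  if (inherits(x, "abundance_table")) {
    profiles <- relative_abundance(x)
    d <- jsd_distance(profiles, sqrt = distance == "sqrt-jsd")
  } else if (inherits(x, "dist")) {
    d <- x
  } else stop2("x must be an abundance_table or a dist")
  m <- as.matrix(d)
  n <- nrow(m)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1))
    stop2("k_range must lie within [2, n - 1]")

  embed <- if (ch_variant == "pcoa") pcoa_embed(m) else NULL
  fits <- lapply(k_range, function(k) pam_cluster(d, k))
  ch <- vapply(seq_along(k_range), function(i)
    ch_index(m, fits[[i]]$clustering, variant = ch_variant,
             coords = embed$coords), numeric(1))
  names(ch) <- k_range

  if (is.null(force_k)) {
    best_i <- which.max(ch)  # ties -> first, i.e. smallest k
  } else {
    if (!force_k %in% k_range) stop2("force_k must be in k_range")
    best_i <- match(force_k, k_range)
  }
  best_k <- k_range[best_i]
  part <- fits[[best_i]]
  ps <- prediction_strength(d, best_k, repeats = ps_repeats, seed = seed)
  si <- silhouette_width(d, part$clustering)

  structure(list(dist = d, profiles = profiles, k_range = k_range,
                 ch_by_k = ch, best_k = best_k, partition = part,
                 ps = ps, si = si,
                 ps_class = classify_ps(ps), si_class = classify_si(si),
                 reliable = ps >= 0.9 && si > 0.25,
                 ps_repeats = ps_repeats, seed = seed,
                 call = match.call()),
            class = "enterotype")
}

#' @export
print.enterotype <- function(x, ...) {
  cat("Enterotype clustering fit\n")
  cat(sprintf("  samples: %d   k searched: %s\n", attr(x$dist, "Size"),
              paste(range(x$k_range), collapse = "-")))
  cat(sprintf("  selected k (max CH): %d   max CH: %.1f\n", x$best_k,
              max(x$ch_by_k)))
  cat(sprintf("  prediction strength: %.2f (%s)\n", x$ps, x$ps_class))
  cat(sprintf("  silhouette index:    %.2f (%s)\n", x$si, x$si_class))
  cat(sprintf("  statistically reliable clusters: %s\n",
              if (x$reliable) "yes" else "no"))
  invisible(x)
}

#' @export
summary.enterotype <- function(object, ...) {
  out <- list(
    n = attr(object$dist, "Size"),
    ch_by_k = object$ch_by_k,
    best_k = object$best_k,
    cluster_sizes = tabulate(object$partition$clustering, object$best_k),
    medoids = object$partition$medoids,
    ps = object$ps, si = object$si,
    ps_class = object$ps_class, si_class = object$si_class,
    reliable = object$reliable
  )
  class(out) <- "summary.enterotype"
  out
}

#' @export
print.summary.enterotype <- function(x, ...) {
  cat("Cluster validation report\n")
  cat(sprintf("  Cluster no. showing max CH score: %d\n", x$best_k))
  cat(sprintf("  Max CH score:        %.1f\n", max(x$ch_by_k)))
  cat(sprintf("  Prediction strength: %.2f  -> %s\n", x$ps, x$ps_class))
  cat(sprintf("  Silhouette index:    %.2f  -> %s\n", x$si, x$si_class))
  cat(sprintf("  Reliable (PS >= 0.9 and SI > 0.25): %s\n",
              if (x$reliable) "yes" else "no"))
  cat("  CH by k:\n")
  print(round(x$ch_by_k, 1))
  cat("  cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  cat("  medoids:", paste(x$medoids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.enterotype <- function(x, axes = c(1, 2), ...) {
  ord <- pcoa(x$dist)
  labs <- x$partition$clustering
  graphics::plot(ord$coords[, axes[1]], ord$coords[, axes[2]],
                 col = labs, pch = 19,
                 xlab = sprintf("PCo%d (%.1f%%)", axes[1], 100 * ord$contributions[axes[1]]),
                 ylab = sprintf("PCo%d (%.1f%%)", axes[2], 100 * ord$contributions[axes[2]]),
                 main = sprintf("PAM k = %d on %s", x$best_k,
                                attr(x$dist, "method") %||% "distance"), ...)
  med <- x$partition$medoid_index
  graphics::points(ord$coords[med, axes[1]], ord$coords[med, axes[2]],
                   pch = 8, cex = 2, col = seq_along(med))
  invisible(x)
}

#' Assign new samples to fitted enterotypes
#'
#' Classifies new samples to the nearest medoid profile under the fitted
#' distance. Requires the fit to have been made from an abundance table
#' (so medoid profiles are available).
#'
#' @param object an `enterotype` fit.
#' @param newdata an [abundance_table] over the same taxa.
#' @param ... unused.
#' @return integer cluster assignments named by sample.
#' @export
predict.enterotype <- function(object, newdata, ...) {
  if (is.null(object$profiles))
    stop2("fit was made from a distance matrix; no medoid profiles stored")
  stopifnot(inherits(newdata, "abundance_table"))
  rel <- relative_abundance(newdata)
  if (!identical(colnames(rel), colnames(object$profiles)))
    stop2("newdata must cover the same taxa in the same order")
  med_prof <- unclass(object$profiles)[object$partition$medoid_index, , drop = FALSE]
  rownames(med_prof) <- paste0(".medoid", seq_len(nrow(med_prof)))
  combined <- abundance_table(rbind(med_prof, unclass(rel) * 1),
                              kind = "relative", level = attr(rel, "level"))
  dd <- as.matrix(jsd_distance(combined, sqrt = identical(attr(object$dist, "method"), "sqrt-jsd")))
  k <- nrow(med_prof)
  assign <- apply(dd[-(seq_len(k)), seq_len(k), drop = FALSE], 1, which.min)
  stats::setNames(as.integer(assign), rownames(rel))
}
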