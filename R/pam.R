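#' Partitioning around medoids on a distance matrix
#'
#' Deterministic k-medoids. For tiny instances (`choose(n, k) <= 2000`) the
#' optimal medoid set is found by exact enumeration, which is as cheap as
#' the heuristic at that scale and avoids its occasional shallow local
#' optima. Larger instances use the classic BUILD phase (greedy seeding by
#' largest objective decrease) followed by SWAP steps that apply the best
#' improving medoid/non-medoid exchange until none remains, a local
#' optimum of the total distance-to-medoid objective. All ties are broken
#' toward the lowest sample index, making the fit reproducible.
#'
#' @param d a [stats::dist] or symmetric matrix of dissimilarities.
#' @param k number of clusters, `1 <= k <= n`.
#' @return an object of class `pam_partition`: list with `k`, `medoids`
#'   (sample ids, ascending by index), `medoid_index`, `clustering`
#'   (integer vector named by sample, cluster = position of its medoid in
#'   `medoids`), and `objective` (sum of distances to assigned medoids).
#' @examples
#' d <- dist(c(a = 0, b = 1, c = 10, d = 11))
#' pam_cluster(d, 2)
#' @export
pam_cluster <- function(d, k) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (is.null(rownames(m))) dimnames(m) <- list(seq_len(n), seq_len(n))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12, check.attributes = FALSE)))
    stop2("distance matrix must be symmetric")
  if (k < 1 || k > n) stop2("k must be between 1 and n = ", n)
  k <- as.integer(k)

  if (choose(n, k) <= 2000) return(pam_exact(m, k))

  # BUILD: start from the 1-medoid optimum, then greedily add the point
  # giving the largest decrease in objective (ties -> lowest index).
  med <- which.min(rowSums(m))
  nearest <- m[, med]
  while (length(med) < k) {
    cand <- setdiff(seq_len(n), med)
    gain <- vapply(cand, function(o) sum(pmax(nearest - m[, o], 0)), numeric(1))
    best <- cand[which.max(gain)]
    med <- c(med, best)
    nearest <- pmin(nearest, m[, best])
  }

  # SWAP: best-improvement exchanges using cached nearest / second-nearest
  # medoid distances.
  repeat {
    dm <- m[, med, drop = FALSE]
    ord <- apply(dm, 1, function(r) order(r)[1:2])
    if (k == 1) {
      near1 <- dm[, 1]
      near2 <- rep(Inf, n)
      which1 <- rep(1L, n)
    } else {
      which1 <- ord[1, ]
      near1 <- dm[cbind(seq_len(n), which1)]
      near2 <- dm[cbind(seq_len(n), ord[2, ])]
    }
    obj <- sum(near1)
    best_delta <- -1e-12
    best_swap <- NULL
    nonmed <- setdiff(seq_len(n), med)
    for (j in seq_along(med)) {
      hit <- which1 == j
      for (o in nonmed) {
        do <- m[, o]
        newcost <- sum(pmin(near1[!hit], do[!hit])) + sum(pmin(near2[hit], do[hit]))
        delta <- newcost - obj
        if (delta < best_delta) {
          best_delta <- delta
          best_swap <- c(j, o)
        }
      }
    }
    if (is.null(best_swap)) break
    med[best_swap[1]] <- best_swap[2]
  }

  pam_result(m, med)
}

# Exhaustive medoid search; first (lexicographically smallest) optimum wins.
pam_exact <- function(m, k) {
  n <- nrow(m)
  sets <- utils::combn(n, k)
  best <- Inf; best_set <- sets[, 1]
  for (i in seq_len(ncol(sets))) {
    obj <- sum(Reduce(pmin, lapply(sets[, i], function(j) m[, j])))
    if (obj < best - 1e-12) { best <- obj; best_set <- sets[, i] }
  }
  pam_result(m, best_set)
}

pam_result <- function(m, med) {
  n <- nrow(m)
  k <- length(med)
  med <- sort(med)
  dm <- m[, med, drop = FALSE]
  clustering <- apply(dm, 1, which.min)  # ties -> first, i.e. lowest medoid index
  structure(list(k = k, medoids = rownames(m)[med], medoid_index = med,
                 clustering = stats::setNames(as.integer(clustering), rownames(m)),
                 objective = sum(dm[cbind(seq_len(n), clustering)])),
            class = "pam_partition")
}

#' @export
print.pam_partition <- function(x, ...) {
  cat(sprintf("PAM partition: k = %d, objective = %.6g\n", x$k, x$objective))
  cat("medoids:", paste(x$medoids, collapse = ", "), "\n")
  cat("cluster sizes:", paste(tabulate(x$clustering, x$k), collapse = ", "), "\n")
  invisible(x)
}
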