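#' Two-group hypothesis tests
#'
#' Thin, validated wrappers around the standard tests used for cohort
#' comparisons: Welch's t test for numerical data, the Mann-Whitney U test
#' for ordinal data (exact only for small untied samples, otherwise the
#' tie-corrected normal approximation with continuity correction), and
#' Fisher's exact test for prevalence contingency tables. Each returns a
#' uniform `micro_test` record.
#'
#' @name two_group_tests
#' @param x,y numeric vectors, one per group.
#' @return a `micro_test` list: `statistic`, `p_value`, `test_name`,
#'   `group_sizes`, `effect_direction` (sign of the x-vs-y effect).
NULL

micro_test <- function(statistic, p_value, test_name, group_sizes, effect_direction = 0) {
  structure(list(statistic = unname(statistic), p_value = unname(min(max(p_value, 0), 1)),
                 test_name = test_name, group_sizes = group_sizes,
                 effect_direction = sign(effect_direction)),
            class = "micro_test")
}

#' @export
print.micro_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$test_name,
              x$statistic, x$p_value, paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}

#' @rdname two_group_tests
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop2("Welch's t test needs n >= 2 per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    # both groups constant: t.test would refuse; identical constants give
    # no evidence of difference, distinct constants a degenerate certainty
    same <- mean(x) == mean(y)
    return(micro_test(if (same) 0 else Inf * sign(mean(x) - mean(y)),
                      if (same) 1 else 0,
                      "Welch's t", c(length(x), length(y)), mean(x) - mean(y)))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  micro_test(ht$statistic, ht$p.value, "Welch's t", c(length(x), length(y)),
             mean(x) - mean(y))
}

#' @rdname two_group_tests
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop2("Mann-Whitney U test needs nonempty groups")
  ties <- anyDuplicated(c(x, y)) > 0
  if (ties && length(unique(c(x, y))) == 1)
    return(micro_test(length(x) * length(y) / 2, 1, "Mann-Whitney U",
                      c(length(x), length(y)), 0))
  exact <- !ties && length(x) <= 8 && length(y) <= 8
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  micro_test(ht$statistic, ht$p.value, "Mann-Whitney U",
             c(length(x), length(y)), mean(rank(c(x, y))[seq_along(x)]) -
               mean(rank(c(x, y))[-seq_along(x)]))
}

#' @rdname two_group_tests
#' @param table 2x2 matrix of nonnegative integer counts.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop2("fisher_exact expects a 2x2 table")
  if (any(table < 0) || any(abs(table - round(table)) > 1e-8))
    stop2("cells must be nonnegative integers")
  if (sum(table) < 1) stop2("empty table")
  ht <- stats::fisher.test(table)
  micro_test(unname(ht$estimate), ht$p.value, "Fisher's exact",
             c(sum(table[1, ]), sum(table[2, ])),
             table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1])
}

#' Holm step-down adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop2("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Kendall tau-b correlation
#'
#' Tau-b with tie corrections in both margins; the two-sided p-value comes
#' from the tie-adjusted normal approximation of the concordance statistic
#' (the sample sizes this package targets make exact enumeration
#' unnecessary). A constant margin leaves tau undefined: by default this is
#' an error; with `on_constant = "missing"` an `NA` record is returned so
#' callers (e.g. the network builder) can exclude the pair.
#'
#' @param x,y paired numeric/ordinal vectors, `n >= 3`.
#' @param a,b optional node labels for the returned edge record.
#' @param on_constant `"error"` or `"missing"`.
#' @return a `correlation_edge` list: `a`, `b`, `tau`, `p_value`, `n`.
#' @export
kendall_tau_b <- function(x, y, a = "x", b = "y", on_constant = c("error", "missing")) {
  on_constant <- match.arg(on_constant)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop2("kendall_tau_b needs at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    if (on_constant == "error")
      stop2("tau is undefined for a constant variable (", a, " vs ", b, ")")
    return(structure(list(a = a, b = b, tau = NA_real_, p_value = NA_real_,
                          n = length(x)), class = "correlation_edge"))
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = FALSE, continuity = FALSE))
  structure(list(a = a, b = b, tau = unname(ht$estimate),
                 p_value = unname(ht$p.value), n = length(x)),
            class = "correlation_edge")
}

#' @export
print.correlation_edge <- function(x, ...) {
  cat(sprintf("%s ~ %s: tau = %.3f, p = %.3g (n = %d)\n", x$a, x$b,
              x$tau, x$p_value, x$n))
  invisible(x)
}

#' Compact letter display from pairwise p-values
#'
#' Insert-and-absorb letter assignment: two groups share a letter exactly
#' when their (adjusted) pairwise p-value is at least `alpha`, the
#' convention used in superscripted cohort tables.
#'
#' @param p_matrix symmetric matrix of pairwise p-values with group names
#'   as dimnames (diagonal ignored).
#' @param alpha significance level (default 0.05).
#' @return named character vector, one letter string per group.
#' @examples
#' p <- matrix(1, 3, 3, dimnames = list(c("A","B","C"), c("A","B","C")))
#' p["A", "C"] <- p["C", "A"] <- 0.001
#' compact_letters(p)
#' @export
compact_letters <- function(p_matrix, alpha = 0.05) {
  p_matrix <- as.matrix(p_matrix)
  g <- nrow(p_matrix)
  if (g != ncol(p_matrix)) stop2("p_matrix must be square")
  if (is.null(rownames(p_matrix))) dimnames(p_matrix) <- list(seq_len(g), seq_len(g))
  if (!isTRUE(all.equal(p_matrix, t(p_matrix), tolerance = 1e-12,
                        check.attributes = FALSE)))
    stop2("p_matrix must be symmetric")
  groups <- rownames(p_matrix)
  sets <- list(seq_len(g))  # letters as index sets; start with one covering all
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    if (is.na(p_matrix[i, j]) || p_matrix[i, j] >= alpha) next
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb letters that are subsets of another
    keep <- rep(TRUE, length(new_sets))
    for (u in seq_along(new_sets)) for (v in seq_along(new_sets)) {
      if (u != v && keep[v] &&
          all(new_sets[[u]] %in% new_sets[[v]]) &&
          (length(new_sets[[u]]) < length(new_sets[[v]]) || u > v))
        keep[u] <- FALSE
    }
    sets <- new_sets[keep]
  }
  # order letters by their first member for stable output
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  out <- stats::setNames(rep("", g), groups)
  for (li in seq_along(sets))
    out[sets[[li]]] <- paste0(out[sets[[li]]], letters[li])
  out
}
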