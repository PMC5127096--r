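#' Alpha diversity and coverage statistics
#'
#' Per-sample Shannon index (log base 2 by default), bias-corrected Chao1
#' richness, Good's coverage and observed taxon count.
#'
#' @name diversity
#' @param counts numeric vector of per-taxon counts for one sample.
#' @param base logarithm base for the Shannon index (default 2).
NULL

check_sample_counts <- function(counts, integer_required = FALSE) {
  if (anyNA(counts) || any(counts < 0)) stop2("counts must be nonnegative")
  if (sum(counts) <= 0) stop2("degenerate sample: all counts are zero")
  if (integer_required && any(abs(counts - round(counts)) > 1e-8))
    stop2("counts must be integers")
  invisible(counts)
}

#' @rdname diversity
#' @return `shannon_index`: entropy of the relative composition, in bits
#'   when `base = 2`.
#' @examples
#' shannon_index(c(1, 1, 2))   # 1.5 bits
#' chao1(c(1, 1, 2))           # 3.5
#' goods_coverage(c(1, 2, 3))  # 5/6
#' @export
shannon_index <- function(counts, base = 2) {
  check_sample_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' @rdname diversity
#' @param bias_corrected use the bias-corrected estimator
#'   `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` (default); otherwise the classic
#'   `S_obs + F1^2 / (2 F2)` form (undefined when `F2 = 0`, where the
#'   bias-corrected form is substituted).
#' @return `chao1`: estimated total richness (>= observed richness).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  check_sample_counts(counts, integer_required = TRUE)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected || f2 == 0) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else s_obs + f1^2 / (2 * f2)
}

#' @rdname diversity
#' @return `goods_coverage`: `1 - F1/N`, the estimated fraction of the
#'   community captured at this depth, in `[0, 1]`.
#' @export
goods_coverage <- function(counts) {
  check_sample_counts(counts, integer_required = TRUE)
  1 - sum(counts == 1) / sum(counts)
}

#' Per-sample diversity profile of a count table
#'
#' @param table an [abundance_table] of counts.
#' @param base Shannon logarithm base.
#' @return data frame with columns `sample_id`, `observed_taxa`, `shannon`,
#'   `chao1`, `goods_coverage`.
#' @export
alpha_diversity <- function(table, base = 2) {
  stopifnot(inherits(table, "abundance_table"))
  if (attr(table, "kind") != "counts")
    stop2("alpha diversity requires raw counts")
  m <- unclass(table)
  data.frame(
    sample_id = rownames(m),
    observed_taxa = apply(m, 1, function(v) sum(v > 0)),
    shannon = apply(m, 1, shannon_index, base = base),
    chao1 = apply(m, 1, chao1),
    goods_coverage = apply(m, 1, goods_coverage),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
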