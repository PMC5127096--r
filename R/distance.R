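#' Jensen-Shannon distances between samples
#'
#' Computes, for every pair of samples, the square root of the
#' Jensen-Shannon divergence of their relative compositions (natural-log
#' entropy): `d(a, b) = sqrt(H((a+b)/2) - (H(a) + H(b))/2)` with
#' `0 log 0 := 0`. The square root makes the divergence a metric, bounded
#' by `sqrt(log 2) ~ 0.8326` (attained for disjoint supports). Plain JSD is
#' available via `sqrt = FALSE`.
#'
#' @param table an [abundance_table] with `kind = "relative"` (convert
#'   counts with [relative_abundance()]).
#' @param sqrt take the square root (default TRUE; the metric form used for
#'   clustering).
#' @return a [stats::dist] object labelled with sample ids.
#' @export
jsd_distance <- function(table, sqrt = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  if (attr(table, "kind") != "relative")
    stop2("jsd_distance requires relative abundances (rows summing to 1)")
  x <- unclass(table)
  n <- nrow(x)
  plogp <- function(p) ifelse(p > 0, p * log(p), 0)
  h <- -rowSums(plogp(x))  # per-sample entropy, nats
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    m <- (x[rest, , drop = FALSE] + rep(x[i, ], each = length(rest))) / 2
    hm <- -rowSums(plogp(m))
    jsd <- pmax(hm - (h[i] + h[rest]) / 2, 0)  # clamp fp negatives
    d[i, rest] <- d[rest, i] <- if (sqrt) base::sqrt(jsd) else jsd
  }
  out <- stats::as.dist(d)
  attr(out, "method") <- if (sqrt) "sqrt-jsd" else "jsd"
  out
}

#' UPGMA dendrogram of a distance matrix
#'
#' Average-linkage agglomeration with cluster-size weighting; node heights
#' are half the merge distance, giving the ultrametric tree in which the
#' path between two leaves through their first common ancestor equals their
#' cophenetic distance.
#'
#' @param d a [stats::dist] (e.g. from [jsd_distance()]).
#' @return an [ape::as.phylo] ultrametric tree (class `phylo`), with the
#'   underlying `hclust` object attached as attribute `"hclust"`.
#' @seealso [write_newick()]
#' @export
upgma <- function(d) {
  d <- stats::as.dist(d)
  if (attr(d, "Size") < 2) stop2("UPGMA needs at least 2 samples")
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)  # tip depth becomes merge distance / 2
  hc$height <- hc$height / 2  # report ultrametric node heights directly
  attr(phy, "hclust") <- hc
  phy
}

#' Write a dendrogram as newick
#'
#' @param tree a `phylo` object (e.g. from [upgma()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as square TSV
#'
#' @param d a [stats::dist].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
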