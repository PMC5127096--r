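#' Kendall tau-b correlation network
#'
#' Tests every taxon-taxon pair (and, when questionnaire items are given,
#' every item-taxon pair) with [kendall_tau_b()] and keeps the edges
#' passing both filters: `p < p_threshold` and `|tau| > tau_threshold`
#' (defaults 0.001 and 0.2, the conventional cut-offs for these networks).
#' Pairs with a constant margin are reported with missing tau and never
#' enter the edge set.
#'
#' @param table an [abundance_table]; counts are converted to relative
#'   abundances.
#' @param items optional data frame of ordinal questionnaire scores, rows
#'   aligned with the table's samples.
#' @param p_threshold,tau_threshold edge filters.
#' @param include_taxon_pairs test taxon-taxon pairs (default TRUE; set
#'   FALSE to test only item-taxon pairs).
#' @return a `correlation_network`: list with `nodes`, `edges` (data frame
#'   `a`, `b`, `tau`, `p_value` of the retained edges), `tests` (all pairs
#'   tested) and the thresholds.
#' @export
build_network <- function(table, items = NULL, p_threshold = 0.001,
                          tau_threshold = 0.2, include_taxon_pairs = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  rel <- unclass(relative_abundance(table))
  vars <- as.data.frame(rel)
  taxa <- colnames(rel)
  item_names <- character(0)
  if (!is.null(items)) {
    items <- as.data.frame(items)
    if (nrow(items) != nrow(rel))
      stop2("items must have one row per sample")
    item_names <- colnames(items)
    vars <- cbind(vars, items)
  }
  pairs <- list()
  if (include_taxon_pairs && length(taxa) >= 2) {
    idx <- utils::combn(taxa, 2)
    pairs <- c(pairs, lapply(seq_len(ncol(idx)), function(i) idx[, i]))
  }
  for (it in item_names) for (tx in taxa) pairs <- c(pairs, list(c(it, tx)))
  if (length(pairs) == 0) stop2("need at least 2 nodes to build a network")

  tests <- do.call(rbind, lapply(pairs, function(pr) {
    e <- kendall_tau_b(vars[[pr[1]]], vars[[pr[2]]], a = pr[1], b = pr[2],
                       on_constant = "missing")
    data.frame(a = e$a, b = e$b, tau = e$tau, p_value = e$p_value,
               stringsAsFactors = FALSE)
  }))
  pass <- !is.na(tests$tau) & tests$p_value < p_threshold &
    abs(tests$tau) > tau_threshold
  structure(list(nodes = c(taxa, item_names), edges = tests[pass, , drop = FALSE],
                 tests = tests, p_threshold = p_threshold,
                 tau_threshold = tau_threshold),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network: %d nodes, %d/%d pairs pass (p < %g, |tau| > %g)\n",
              length(x$nodes), nrow(x$edges), nrow(x$tests),
              x$p_threshold, x$tau_threshold))
  if (nrow(x$edges)) {
    show <- x$edges[order(-abs(x$edges$tau)), ]
    print(utils::head(show, 10), row.names = FALSE)
  }
  invisible(x)
}

#' Write a network edge list as TSV
#'
#' @param network a `correlation_network`.
#' @param path output file.
#' @param all write all tested pairs instead of only retained edges.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, all = FALSE) {
  df <- if (all) network$tests else network$edges
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
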