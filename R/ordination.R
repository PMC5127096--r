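#' Principal component biplot coordinates
#'
#' PCA of the column-centred (unscaled) sample x taxon matrix of relative
#' abundances: scores are the centred data projected on the covariance
#' eigenvectors, loadings are the eigenvectors, and each axis's
#' contribution is its eigenvalue's share of the total variance. Axis signs
#' are fixed so the largest-magnitude loading on each axis is positive,
#' making the output deterministic.
#'
#' @param table an [abundance_table] with `kind = "relative"`.
#' @return an `ordination` object: list with `method = "pca"`, `coords`
#'   (sample scores), `loadings` (taxon x axis), `contributions`
#'   (per-axis variance fractions).
#' @export
pca_biplot <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (attr(table, "kind") != "relative")
    stop2("pca_biplot expects relative abundances")
  x <- unclass(table)
  if (nrow(x) < 3 || ncol(x) < 2) stop2("need at least 3 samples and 2 taxa")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (sum(pc$sdev^2) <= 0) stop2("matrix has zero variance")
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  structure(list(method = "pca", coords = scores, loadings = loadings,
                 contributions = pc$sdev^2 / sum(pc$sdev^2)),
            class = "ordination")
}

#' Principal coordinates analysis
#'
#' Classical scaling (Gower double-centring of squared dissimilarities):
#' only positive-eigenvalue axes are kept; with non-Euclidean input (such
#' as square-root Jensen-Shannon distances) the magnitude of the discarded
#' negative eigenvalues is recorded in `negative_magnitude`. Axis
#' contributions are eigenvalue shares of the positive total.
#'
#' @param d a [stats::dist].
#' @return an `ordination` object with `method = "pcoa"`, `coords`,
#'   `contributions`, `eigenvalues` and `negative_magnitude`.
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop2("need at least 3 samples")
  if (all(m == 0)) stop2("all distances are zero")
  emb <- pcoa_embed(m)
  coords <- emb$coords
  flip <- apply(coords, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  coords <- sweep(coords, 2, flip, `*`)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(method = "pcoa", coords = coords,
                 contributions = emb$positive[seq_len(ncol(coords))] / sum(emb$positive),
                 eigenvalues = emb$eig,
                 negative_magnitude = emb$negative_magnitude),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, %d axes\n", toupper(x$method),
              nrow(x$coords), ncol(x$coords)))
  pct <- round(100 * x$contributions[seq_len(min(3, length(x$contributions)))], 1)
  cat("axis contributions (%):", paste(pct, collapse = ", "),
      if (length(x$contributions) > 3) "..." else "", "\n")
  invisible(x)
}

#' Write ordination coordinates (and loadings) as TSV
#'
#' @param ord an `ordination` object.
#' @param path coordinates output file; contributions are written as a
#'   commented header line, loadings (PCA) to `<path>.loadings.tsv`.
#' @return `path`, invisibly.
#' @export
write_ordination <- function(ord, path) {
  con <- file(path, "w")
  writeLines(sprintf("# axis contributions (%%): %s",
                     paste(round(100 * ord$contributions, 1), collapse = "\t")), con)
  df <- data.frame(sample_id = rownames(ord$coords), ord$coords, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(ord$loadings)) {
    lf <- data.frame(taxon_id = rownames(ord$loadings), ord$loadings, check.names = FALSE)
    utils::write.table(lf, paste0(path, ".loadings.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
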