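#' Sample-by-taxon abundance tables
#'
#' An `abundance_table` is a numeric matrix with samples in rows and taxa in
#' columns, tagged with the kind of values it holds (`"counts"` or
#' `"relative"`) and the taxonomic rank of its columns (e.g. `"family"`).
#' It is the common currency of the package: the simulator emits one, the
#' diversity, distance, ordination and association functions consume one.
#'
#' @param x numeric matrix, samples x taxa, with unique row (sample) and
#'   column (taxon) names; all values must be nonnegative.
#' @param kind `"counts"` or `"relative"`. Relative tables must have rows
#'   summing to 1 (tolerance 1e-9).
#' @param level taxonomic rank label for the columns (default `"family"`).
#' @return an object of class `abundance_table` (a matrix with attributes).
#' @examples
#' m <- matrix(c(10, 0, 5, 85, 60, 40), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' tab <- abundance_table(m)
#' relative_abundance(tab)
#' @export
abundance_table <- function(x, kind = c("counts", "relative"), level = "family") {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop2("abundance_table requires sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(x)))
    stop2("duplicate sample ids: ", paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop2("duplicate taxon ids: ", paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x) || any(x < 0))
    stop2("abundance values must be nonnegative and non-missing")
  if (kind == "relative") {
    rs <- rowSums(x)
    if (any(abs(rs - 1) > 1e-9))
      stop2("relative abundance rows must sum to 1; offending samples: ",
            paste(rownames(x)[abs(rs - 1) > 1e-9], collapse = ", "))
  }
  structure(x, kind = kind, level = level, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s, rank: %s)\n",
              nrow(x), ncol(x), attr(x, "kind"), attr(x, "level")))
  n <- min(nrow(x), 5L); p <- min(ncol(x), 5L)
  print(unclass(x)[seq_len(n), seq_len(p), drop = FALSE], ...)
  if (nrow(x) > n || ncol(x) > p)
    cat(sprintf("... (%d more samples, %d more taxa)\n", nrow(x) - n, ncol(x) - p))
  invisible(x)
}

#' @export
`[.abundance_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, kind = attr(x, "kind"), level = attr(x, "level"),
                     class = class(x))
  out
}

table_kind <- function(x) attr(x, "kind")

#' Read an abundance table from disk
#'
#' Reads the tab-separated layout used throughout this package (taxa in rows,
#' samples in columns, first header cell `taxon_id`) or a dense BIOM-style
#' JSON file. Tables are returned in the in-memory orientation
#' (samples x taxa) with `kind = "counts"`.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom-json"`.
#' @param level rank label to attach.
#' @return an [abundance_table].
#' @seealso [write_abundance()]
#' @export
read_abundance <- function(path, format = c("tsv", "biom-json"), level = "family") {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#", fill = FALSE)
    if (ncol(df) < 2) stop2("malformed table (need taxon id column plus samples): ", path)
    taxa <- as.character(df[[1]])
    cells <- df[, -1, drop = FALSE]
    mat <- matrix(suppressWarnings(vapply(cells, as.numeric, numeric(nrow(df)))),
                  nrow = nrow(df), dimnames = list(taxa, colnames(cells)))
    bad <- is.na(mat) & !is.na(as.matrix(cells))
    if (any(bad))
      stop2("non-numeric cells in ", path, " (first offending row: ",
            taxa[which(rowSums(matrix(bad, nrow = nrow(df))) > 0)[1]], ")")
    if (anyNA(mat)) stop2("missing values in ", path)
    mat <- t(mat)  # disk is taxa x samples; memory is samples x taxa
  } else {
    biom <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (!identical(biom$matrix_type, "dense"))
      stop2("only dense BIOM-style JSON is supported")
    dat <- biom$data
    if (is.list(dat)) dat <- do.call(rbind, dat)
    dimnames(dat) <- list(biom$rows$id, biom$columns$id)
    mat <- t(dat)
  }
  if (any(mat < 0)) {
    bad <- colnames(mat)[apply(mat, 2, function(v) any(v < 0))]
    stop2("negative values for taxa: ", paste(bad, collapse = ", "))
  }
  abundance_table(mat, kind = "counts", level = level)
}

#' Write an abundance table to disk
#'
#' @param table an [abundance_table].
#' @param path output file path.
#' @param format `"tsv"` (taxa rows x sample columns) or `"biom-json"`
#'   (dense BIOM 1.0-style JSON).
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "abundance_table"))
  if (format == "tsv") {
    m <- t(unclass(table))  # taxa x samples on disk
    df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    m <- t(unclass(table))
    biom <- list(
      id = NULL,
      format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org",
      type = "OTU table",
      generated_by = paste0("enterotyper ", as.character(utils::packageVersion("enterotyper"))),
      matrix_type = "dense",
      matrix_element_type = if (attr(table, "kind") == "counts") "int" else "float",
      shape = dim(m),
      rows = data.frame(id = rownames(m)),
      columns = data.frame(id = colnames(m)),
      data = unname(split(m, row(m)))
    )
    jsonlite::write_json(biom, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Taxonomy maps
#'
#' A taxonomy map links taxon ids (e.g. OTU ids) to a ranked lineage. It is
#' a data frame with a `taxon_id` column and one column per rank; `NA`
#' entries mark unclassified ranks.
#'
#' @param taxon_id character vector of taxon ids.
#' @param ... named character vectors, one per rank (e.g. `family = ...`),
#'   recycled to length of `taxon_id`; use `NA` for unclassified.
#' @return a `taxonomy_map` data frame.
#' @export
taxonomy_map <- function(taxon_id, ...) {
  ranks <- list(...)
  if (length(ranks) == 0) stop2("at least one rank column is required")
  df <- data.frame(taxon_id = as.character(taxon_id), ranks,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(df$taxon_id)) stop2("duplicate taxon ids in taxonomy")
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' Collapse a table to a taxonomic rank
#'
#' Sums member taxa into one row per distinct lineage value at `level`,
#' pooling taxa unclassified at that rank into a single
#' `unclassified_<level>` group. Per-sample totals are preserved.
#'
#' @param table an [abundance_table] whose columns appear in `taxonomy`.
#' @param taxonomy a [taxonomy_map] with a column named `level`.
#' @param level rank to collapse to (default `"family"`).
#' @return an [abundance_table] at the requested rank.
#' @export
collapse_taxa <- function(table, taxonomy, level = "family") {
  stopifnot(inherits(table, "abundance_table"))
  if (!level %in% names(taxonomy)) stop2("taxonomy has no rank column '", level, "'")
  idx <- match(colnames(table), taxonomy$taxon_id)
  if (anyNA(idx))
    stop2("taxa missing from taxonomy: ",
          paste(colnames(table)[is.na(idx)], collapse = ", "))
  grp <- as.character(taxonomy[[level]][idx])
  grp[is.na(grp) | grp == ""] <- paste0("unclassified_", level)
  out <- t(rowsum(t(unclass(table)), group = grp, reorder = FALSE))
  abundance_table(out, kind = attr(table, "kind"), level = level)
}

#' Convert counts to relative abundances
#'
#' Divides each cell by its sample total; rows of the result sum to 1.
#'
#' @param table an [abundance_table] of counts.
#' @return an [abundance_table] with `kind = "relative"`.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (attr(table, "kind") == "relative") return(table)
  totals <- rowSums(table)
  if (any(totals <= 0))
    stop2("samples with zero total count: ",
          paste(rownames(table)[totals <= 0], collapse = ", "))
  abundance_table(unclass(table) / totals, kind = "relative", level = attr(table, "level"))
}

#' Per-taxon prevalence
#'
#' Fraction of samples in which each taxon is detected (strictly positive
#' value), optionally within a subset of samples.
#'
#' @param table an [abundance_table] (counts or relative; the zero pattern
#'   is identical).
#' @param samples optional character vector of sample ids or logical/integer
#'   index; default all samples.
#' @return named numeric vector in `[0, 1]`, one entry per taxon.
#' @export
prevalence <- function(table, samples = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  m <- unclass(table)
  if (!is.null(samples)) {
    if (is.character(samples)) {
      missing <- setdiff(samples, rownames(m))
      if (length(missing)) stop2("unknown sample ids: ", paste(missing, collapse = ", "))
    }
    m <- m[samples, , drop = FALSE]
  }
  if (nrow(m) == 0) stop2("sample group is empty")
  colMeans(m > 0)
}
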