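#' Split samples into metadata strata
#'
#' Disjoint, exhaustive subsets of the samples with a non-missing value of
#' the stratifying variable; samples with missing values belong to no
#' subset and are reported via a message.
#'
#' @param metadata data frame with a `sample_id` column.
#' @param by name of the stratifying column (e.g. `"region"`, `"gender"`).
#' @return named list of character vectors of sample ids.
#' @export
stratify <- function(metadata, by) {
  if (!by %in% names(metadata)) stop2("unknown stratification variable: ", by)
  if (!"sample_id" %in% names(metadata)) stop2("metadata needs a sample_id column")
  v <- metadata[[by]]
  dropped <- sum(is.na(v))
  if (dropped > 0)
    message(dropped, " sample(s) with missing '", by, "' excluded from strata")
  split(metadata$sample_id[!is.na(v)], v[!is.na(v)])
}

star_code <- function(p) {
  if (is.na(p)) "NA" else if (p < 0.01) "**" else if (p < 0.05) "*" else "NS"
}

#' Stratified group comparison of taxon abundance and prevalence
#'
#' For each taxon: with two groups, Welch's t test on relative abundance
#' and Fisher's exact test on prevalence; with more than two groups, all
#' pairwise tests with Holm correction summarised as compact letter
#' displays. Questionnaire (ordinal) variables can be compared the same
#' way via the Mann-Whitney U test by passing them as extra columns.
#'
#' @param table an [abundance_table]; converted to relative abundances.
#' @param metadata data frame with `sample_id` and the grouping column.
#' @param by grouping variable name.
#' @param taxa taxa to compare (default all).
#' @param alpha significance level for letters/stars.
#' @return a data frame, one row per taxon and group, with mean, sd,
#'   prevalence and (two groups) p-values with stars or (more groups)
#'   compact letters for abundance and prevalence.
#' @export
group_compare <- function(table, metadata, by, taxa = NULL, alpha = 0.05) {
  stopifnot(inherits(table, "abundance_table"))
  rel <- unclass(relative_abundance(table))
  strata <- stratify(metadata, by)
  if (length(strata) < 2) stop2("need at least two groups")
  taxa <- taxa %||% colnames(rel)
  groups <- names(strata)
  out <- list()
  for (tx in taxa) {
    vals <- lapply(strata, function(ids) rel[ids, tx])
    det <- vapply(vals, function(v) sum(v > 0), numeric(1))
    n <- vapply(vals, length, numeric(1))
    row <- data.frame(taxon = tx, group = groups,
                      n = n,
                      mean_pct = 100 * vapply(vals, mean, numeric(1)),
                      sd_pct = 100 * vapply(vals, stats::sd, numeric(1)),
                      prevalence_pct = 100 * det / n,
                      stringsAsFactors = FALSE)
    if (length(groups) == 2) {
      pa <- welch_t(vals[[1]], vals[[2]])$p_value
      pp <- fisher_exact(rbind(c(det[1], n[1] - det[1]),
                               c(det[2], n[2] - det[2])))$p_value
      row$abundance_p <- pa
      row$abundance_sig <- star_code(pa)
      row$prevalence_p <- pp
      row$prevalence_sig <- star_code(pp)
    } else {
      row$abundance_letters <- pairwise_letters(vals, test = "welch", alpha = alpha)
      row$prevalence_letters <- pairwise_letters(
        lapply(seq_along(vals), function(i) c(det[i], n[i])),
        test = "fisher", alpha = alpha, labels = groups)
    }
    out[[tx]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Pairwise tests with Holm correction summarised as compact letters.
# vals: list per group of either raw values (welch / mann-whitney) or
# c(detected, n) pairs (fisher).
pairwise_letters <- function(vals, test = c("welch", "mann-whitney", "fisher"),
                             alpha = 0.05, labels = names(vals)) {
  test <- match.arg(test)
  g <- length(vals)
  labels <- labels %||% as.character(seq_len(g))
  pairs <- utils::combn(g, 2)
  p <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    switch(test,
      welch = welch_t(vals[[i]], vals[[j]])$p_value,
      `mann-whitney` = mann_whitney_u(vals[[i]], vals[[j]])$p_value,
      fisher = fisher_exact(rbind(
        c(vals[[i]][1], vals[[i]][2] - vals[[i]][1]),
        c(vals[[j]][1], vals[[j]][2] - vals[[j]][1])))$p_value)
  })
  p <- holm_adjust(p)
  pm <- matrix(1, g, g, dimnames = list(labels, labels))
  for (c_i in seq_len(ncol(pairs)))
    pm[pairs[1, c_i], pairs[2, c_i]] <- pm[pairs[2, c_i], pairs[1, c_i]] <- p[c_i]
  compact_letters(pm, alpha = alpha)
}

#' Lean/obese comparison of abundance, prevalence and bowel habit
#'
#' Stratifies the cohort by BMI into a lean (`BMI < lean_below`) and an
#' obese (`BMI > obese_above`) group, excluding the overweight middle, and
#' compares: each taxon's relative abundance (Welch's t test) and
#' prevalence (Fisher's exact test), and an ordinal questionnaire item
#' such as bowel movement frequency (Mann-Whitney U test). Defaults follow
#' the conventional cut-offs BMI < 25 (lean) and BMI > 30 (obese).
#'
#' @param table an [abundance_table].
#' @param metadata data frame with `sample_id`, `bmi` and the item column.
#' @param item name of the ordinal item to compare (default `"Q7"`); set
#'   NULL to skip.
#' @param taxa taxa to compare (default all).
#' @param lean_below,obese_above BMI cut-offs.
#' @return a `bmi_comparison` list with `item` (a `micro_test` or NULL),
#'   `taxa` (data frame per taxon: means, prevalences, p-values, stars)
#'   and the group sizes.
#' @export
bmi_strata_compare <- function(table, metadata, item = "Q7", taxa = NULL,
                               lean_below = 25, obese_above = 30) {
  stopifnot(inherits(table, "abundance_table"))
  if (!"bmi" %in% names(metadata)) stop2("metadata needs a 'bmi' column")
  keep <- !is.na(metadata$bmi)
  lean_ids <- metadata$sample_id[keep & metadata$bmi < lean_below]
  obese_ids <- metadata$sample_id[keep & metadata$bmi > obese_above]
  if (length(lean_ids) == 0 || length(obese_ids) == 0)
    stop2("empty BMI stratum (lean n = ", length(lean_ids),
          ", obese n = ", length(obese_ids), ")")
  rel <- unclass(relative_abundance(table))
  taxa <- taxa %||% colnames(rel)

  rows <- lapply(taxa, function(tx) {
    lv <- rel[lean_ids, tx]; ov <- rel[obese_ids, tx]
    pa <- welch_t(lv, ov)$p_value
    pp <- fisher_exact(rbind(c(sum(lv > 0), length(lv) - sum(lv > 0)),
                             c(sum(ov > 0), length(ov) - sum(ov > 0))))$p_value
    data.frame(taxon = tx,
               lean_mean_pct = 100 * mean(lv), lean_sd_pct = 100 * stats::sd(lv),
               obese_mean_pct = 100 * mean(ov), obese_sd_pct = 100 * stats::sd(ov),
               abundance_p = pa, abundance_sig = star_code(pa),
               lean_prevalence_pct = 100 * mean(lv > 0),
               obese_prevalence_pct = 100 * mean(ov > 0),
               prevalence_p = pp, prevalence_sig = star_code(pp),
               stringsAsFactors = FALSE)
  })
  item_test <- NULL
  if (!is.null(item)) {
    if (!item %in% names(metadata)) stop2("metadata has no item column '", item, "'")
    sc <- stats::setNames(metadata[[item]], metadata$sample_id)
    item_test <- mann_whitney_u(stats::na.omit(sc[lean_ids]),
                                stats::na.omit(sc[obese_ids]))
  }
  structure(list(item = item_test, item_name = item,
                 taxa = do.call(rbind, rows),
                 n_lean = length(lean_ids), n_obese = length(obese_ids),
                 lean_below = lean_below, obese_above = obese_above),
            class = "bmi_comparison")
}

#' @export
print.bmi_comparison <- function(x, ...) {
  cat(sprintf("BMI strata: lean (BMI < %g, n = %d) vs obese (BMI > %g, n = %d)\n",
              x$lean_below, x$n_lean, x$obese_above, x$n_obese))
  if (!is.null(x$item))
    cat(sprintf("%s (Mann-Whitney U): p = %.3g %s\n", x$item_name,
                x$item$p_value, star_code(x$item$p_value)))
  sig <- x$taxa[x$taxa$abundance_sig != "NS" | x$taxa$prevalence_sig != "NS", ]
  cat(nrow(sig), "of", nrow(x$taxa), "taxa significant at 0.05\n")
  if (nrow(sig)) print(sig[, c("taxon", "lean_mean_pct", "obese_mean_pct",
                               "abundance_p", "abundance_sig",
                               "prevalence_p", "prevalence_sig")],
                       row.names = FALSE, digits = 3)
  invisible(x)
}
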