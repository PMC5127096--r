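#' Pipeline configuration
#'
#' Assembles (or reads from YAML/JSON) the configuration of a full cohort
#' analysis run. Either `counts` (a TSV path) plus optional `metadata`
#' (TSV with sample_id and covariates) and `taxonomy` (TSV mapping
#' taxon_id to ranks) are given, or `synthetic` holds arguments for
#' [cohort_config()] and the cohort is generated. Every analysis threshold
#' is carried here rather than hard-coded in the stages.
#'
#' @param path optional YAML or JSON file to read the configuration from;
#'   explicitly supplied arguments override file values.
#' @param counts,metadata,taxonomy input file paths (NULL for synthetic).
#' @param synthetic list of [cohort_config()] arguments.
#' @param level rank to collapse to when a taxonomy is given.
#' @param k_range candidate cluster numbers.
#' @param ps_repeats prediction-strength repeats.
#' @param p_threshold,tau_threshold network filters.
#' @param strata metadata variables for stratified clustering/comparisons.
#' @param bmi_item ordinal item for the BMI comparison (NULL to skip).
#' @param min_stratum_n smallest stratum for which per-stratum cluster
#'   validation is attempted.
#' @param seed integer seed for all stochastic stages.
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, counts = NULL, metadata = NULL,
                            taxonomy = NULL, synthetic = list(),
                            level = "family", k_range = 2:10,
                            ps_repeats = 100, p_threshold = 0.001,
                            tau_threshold = 0.2,
                            strata = c("region", "gender"), bmi_item = "Q7",
                            min_stratum_n = 20, seed = 1L, out_dir = "results") {
  cfg <- list(counts = counts, metadata = metadata, taxonomy = taxonomy,
              synthetic = synthetic, level = level, k_range = k_range,
              ps_repeats = ps_repeats, p_threshold = p_threshold,
              tau_threshold = tau_threshold, strata = strata,
              bmi_item = bmi_item, min_stratum_n = min_stratum_n,
              seed = seed, out_dir = out_dir)
  if (!is.null(path)) {
    if (!file.exists(path)) stop2("config file not found: ", path)
    file_cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
                else jsonlite::fromJSON(path, simplifyVector = TRUE)
    supplied <- names(as.list(match.call())[-1])
    for (nm in names(file_cfg))
      if (!nm %in% supplied) cfg[[nm]] <- file_cfg[[nm]]
  }
  for (f in c("counts", "metadata", "taxonomy"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop2("configured ", f, " file does not exist: ", cfg[[f]])
  cfg$k_range <- as.integer(cfg$k_range)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

config_fingerprint <- function(config) {
  fnv1a32(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                           null = "null"))
}

write_stage_tsv <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the full cohort analysis pipeline
#'
#' Executes, in order: data ingest (or synthetic cohort generation), rank
#' collapse, relative abundance and prevalence, alpha diversity, sqrt-JSD
#' distances, UPGMA dendrogram, PCA and PCoA ordination, enterotype
#' cluster validation for the whole cohort and per stratum, stratified
#' group comparisons with Holm-corrected compact letters, the Kendall
#' tau-b correlation network, and the lean/obese BMI comparison. Every
#' output carries a header with the package version, seed and a
#' configuration fingerprint; a manifest of written files is returned and
#' saved. Re-running with an unchanged configuration and an existing
#' manifest is a no-op unless `force = TRUE`.
#'
#' @param config a [pipeline_config()] (or a path to one).
#' @param force rerun even if an up-to-date manifest exists.
#' @return data frame manifest (stage, file), invisibly.
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- pipeline_config(path = config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  fp <- config_fingerprint(config)
  manifest_path <- file.path(out, "manifest.tsv")
  if (!force && file.exists(manifest_path)) {
    prev <- utils::read.delim(manifest_path, comment.char = "")
    if (any(grepl(fp, prev$file)) || fp %in% prev$fingerprint) {
      message("manifest up to date (fingerprint ", fp, "); use force = TRUE to rerun")
      return(invisible(prev))
    }
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# enterotyper %s seed=%d config=%s",
                 as.character(utils::packageVersion("enterotyper")),
                 config$seed, fp)
  manifest <- data.frame(stage = character(0), file = character(0))
  note <- function(stage, file) {
    message(sprintf("[%s] wrote %s", stage, file))
    manifest <<- rbind(manifest, data.frame(stage = stage, file = file))
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e)
      stop2("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  }

  # -- ingest or generate ----------------------------------------------
  metadata <- NULL
  run_stage("ingest", {
    if (!is.null(config$counts)) {
      tab <- read_abundance(config$counts, level = if (is.null(config$taxonomy)) config$level else "otu")
      if (!is.null(config$metadata))
        metadata <- utils::read.delim(config$metadata, stringsAsFactors = FALSE,
                                      comment.char = "#")
      if (!is.null(config$taxonomy)) {
        txdf <- utils::read.delim(config$taxonomy, stringsAsFactors = FALSE,
                                  comment.char = "#")
        class(txdf) <- c("taxonomy_map", "data.frame")
        tab <- collapse_taxa(tab, txdf, level = config$level)
      }
    } else {
      cc <- do.call(cohort_config, c(config$synthetic, list(seed = config$seed)))
      cohort <- generate_cohort(cc)
      tab <- cohort$counts
      metadata <- cohort$metadata
      note("ingest", write_stage_tsv(
        data.frame(sample_id = rownames(tab), true_label = cohort$true_labels),
        file.path(out, "true_labels.tsv"), hdr))
    }
    write_abundance(tab, file.path(out, "counts.tsv"))
    note("ingest", file.path(out, "counts.tsv"))
    if (!is.null(metadata))
      note("ingest", write_stage_tsv(metadata, file.path(out, "metadata.tsv"), hdr))
    tab
  }) -> tab

  rel <- run_stage("relative_abundance", {
    rel <- relative_abundance(tab)
    note("relative_abundance", write_stage_tsv(
      data.frame(taxon_id = colnames(rel), t(unclass(rel)), check.names = FALSE),
      file.path(out, "relative_abundance.tsv"), hdr))
    prev <- prevalence(tab)
    note("prevalence", write_stage_tsv(
      data.frame(taxon_id = names(prev), prevalence = prev),
      file.path(out, "prevalence.tsv"), hdr))
    rel
  })

  run_stage("diversity", {
    div <- alpha_diversity(tab)
    note("diversity", write_stage_tsv(div, file.path(out, "alpha_diversity.tsv"), hdr))
  })

  d <- run_stage("distance", {
    d <- jsd_distance(rel)
    note("distance", write_distance(d, file.path(out, "sqrt_jsd.tsv")))
    note("dendrogram", write_newick(upgma(d), file.path(out, "upgma.nwk")))
    d
  })

  run_stage("ordination", {
    note("ordination", write_ordination(pca_biplot(rel), file.path(out, "pca.tsv")))
    note("ordination", write_ordination(pcoa(d), file.path(out, "pcoa.tsv")))
  })

  validations <- run_stage("cluster_validation", {
    fit_one <- function(dd, label) {
      n <- attr(dd, "Size")
      kr <- config$k_range[config$k_range <= min(floor(n / 2), n - 1)]
      fit <- enterotype(dd, k_range = kr, ps_repeats = config$ps_repeats,
                        seed = config$seed)
      data.frame(stratum = label, n = n, best_k = fit$best_k,
                 max_ch = max(fit$ch_by_k), prediction_strength = fit$ps,
                 silhouette = fit$si, ps_class = fit$ps_class,
                 si_class = fit$si_class, reliable = fit$reliable)
    }
    rows <- list(fit_one(d, "whole"))
    if (!is.null(metadata)) {
      for (v in intersect(config$strata, names(metadata))) {
        st <- stratify(metadata, v)
        for (s in names(st)) {
          ids <- st[[s]]
          if (length(ids) < config$min_stratum_n) {
            message("stratum ", v, "=", s, " too small (n=", length(ids), "); skipped")
            next
          }
          dd <- stats::as.dist(as.matrix(d)[ids, ids])
          rows <- c(rows, list(fit_one(dd, paste0(v, ":", s))))
        }
      }
    }
    df <- do.call(rbind, rows)
    note("cluster_validation", write_stage_tsv(
      df, file.path(out, "cluster_validation.tsv"), hdr))
    df
  })

  if (!is.null(metadata)) {
    run_stage("group_comparisons", {
      for (v in intersect(config$strata, names(metadata))) {
        cmp <- group_compare(tab, metadata, by = v)
        note("group_comparisons", write_stage_tsv(
          cmp, file.path(out, paste0("compare_", v, ".tsv")), hdr))
      }
    })
  }

  run_stage("network", {
    reserved <- c("sample_id", "region", "gender", "age", "bmi")
    items <- if (!is.null(metadata))
      metadata[, setdiff(names(metadata), reserved), drop = FALSE] else NULL
    if (!is.null(items) && ncol(items) == 0) items <- NULL
    net <- build_network(tab, items = items, p_threshold = config$p_threshold,
                         tau_threshold = config$tau_threshold)
    note("network", write_network(net, file.path(out, "network_edges.tsv")))
  })

  if (!is.null(metadata) && !is.null(config$bmi_item) &&
      "bmi" %in% names(metadata) && config$bmi_item %in% names(metadata)) {
    lean <- sum(metadata$bmi < 25, na.rm = TRUE)
    obese <- sum(metadata$bmi > 30, na.rm = TRUE)
    if (lean > 1 && obese > 1) {
      run_stage("bmi_comparison", {
        bc <- bmi_strata_compare(tab, metadata, item = config$bmi_item)
        note("bmi_comparison", write_stage_tsv(
          bc$taxa, file.path(out, "bmi_comparison.tsv"), hdr))
      })
    } else message("BMI stratum too small (lean=", lean, ", obese=", obese,
                   "); comparison skipped")
  }

  manifest$fingerprint <- fp
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("manifest: ", manifest_path, " (", nrow(manifest), " files)")
  invisible(manifest)
}
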