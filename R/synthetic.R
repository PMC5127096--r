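#' Enterotype archetypes for cohort simulation
#'
#' An archetype is the centre of an enterotype-like cluster: a mean
#' family-level composition plus a Dirichlet precision controlling how
#' tightly simulated samples scatter around it. The default archetypes mimic
#' the configurations repeatedly reported for the human gut: one driven by
#' Prevotellaceae, the other by Bacteroidaceae with Lachnospiraceae and
#' Ruminococcaceae.
#'
#' `dominant` fixes the mean proportions of named families; the remaining
#' mass is spread over all other taxa following a geometric rank-abundance
#' decay, so minor families have realistic, unequal means.
#'
#' @param name archetype label.
#' @param dominant named numeric vector of mean proportions for the driver
#'   families; names must appear in `taxa`; must sum to < 1.
#' @param concentration Dirichlet precision (total alpha); higher values
#'   give tighter clusters.
#' @param taxa character vector of taxon ids for the community (default the
#'   66-family panel of [default_taxa()]).
#' @param decay geometric decay rate of the background rank-abundance
#'   profile (default 0.9).
#' @return an object of class `enterotype_archetype` with fields `name`,
#'   `mean_composition` (named, sums to 1) and `concentration`.
#' @export
archetype <- function(name, dominant, concentration, taxa = default_taxa(),
                      decay = 0.9) {
  stopifnot(is.numeric(dominant), !is.null(names(dominant)))
  if (!is.numeric(concentration) || length(concentration) != 1 || concentration <= 0)
    stop2("concentration must be a positive scalar")
  missing <- setdiff(names(dominant), taxa)
  if (length(missing)) stop2("dominant families not in taxa: ", paste(missing, collapse = ", "))
  if (any(dominant < 0) || sum(dominant) >= 1)
    stop2("dominant proportions must be nonnegative and sum to < 1")
  p <- stats::setNames(numeric(length(taxa)), taxa)
  p[names(dominant)] <- dominant
  rest <- setdiff(taxa, names(dominant))
  w <- decay^seq_along(rest)
  p[rest] <- (1 - sum(dominant)) * w / sum(w)
  stopifnot(abs(sum(p) - 1) < 1e-9)
  structure(list(name = name, mean_composition = p, concentration = concentration),
            class = "enterotype_archetype")
}

#' @export
print.enterotype_archetype <- function(x, ...) {
  top <- sort(x$mean_composition, decreasing = TRUE)[1:3]
  cat(sprintf("archetype '%s' (concentration %.6g): %s\n", x$name, x$concentration,
              paste(sprintf("%s %.2f", names(top), top), collapse = ", ")))
  invisible(x)
}

#' Default 66-family taxon panel
#'
#' The first ten names are gut bacterial families that recur throughout
#' enterotype and lifestyle-association analyses; the remainder are
#' synthetic placeholder families bringing the panel to the 66 families
#' typically resolved at this rank in 16S surveys of the adult gut.
#'
#' @param n total number of taxa (default 66).
#' @return character vector of taxon ids.
#' @export
default_taxa <- function(n = 66) {
  named <- c("Bacteroidaceae", "Lachnospiraceae", "Ruminococcaceae",
             "Prevotellaceae", "Bifidobacteriaceae", "Christensenellaceae",
             "Mogibacteriaceae", "Rikenellaceae", "Lactobacillaceae",
             "Bacillaceae")
  if (n <= length(named)) return(named[seq_len(n)])
  c(named, sprintf("Family%02d", seq_len(n - length(named)) + length(named)))
}

#' @rdname archetype
#' @param taxa character vector of taxon ids.
#' @param concentration Dirichlet precision shared by both defaults.
#' @export
default_archetypes <- function(taxa = default_taxa(), concentration = 200) {
  list(
    archetype("Prevotella-driven",
              c(Prevotellaceae = 0.45, Bacteroidaceae = 0.10, Lachnospiraceae = 0.10),
              concentration, taxa = taxa),
    archetype("Bacteroides-driven",
              c(Bacteroidaceae = 0.30, Lachnospiraceae = 0.20, Ruminococcaceae = 0.15),
              concentration, taxa = taxa)
  )
}

#' Region and gender strata of the reference cohort
#'
#' Per-stratum sample counts of a 516-subject nationwide Japanese cohort:
#' seven regions of residence and the overall female:male split. Used as the
#' default metadata strata of the simulator.
#'
#' @return a list with `region` (named integer vector, sums to 516) and
#'   `gender` (named integer vector, sums to 516).
#' @export
study_strata <- function() {
  list(
    region = c(Hokkaido = 38L, Tohoku = 40L, Kanto = 193L, Chubu = 49L,
               Kansai = 49L, ChugokuShikoku = 48L, Kyushu = 99L),
    gender = c(Female = 325L, Male = 191L)
  )
}

#' Default questionnaire couplings
#'
#' Three lifestyle items coupled to family abundances at the tau-b strengths
#' reported for gut cohorts: bowel movement frequency (Q7) negatively
#' coupled to Christensenellaceae, Mogibacteriaceae and Rikenellaceae;
#' dairy intake (Q13) positively to Lactobacillaceae; natto intake (Q21)
#' positively to Bacillaceae.
#'
#' @return list of couplings, each a list with `item`, `taxa`, `tau`,
#'   `levels`.
#' @export
default_couplings <- function() {
  list(
    list(item = "Q7", taxa = c("Christensenellaceae", "Mogibacteriaceae", "Rikenellaceae"),
         tau = -0.26, levels = 5L),
    list(item = "Q13", taxa = "Lactobacillaceae", tau = 0.25, levels = 5L),
    list(item = "Q21", taxa = "Bacillaceae", tau = 0.34, levels = 5L)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the Dirichlet-multinomial simulator. Defaults
#' reproduce the reference study's conditions: 516 subjects across seven
#' regions (325 female, 191 male), 66 bacterial families, sequencing depth
#' 10252 +/- 2406 reads per sample, two enterotype-like archetypes, and
#' three questionnaire couplings.
#'
#' @param n_samples number of samples.
#' @param archetypes list of [archetype()] objects over a common taxon set.
#' @param mixing_proportions archetype mixture weights (sum to 1).
#' @param depth_mean,depth_sd mean and SD of the per-sample read depth
#'   (depths are drawn Normal, rounded, and clamped at 100 reads).
#' @param metadata_strata list with named integer vectors `region` and
#'   `gender`; counts are rescaled to `n_samples` by largest remainder.
#' @param questionnaire_couplings list of couplings as in
#'   [default_couplings()]; each needs `item`, `taxa`, `tau`
#'   (`abs(tau) < 1`) and `levels >= 2`.
#' @param seed integer seed making the cohort reproducible.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 516L,
                          archetypes = default_archetypes(),
                          mixing_proportions = c(0.3, 0.7),
                          depth_mean = 10252, depth_sd = 2406,
                          metadata_strata = study_strata(),
                          questionnaire_couplings = default_couplings(),
                          seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 1)
    stop2("n_samples must be a positive integer")
  if (length(archetypes) == 0) stop2("at least one archetype is required")
  if (!all(vapply(archetypes, inherits, logical(1), "enterotype_archetype")))
    stop2("archetypes must be enterotype_archetype objects")
  if (length(mixing_proportions) != length(archetypes))
    stop2("mixing_proportions must match the number of archetypes")
  if (any(mixing_proportions < 0) || abs(sum(mixing_proportions) - 1) > 1e-9)
    stop2("mixing_proportions must be nonnegative and sum to 1")
  taxa <- names(archetypes[[1]]$mean_composition)
  for (a in archetypes)
    if (!identical(names(a$mean_composition), taxa))
      stop2("all archetypes must share the same taxon set")
  if (depth_mean <= 0 || depth_sd < 0) stop2("invalid depth parameters")
  for (cp in questionnaire_couplings) {
    if (abs(cp$tau) >= 1) stop2("coupling |tau| must be < 1 (item ", cp$item, ")")
    if (cp$levels < 2) stop2("ordinal items need >= 2 levels (item ", cp$item, ")")
  }
  structure(list(n_samples = as.integer(n_samples), archetypes = archetypes,
                 mixing_proportions = mixing_proportions, depth_mean = depth_mean,
                 depth_sd = depth_sd, taxa = taxa,
                 metadata_strata = metadata_strata,
                 questionnaire_couplings = questionnaire_couplings,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Allocate n samples to strata proportionally to reference counts, by
# largest remainder, so exact reference counts are reproduced when n matches
# their total.
allocate_strata <- function(counts, n) {
  quota <- counts / sum(counts) * n
  base <- floor(quota)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(counts))
}

#' Generate a synthetic fecal-microbiota cohort
#'
#' Draws, for each sample, an archetype from the mixture, a composition from
#' `Dirichlet(concentration * mean_composition)`, a library depth from a
#' rounded Normal clamped at 100 reads, and counts from a multinomial at
#' that depth. Region and gender labels are assigned without replacement to
#' hit the configured per-stratum counts exactly; age and BMI are drawn to
#' match the reference cohort's summary statistics. Questionnaire items are
#' added by [generate_questionnaire()].
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: list with `counts`
#'   (an [abundance_table] of counts), `metadata` (data frame with region,
#'   gender, age, bmi and ordinal item scores), `true_labels` (archetype
#'   index per sample), `true_tau` (targeted tau per item/taxon) and
#'   `config`.
#' @examples
#' cfg <- cohort_config(n_samples = 40, seed = 42)
#' coh <- generate_cohort(cfg)
#' table(coh$true_labels)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    k <- length(config$archetypes)
    taxa <- config$taxa
    ids <- sprintf("S%04d", seq_len(n))

    labels <- sample.int(k, n, replace = TRUE, prob = config$mixing_proportions)
    depths <- pmax(100, round(stats::rnorm(n, config$depth_mean, config$depth_sd)))

    counts <- matrix(0, n, length(taxa), dimnames = list(ids, taxa))
    for (i in seq_len(n)) {
      a <- config$archetypes[[labels[i]]]
      alpha <- a$concentration * a$mean_composition
      g <- stats::rgamma(length(alpha), shape = alpha)
      if (sum(g) == 0) g[which.max(alpha)] <- 1  # guard against underflow
      counts[i, ] <- stats::rmultinom(1, depths[i], g / sum(g))
    }

    strata <- config$metadata_strata
    region <- rep(names(strata$region), allocate_strata(strata$region, n))
    gender <- rep(names(strata$gender), allocate_strata(strata$gender, n))
    metadata <- data.frame(
      sample_id = ids,
      region = sample(region),
      gender = sample(gender),
      age = pmin(88, pmax(21, round(stats::rnorm(n, 52.4, 13.4)))),
      bmi = round(pmin(45, pmax(15, stats::rnorm(n, 22.3, 3.2))), 1),
      stringsAsFactors = FALSE
    )
    rownames(metadata) <- ids

    cohort <- structure(
      list(counts = abundance_table(counts, kind = "counts", level = "family"),
           metadata = metadata, true_labels = labels, true_tau = list(),
           config = config),
      class = "synthetic_cohort")
    if (length(config$questionnaire_couplings))
      cohort <- generate_questionnaire(cohort, config$questionnaire_couplings,
                                       seed = config$seed + 1L)
    cohort
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d taxa, %d archetype(s)\n",
              nrow(x$counts), ncol(x$counts), length(x$config$archetypes)))
  cat("archetype sizes:", paste(tabulate(x$true_labels, length(x$config$archetypes)),
                                collapse = ", "), "\n")
  cat(sprintf("mean depth: %.0f reads\n", mean(rowSums(x$counts))))
  invisible(x)
}

#' Attach copula-coupled ordinal questionnaire scores
#'
#' For each coupling, the mean rank of the coupled taxa's relative
#' abundances is mapped to normal scores; a latent Gaussian is drawn with
#' correlation `rho = sin(pi * tau / 2)` to those scores (Greiner's
#' relation, so the *latent* Kendall tau equals the target) and discretized
#' into the requested number of ordinal levels at equal-probability normal
#' thresholds. Discretization attenuates the observable tau-b slightly;
#' with 5 or more levels the attenuation is small.
#'
#' @param cohort a `synthetic_cohort`.
#' @param couplings list of couplings (see [default_couplings()]).
#' @param seed integer seed.
#' @return the cohort with item-score columns added to `$metadata` and the
#'   targets recorded in `$true_tau`.
#' @export
generate_questionnaire <- function(cohort, couplings, seed) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rel <- relative_abundance(cohort$counts)
  n <- nrow(rel)
  with_seed(seed, {
    for (cp in couplings) {
      missing <- setdiff(cp$taxa, colnames(rel))
      if (length(missing))
        stop2("coupling '", cp$item, "' references unknown taxa: ",
              paste(missing, collapse = ", "))
      taxon_rank <- rowMeans(apply(rel[, cp$taxa, drop = FALSE], 2, rank))
      z <- stats::qnorm((rank(taxon_rank, ties.method = "average") - 0.5) / n)
      rho <- sin(pi * cp$tau / 2)
      latent <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
      cuts <- stats::qnorm(seq_len(cp$levels - 1) / cp$levels)
      score <- findInterval(latent, cuts) + 1L
      cohort$metadata[[cp$item]] <- score
      cohort$true_tau[[cp$item]] <- stats::setNames(rep(cp$tau, length(cp$taxa)), cp$taxa)
    }
    cohort
  })
}
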