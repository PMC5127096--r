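# Independent brute-force oracles used to validate the package's own
# implementations on small instances, plus small fixture builders.

# Exhaustive k-medoids optimum: best objective over all C(n, k) medoid sets.
brute_pam_objective <- function(m, k) {
  n <- nrow(m)
  best <- Inf
  sets <- utils::combn(n, k)
  for (i in seq_len(ncol(sets))) {
    obj <- sum(apply(m[, sets[, i], drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

# Silhouette from the bare definition, one sample at a time.
brute_silhouette <- function(m, labels) {
  n <- nrow(m)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(m[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(m[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Classic CH index from raw coordinates.
brute_ch <- function(coords, labels) {
  n <- nrow(coords)
  k <- length(unique(labels))
  total <- sum(sweep(coords, 2, colMeans(coords))^2)
  w <- 0
  for (g in unique(labels)) {
    cg <- coords[labels == g, , drop = FALSE]
    w <- w + sum(sweep(cg, 2, colMeans(cg))^2)
  }
  ((total - w) / (k - 1)) / (w / (n - k))
}

# Two-sided Fisher p by full hypergeometric enumeration (probability-mass
# rule) for a 2x2 table.
brute_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, N - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Does a letter display satisfy its defining invariant against a
# significance matrix? (share a letter <=> not significant)
letters_valid <- function(disp, sig) {
  g <- length(disp)
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    share <- length(intersect(strsplit(disp[i], "")[[1]],
                              strsplit(disp[j], "")[[1]])) > 0
    if (share == sig[i, j]) return(FALSE)
  }
  TRUE
}

# Random relative abundance table, samples x taxa.
random_relative <- function(n, p, seed = 1) {
  set.seed(seed)
  m <- matrix(rgamma(n * p, shape = 1), n, p,
              dimnames = list(paste0("s", seq_len(n)), paste0("t", seq_len(p))))
  abundance_table(m / rowSums(m), kind = "relative")
}

# Small two-archetype count cohort for reuse across files.
two_archetype_cohort <- function(n = 120, concentration = 200, depth = 10000,
                                 seed = 101, prevotella = 0.6, bacteroides = 0.6) {
  cfg <- cohort_config(
    n_samples = n,
    archetypes = list(
      archetype("Prevotella", c(Prevotellaceae = prevotella), concentration),
      archetype("Bacteroides", c(Bacteroidaceae = bacteroides), concentration)),
    mixing_proportions = c(0.5, 0.5),
    depth_mean = depth, depth_sd = 0,
    questionnaire_couplings = list(), seed = seed)
  generate_cohort(cfg)
}

single_archetype_cohort <- function(n = 120, concentration = 200, depth = 10000,
                                    seed = 202) {
  cfg <- cohort_config(
    n_samples = n,
    archetypes = list(archetype("one", c(Bacteroidaceae = 0.3,
                                         Lachnospiraceae = 0.2,
                                         Ruminococcaceae = 0.15), concentration)),
    mixing_proportions = 1,
    depth_mean = depth, depth_sd = 0,
    questionnaire_couplings = list(), seed = seed)
  generate_cohort(cfg)
}
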