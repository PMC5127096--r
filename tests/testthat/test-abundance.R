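test_that("abundance tables round-trip through TSV and BIOM-style JSON", {
  set.seed(1)
  m <- matrix(rpois(12, 20), 3, 4,
              dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
  tab <- abundance_table(m)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(tab, tsv)
  expect_equal(unclass(read_abundance(tsv)), unclass(tab))

  biom <- withr::local_tempfile(fileext = ".json")
  write_abundance(tab, biom, format = "biom-json")
  expect_equal(unclass(read_abundance(biom, format = "biom-json")), unclass(tab))
})

test_that("a generated cohort survives a write/read cycle unchanged", {
  coh <- two_archetype_cohort(n = 15, seed = 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(coh$counts, tsv)
  back <- read_abundance(tsv)
  expect_equal(unclass(back), unclass(coh$counts))
  expect_identical(attr(back, "kind"), "counts")
})

test_that("malformed input files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "tA\t3\t-1", "tB\t1\t2"), f)
  expect_error(read_abundance(f), "negative")

  writeLines(c("taxon_id\ts1\ts2", "tA\t3\tx", "tB\t1\t2"), f)
  expect_error(read_abundance(f), "non-numeric.*tA")

  writeLines(c("taxon_id\ts1\ts2", "tA\t3", "tB\t1\t2"), f)
  expect_error(read_abundance(f))

  m <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(abundance_table(m), "duplicate sample")
})

test_that("collapse to family sums member taxa and preserves sample totals", {
  m <- matrix(c(5, 1, 3, 2, 7, 4), nrow = 2,
              dimnames = list(c("s1", "s2"), c("otu1", "otu2", "otu3")))
  tab <- abundance_table(m, level = "otu")
  tx <- taxonomy_map(c("otu1", "otu2", "otu3"),
                     family = c("F1", "F1", "F2"))
  out <- collapse_taxa(tab, tx, "family")
  expect_identical(colnames(out), c("F1", "F2"))
  expect_equal(unname(rowSums(out)), unname(rowSums(tab)))
  expect_equal(unname(unclass(out)[, "F1"]), c(5 + 3, 1 + 2))

  # all in one family -> single column equal to totals
  tx1 <- taxonomy_map(c("otu1", "otu2", "otu3"), family = rep("F", 3))
  one <- collapse_taxa(tab, tx1, "family")
  expect_equal(ncol(one), 1L)
  expect_equal(unname(unclass(one)[, 1]), unname(rowSums(tab)))

  # unclassified pooled; missing taxonomy entry errors
  txu <- taxonomy_map(c("otu1", "otu2", "otu3"), family = c("F1", NA, NA))
  expect_true("unclassified_family" %in% colnames(collapse_taxa(tab, txu, "family")))
  expect_error(collapse_taxa(tab, taxonomy_map("otu1", family = "F1")), "missing")
})

test_that("OTU-scale fixture collapses to the family-level cardinality", {
  set.seed(8)
  n_otu <- 3119
  fams <- default_taxa(66)
  m <- matrix(rpois(4 * n_otu, 2), nrow = 4,
              dimnames = list(paste0("s", 1:4), paste0("otu", seq_len(n_otu))))
  tab <- abundance_table(m, level = "otu")
  tx <- taxonomy_map(colnames(m), family = rep(fams, length.out = n_otu))
  out <- collapse_taxa(tab, tx, "family")
  expect_equal(ncol(out), 66L)
  expect_equal(unname(rowSums(out)), unname(rowSums(tab)))
})

test_that("relative abundance normalizes rows and flags zero-total samples", {
  m <- matrix(c(2, 0, 2, 5), 2, 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  rel <- relative_abundance(abundance_table(m))
  expect_equal(unname(unclass(rel)["s1", ]), c(0.5, 0.5))
  expect_equal(unname(rowSums(rel)), c(1, 1))

  m0 <- matrix(c(1, 0, 2, 0), 2, 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(relative_abundance(abundance_table(m0)), "s2")
})

test_that("Dirichlet-multinomial mean recovers the archetype mean", {
  coh <- single_archetype_cohort(n = 200, seed = 31)
  rel <- relative_abundance(coh$counts)
  target <- coh$config$archetypes[[1]]$mean_composition["Bacteroidaceae"]
  est <- mean(unclass(rel)[, "Bacteroidaceae"])
  # Dirichlet variance p(1-p)/(c+1) dominates; 3 standard errors at n=200
  se <- sqrt(target * (1 - target) / 201) / sqrt(200)
  expect_lt(abs(est - target), 3 * se + 1e-3)
})

test_that("prevalence counts strictly positive cells and respects subsets", {
  m <- matrix(c(rep(1, 15), rep(0, 0),            # always present
                rep(0, 15),                       # absent
                c(rep(2, 11), rep(0, 4))), 15, 3,
              dimnames = list(paste0("s", 1:15), c("always", "never", "some")))
  tab <- abundance_table(m)
  pv <- prevalence(tab)
  expect_equal(unname(pv), c(1, 0, 11 / 15))
  expect_equal(unname(prevalence(tab, paste0("s", 1:11))["some"]), 1)
  expect_error(prevalence(tab, character(0)), "empty")

  # prevalence invariant under conversion to relative abundances
  m2 <- m; m2[, "never"] <- 0.5  # avoid zero-sum rows staying informative
  tab2 <- abundance_table(m2)
  expect_equal(prevalence(tab2), prevalence(relative_abundance(tab2)))
})

test_that("collapse and normalization commute on random tables", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rpois(60, 5) + 1, 5, 12,
                dimnames = list(paste0("s", 1:5), paste0("otu", 1:12)))
    tab <- abundance_table(m, level = "otu")
    tx <- taxonomy_map(colnames(m), family = sample(c("A", "B", "C"), 12, TRUE))
    a <- relative_abundance(collapse_taxa(tab, tx, "family"))
    b <- collapse_taxa(relative_abundance(tab), tx, "family")
    expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
  }
})
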