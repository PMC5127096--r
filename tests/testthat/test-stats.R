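test_that("Welch's t matches the hand formula with Satterthwaite df", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  res <- welch_t(x, y)
  # hand computation: t = -1 / sqrt(1/3 + 1/3), df = 4
  t_hand <- (mean(x) - mean(y)) / sqrt(var(x) / 3 + var(y) / 3)
  df_hand <- (var(x) / 3 + var(y) / 3)^2 /
    ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(res$statistic, t_hand, tolerance = 1e-6)
  expect_equal(t_hand, -1.2247, tolerance = 1e-4)
  expect_equal(df_hand, 4)
  expect_equal(res$p_value, 2 * pt(t_hand, df_hand), tolerance = 1e-6)
  expect_equal(res$p_value, 0.2878, tolerance = 1e-3)
  expect_equal(res$effect_direction, -1)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("Welch's t detects a shift with the right sign at large n", {
  set.seed(91)
  x <- rnorm(200, 0.5); y <- rnorm(200, 0)
  res <- welch_t(x, y)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$effect_direction, 1)
})

test_that("Mann-Whitney U uses exact enumeration for small untied samples", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)            # all y exceed all x
  expect_equal(res$p_value, 2 / choose(4, 2), tolerance = 1e-12)

  tied <- mann_whitney_u(c(2, 2, 2), c(2, 2))
  expect_equal(tied$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("Fisher's exact equals hypergeometric enumeration on random tables", {
  tab <- rbind(c(1, 9), c(11, 3))
  expect_equal(fisher_exact(tab)$p_value, brute_fisher_p(tab), tolerance = 1e-9)
  expect_equal(fisher_exact(tab)$p_value, 0.002759, tolerance = 1e-3)
  expect_equal(fisher_exact(rbind(c(5, 5), c(5, 5)))$p_value, 1)

  set.seed(37)
  for (i in 1:50) {
    t2 <- matrix(rpois(4, 6), 2, 2)
    p <- fisher_exact(t2)$p_value
    expect_equal(p, brute_fisher_p(t2), tolerance = 1e-9)
    # invariance under simultaneous row and column swap
    expect_equal(fisher_exact(t2[2:1, 2:1])$p_value, p, tolerance = 1e-12)
  }
  expect_error(fisher_exact(rbind(c(-1, 2), c(3, 4))), "nonnegative")
})

test_that("Holm adjustment reproduces the step-down walk", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  set.seed(44)
  p <- runif(12)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj <= 1))
  expect_error(holm_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("Kendall tau-b matches pair enumeration and Greiner's relation", {
  expect_equal(kendall_tau_b(1:10, 1:10)$tau, 1)
  expect_equal(kendall_tau_b(c(1, 2, 3, 4), c(2, 1, 4, 3))$tau, 1 / 3,
               tolerance = 1e-12)  # C = 4, D = 2

  set.seed(53)
  n <- 2000
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  est <- kendall_tau_b(z1, z2)$tau
  se <- sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  expect_lt(abs(est - (2 / pi) * asin(0.5)), 3 * se)

  # antisymmetry under reversing one variable
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(kendall_tau_b(x, y)$tau, -kendall_tau_b(x, -y)$tau,
               tolerance = 1e-12)

  expect_error(kendall_tau_b(rep(1, 10), rnorm(10)), "constant")
  miss <- kendall_tau_b(rep(1, 10), rnorm(10), on_constant = "missing")
  expect_true(is.na(miss$tau))
})

test_that("type-I error of the two-group tests is calibrated at alpha = 0.05", {
  set.seed(71)
  reps <- 2000
  welch_rej <- mean(replicate(reps, welch_t(rnorm(15), rnorm(15))$p_value < 0.05))
  expect_lt(abs(welch_rej - 0.05), 0.02)
  mw_rej <- mean(replicate(reps, {
    mann_whitney_u(sample(1:5, 25, TRUE), sample(1:5, 25, TRUE))$p_value < 0.05
  }))
  expect_lte(mw_rej, 0.07)  # tie-corrected approximation is near-nominal
})

test_that("compact letters reproduce the canonical patterns", {
  g3 <- c("A", "B", "C")
  none <- matrix(1, 3, 3, dimnames = list(g3, g3))
  expect_true(all(compact_letters(none) == "a"))

  all_sig <- matrix(0.001, 3, 3, dimnames = list(g3, g3)); diag(all_sig) <- 1
  expect_setequal(unname(compact_letters(all_sig)), c("a", "b", "c"))

  # only Hokkaido vs Kyushu significant among 7 regions
  regions <- c("Hokkaido", "Tohoku", "Kanto", "Chubu", "Kansai",
               "ChugokuShikoku", "Kyushu")
  pm <- matrix(1, 7, 7, dimnames = list(regions, regions))
  pm["Hokkaido", "Kyushu"] <- pm["Kyushu", "Hokkaido"] <- 0.01
  disp <- compact_letters(pm)
  shared <- function(a, b) length(intersect(strsplit(disp[a], "")[[1]],
                                            strsplit(disp[b], "")[[1]])) > 0
  expect_false(shared("Hokkaido", "Kyushu"))
  for (r in setdiff(regions, c("Hokkaido", "Kyushu"))) {
    expect_true(shared("Hokkaido", r))
    expect_true(shared("Kyushu", r))
  }
})

test_that("compact letters satisfy their defining invariant on random instances", {
  set.seed(77)
  for (rep in 1:30) {
    g <- sample(3:8, 1)
    pm <- matrix(1, g, g, dimnames = list(letters[1:g], letters[1:g]))
    for (i in seq_len(g - 1)) for (j in (i + 1):g)
      pm[i, j] <- pm[j, i] <- sample(c(0.001, 0.5), 1)
    disp <- compact_letters(pm)
    expect_true(letters_valid(disp, pm < 0.05))
  }
})
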