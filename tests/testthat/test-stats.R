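# Assumption checks, one-way ANOVA, step-down Holm-Sidak adjustment,
# letter codes and Welch t-tests.

test_that("step-down Sidak adjustment matches the hand computation", {
  # hand oracle, m = 3: sorted (0.01, 0.03, 0.04)
  # 1-(1-0.01)^3 = 0.029701; 1-(1-0.03)^2 = 0.0591; 1-(1-0.04)^1 = 0.04
  # monotonicity lifts the last to 0.0591; restore input order
  expect_equal(holm_sidak_adjust(c(0.01, 0.04, 0.03)),
               c(0.029701, 0.0591, 0.0591), tolerance = 1e-6)
  expect_equal(holm_sidak_adjust(0.2), 0.2)
  expect_identical(holm_sidak_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.5, 0.02, 0.9, 0.04)
  adj <- holm_sidak_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(holm_sidak_adjust(c(0.5, 1.2)), "invalid p")
})

test_that("one-way ANOVA recovers the classical F in known cases", {
  ident <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  an <- oneway_anova(ident)
  expect_equal(an$f, 0)
  expect_equal(an$p, 1)
  # two groups: F equals the squared pooled-variance t
  set.seed(11)
  g <- list(a = rnorm(6), b = rnorm(6, 1))
  an2 <- oneway_anova(g)
  tt <- welch_t_test(g$a, g$b, pooled = TRUE)
  expect_equal(an2$f, tt$t^2, tolerance = 1e-10)
  expect_equal(an2$p, tt$p, tolerance = 1e-10)
  # well-separated means reject decisively
  set.seed(12)
  sep <- list(a = rnorm(4, 0, 1), b = rnorm(4, 10, 1))
  expect_lt(oneway_anova(sep)$p, 1e-3)
  expect_error(oneway_anova(list(a = c(1, 1), b = c(1, 1))), "degenerate")
})

test_that("Welch t-test is antisymmetric and degenerate-safe", {
  set.seed(3)
  a <- rnorm(5); b <- rnorm(5, 0.5)
  ab <- welch_t_test(a, b); ba <- welch_t_test(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t_test(c(1, 1), c(1, 1)), "degenerate")
})

test_that("assumption checks flag heteroscedasticity and skip degenerate groups", {
  set.seed(21)
  ok <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  chk <- assumption_checks(ok)
  expect_true(all(!chk$shapiro$skipped))
  # constant group: normality undefined, skipped not failed
  dg <- assumption_checks(list(a = c(2, 2, 2, 2), b = rnorm(4)))
  expect_true(dg$shapiro$skipped[dg$shapiro$group == "a"])
  # variance ratio 100:1 at n = 20 is detected almost surely
  set.seed(22)
  rejections <- sum(replicate(40, {
    g <- list(a = rnorm(20, sd = 1), b = rnorm(20, sd = 10))
    assumption_checks(g)$brown_forsythe_p < 0.05
  }))
  expect_gt(rejections / 40, 0.95)
})

test_that("type-I error of the Welch test is calibrated near 5%", {
  set.seed(31)
  n_sim <- 800
  hits <- sum(replicate(n_sim, welch_t_test(rnorm(4), rnorm(4))$p <= 0.05))
  rate <- hits / n_sim
  mc3 <- 3 * sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rate - 0.05), mc3 + 0.01)
})

test_that("letter codes are a deterministic function of the adjusted-p matrix", {
  cmp <- data.frame(group_a = c("A", "A", "B"),
                    group_b = c("B", "C", "C"),
                    adj_p = c(0.20, 0.01, 0.30))
  lt <- letter_codes(cmp, c("A", "B", "C"))
  # A differs from C only: A and B share a letter, B and C share a letter,
  # A and C never share one
  shares <- function(x, y) any(strsplit(lt[[x]], "")[[1]] %in%
                                 strsplit(lt[[y]], "")[[1]])
  expect_true(shares("A", "B"))
  expect_true(shares("B", "C"))
  expect_false(shares("A", "C"))
  expect_identical(lt, letter_codes(cmp, c("A", "B", "C")))
  # all-different matrix gives distinct single letters
  alldiff <- data.frame(group_a = c("A", "A", "B"), group_b = c("B", "C", "C"),
                        adj_p = c(0.001, 0.001, 0.001))
  lt2 <- letter_codes(alldiff, c("A", "B", "C"))
  expect_identical(sort(unname(lt2)), c("a", "b", "c"))
})

test_that("pairwise Holm-Sidak separates a clearly different group", {
  set.seed(41)
  g <- list(ctrl = rnorm(4, 0, 0.5), mid = rnorm(4, 0.3, 0.5),
            high = rnorm(4, 8, 0.5))
  pw <- pairwise_holm_sidak(g)
  cmp <- pw$comparisons
  hi <- cmp[cmp$group_a == "high" | cmp$group_b == "high", ]
  expect_true(all(hi$significant))
  expect_true(all(cmp$adj_p >= cmp$raw_p))
  # ctrl and mid share a letter, high stands alone
  expect_false(grepl(pw$letters[["high"]], pw$letters[["ctrl"]], fixed = TRUE))
})
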