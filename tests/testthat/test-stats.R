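# Normality gate, Dunn's test and the branch-selection ladder.

test_that("K2 omnibus statistic matches an independent reference", {
  # expected values computed once with an independent implementation of the
  # same published test (SciPy's normaltest) and frozen here
  x1 <- c(7.15235, 12.527457, 8.258677, 9.481654, 9.849313, 8.518231,
          7.264415, 11.297786, 10.722116, 6.094274, 14.694819, 11.936994,
          8.481226, 11.804397, 9.066094, 9.878621, 11.577689, 7.486664,
          11.151715, 12.797958, 12.644596, 9.400603, 11.805839, 6.756835,
          9.683621)
  d1 <- dagostino_pearson(x1)
  expect_equal(d1$statistic, 0.6059013344, tolerance = 1e-9)
  expect_equal(d1$p.value, 0.7386355344, tolerance = 1e-9)

  x2 <- c(4.073634, 0.8112, 2.525606, 12.836157, 28.684115, 5.471896,
          5.730311, 1.146726, 0.915349, 0.762569, 4.425539, 5.348122,
          1.502478, 0.899598, 3.4274, 3.602444, 2.416377, 8.524845,
          2.500108, 2.56117, 1.00261, 3.072099, 9.137346, 2.87206,
          2.897427, 4.016011, 3.489419, 4.380782, 4.40636, 4.742266,
          1.329076, 3.560952, 0.642472, 3.456025, 0.873313, 2.549396,
          4.164702, 1.871297, 2.968168, 0.62103)
  d2 <- dagostino_pearson(x2)
  expect_equal(d2$statistic, 64.7651606307, tolerance = 1e-8)
  expect_lt(d2$p.value, 1e-10)

  expect_error(dagostino_pearson(1:7), "n >= 8")
  expect_error(dagostino_pearson(rep(2, 20)), "constant")
})

test_that("Dunn z for two groups matches the Mann-Whitney normal approx", {
  set.seed(5)
  a <- rexp(25); b <- rexp(30, rate = 0.5)
  dn <- dunn_test(list(a = a, b = b))
  w <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(dn$p_raw, w$p.value, tolerance = 1e-10)
  # with one pair there is nothing to adjust
  expect_equal(dn$p_adj, dn$p_raw)
  # Bonferroni over all pairs for three groups
  dn3 <- dunn_test(list(a = a, b = b, c = rexp(20)))
  expect_equal(dn3$p_adj, pmin(1, dn3$p_raw * 3))
})

test_that("branch selection follows the design x normality decision table", {
  set.seed(10)
  norm1 <- rnorm(30); norm2 <- rnorm(30, 0.2); norm3 <- rnorm(30, 1)
  skew1 <- rexp(30); skew2 <- rexp(30, 0.5)

  expect_identical(test_group_difference(list(a = norm1, b = norm2))$test,
                   "Welch t-test")
  expect_identical(test_group_difference(list(a = skew1, b = skew2))$test,
                   "Mann-Whitney")
  expect_identical(
    test_group_difference(list(a = norm1, b = norm2, c = norm3))$test,
    "one-way ANOVA + Sidak")
  expect_identical(
    test_group_difference(list(a = skew1, b = skew2, c = rexp(30)))$test,
    "Kruskal-Wallis + Dunn")
  # small groups force the nonparametric branch and say so in the audit
  small <- test_group_difference(list(a = rnorm(5), b = rnorm(5)))
  expect_identical(small$test, "Mann-Whitney")
  expect_true(any(grepl("forced", small$audit)))

  expect_error(test_group_difference(list(a = 1:2, b = 1:10)), "n >= 3")
  expect_error(test_group_difference(list(a = 1:10)), "2 groups")
})

test_that("identical groups are not significant; large shifts are", {
  g <- c(1.2, 3.4, 2.2, 5.1, 4.4, 3.3, 2.8, 3.9, 4.6, 2.5)
  same <- test_group_difference(list(a = g, b = g))
  expect_gt(same$p_value, 0.9)
  expect_false(same$significant)

  set.seed(6)
  a <- rnorm(50); b <- rnorm(50, mean = 5)  # 5 sd shift
  shift <- test_group_difference(list(a = a, b = b))
  expect_true(shift$significant)
  expect_lt(shift$p_value, 1e-10)
})

test_that("repeated-measures branch runs RM ANOVA with Dunnett contrasts", {
  set.seed(12)
  d <- expand.grid(subject = paste0("s", 1:18), time = paste0("t", 1:4))
  d$group <- rep(rep(c("control", "lps", "glu"), each = 6), 4)
  d$value <- rnorm(nrow(d)) + ifelse(d$group == "glu", 2, 0)
  cmp <- test_group_difference(d, design = "repeated_time_by_group",
                               control = "control")
  expect_identical(cmp$test, "two-way RM ANOVA + Dunnett")
  expect_equal(nrow(cmp$pairwise), 2)           # each group vs control
  expect_true(all(grepl("control", cmp$pairwise$contrast)))
  glu_p <- cmp$pairwise$p_adj[grepl("glu", cmp$pairwise$contrast)]
  lps_p <- cmp$pairwise$p_adj[grepl("lps", cmp$pairwise$contrast)]
  expect_lt(glu_p, 0.01)
  expect_gt(lps_p, 0.05)
  expect_true(any(grepl("Dunnett", cmp$audit)))

  # subjects appearing in two groups are a mixed design
  d_bad <- d; d_bad$group[d_bad$subject == "s1"][1] <- "glu"
  expect_error(test_group_difference(d_bad, "repeated_time_by_group"),
               "mixed")
})

test_that("summaries use the reporting conventions", {
  s_np <- summarize_values(c(1, 2, 3), "nonparametric")
  expect_equal(s_np$median, 2)
  expect_equal(s_np$q1, 1.5)   # linear-interpolation quantiles
  expect_equal(s_np$q3, 2.5)
  s_p <- summarize_values(c(1, 2, 3), "parametric")
  expect_equal(s_p$mean, 2)
  expect_equal(s_p$sd, 1)
  expect_equal(s_p$sem, 1 / sqrt(3))
  expect_equal(summarize_values(7, "nonparametric")$median, 7)
  expect_error(summarize_values(numeric(0)), "empty")
})
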