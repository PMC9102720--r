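fx <- stat_fixtures()

test_that("the omnibus normality test matches the independent reference to 1e-6", {
  dn <- dagostino_pearson(fx$x_norm)
  expect_equal(dn$statistic, stat_oracle$normaltest_norm$k2, tolerance = 1e-6)
  expect_equal(dn$p, stat_oracle$normaltest_norm$p, tolerance = 1e-6)
  expect_true(dn$normal)
  de <- dagostino_pearson(fx$x_exp)
  expect_equal(de$statistic, stat_oracle$normaltest_exp$k2, tolerance = 1e-6)
  expect_equal(de$p, stat_oracle$normaltest_exp$p, tolerance = 1e-6)
  expect_false(de$normal)
  expect_error(dagostino_pearson(rnorm(5)), "insufficient n")
})

test_that("the omnibus normality test separates normal from skewed samples", {
  verdicts_norm <- logical(100)
  verdicts_exp <- logical(100)
  for (s in 1:100) {
    set.seed(s)
    verdicts_norm[s] <- dagostino_pearson(rnorm(500))$p > 0.05
    verdicts_exp[s] <- dagostino_pearson(rexp(500))$p < 0.05
  }
  expect_gte(mean(verdicts_norm), 0.95)
  expect_gte(mean(verdicts_exp), 0.95)
})

test_that("Kruskal-Wallis + Dunn matches the independent reference to 1e-6", {
  kd <- kw_dunn(fx$groups, "WT")
  expect_equal(kd$statistic, stat_oracle$kruskal$H, tolerance = 1e-6)
  expect_equal(kd$p, stat_oracle$kruskal$p, tolerance = 1e-6)
  for (g in c("DAAM", "frl", "form3")) {
    row <- kd$comparisons[kd$comparisons$group == g, ]
    expect_equal(row$z, stat_oracle$dunn[[g]]$z, tolerance = 1e-6)
    expect_equal(row$p_unadj, stat_oracle$dunn[[g]]$p_unadj, tolerance = 1e-6)
    expect_equal(row$p_adj, stat_oracle$dunn[[g]]$p_adj, tolerance = 1e-6)
  }
  # clearly separated groups are detected
  sep <- kw_dunn(list(ref = c(51, 52, 53), lo = c(1, 2, 3),
                      hi = c(101, 102, 103)), "ref")
  expect_lt(sep$p, 0.05)
})

test_that("degenerate rank data is flagged, not an exception", {
  same <- kw_dunn(list(a = rep(4, 5), b = rep(4, 6)), "a")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_equal(same$flag, "degenerate")
  expect_equal(same$comparisons$p_adj, 1)
  # two groups with identical values: Dunn adjusted p = 1
  ident <- kw_dunn(list(a = c(1, 2, 3), b = c(1, 2, 3)), "a")
  expect_equal(ident$comparisons$p_adj, 1)
})

test_that("ANOVA + Dunnett matches the independent reference", {
  ad <- anova_dunnett(fx$groups, "WT")
  expect_equal(ad$statistic, stat_oracle$anova$F, tolerance = 1e-6)
  expect_equal(ad$p, stat_oracle$anova$p, tolerance = 1e-6)
  comp <- ad$comparisons[match(c("DAAM", "frl", "form3"),
                               ad$comparisons$group), ]
  expect_equal(comp$t, stat_oracle$dunnett$stat, tolerance = 1e-6)
  # the multivariate-t adjustment is quadrature-limited, not closed-form
  expect_equal(comp$p_adj, stat_oracle$dunnett$p, tolerance = 5e-4)

  # identical groups: F = 0
  f0 <- anova_dunnett(list(a = c(1, 2, 3), b = c(1, 2, 3)), "a")
  expect_equal(f0$statistic, 0, tolerance = 1e-12)
  expect_error(anova_dunnett(list(a = c(1, 1), b = c(2, 2)), "a"),
               "zero within-group variance")
  expect_error(anova_dunnett(list(a = 1, b = c(1, 2)), "a"), "at least 2")
})

test_that("raising a group's mean never increases its Dunnett-adjusted p", {
  set.seed(21)
  base <- list(WT = rnorm(8), m1 = rnorm(8), m2 = rnorm(8))
  # start from exactly equal means so the shift grid moves strictly away
  base$m1 <- base$m1 - mean(base$m1) + mean(base$WT)
  shifts <- seq(0, 2, by = 0.25)
  ps <- vapply(shifts, function(s) {
    g <- base
    g$m1 <- base$m1 + s
    ad <- anova_dunnett(g, "WT")
    ad$comparisons$p_adj[ad$comparisons$group == "m1"]
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-6))
})

test_that("the phenotype chi-square is Pearson's without continuity correction", {
  pc <- phenotype_chisq(fx$counts)
  # hand computation from the marginal expected counts
  expect_equal(pc$statistic, stat_oracle$chisq$stat, tolerance = 1e-6)
  expect_equal(pc$statistic, 50.0932, tolerance = 0.01)
  expect_equal(pc$p, stat_oracle$chisq$p, tolerance = 1e-6)

  same <- phenotype_chisq(rbind(c(10, 20, 5), c(10, 20, 5)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(phenotype_chisq(rbind(c(-1, 2), c(3, 4))), "non-negative")
  expect_error(phenotype_chisq(rbind(c(0, 2), c(0, 4))), "marginal")
  expect_error(phenotype_chisq(matrix(1:3, 1)), "2 x 2")
})

test_that("significance stars follow the closed-boundary mapping", {
  expect_equal(star_map(0.05), "*")
  expect_equal(star_map(0.051), "ns")
  expect_equal(star_map(0.01), "**")
  expect_equal(star_map(0.001), "***")
  expect_equal(star_map(0.0001), "****")
  expect_equal(star_map(0.00005), "****")
  expect_equal(star_map(c(0.6, 0.02)), c("ns", "*"))
  expect_error(star_map(1.2), "0, 1")
  expect_error(star_map(-0.1), "0, 1")
})

test_that("the summary table propagates sample sizes and adjusted p-values", {
  expect_equal(nrow(summary_table(list())), 0L)
  kd <- kw_dunn(fx$groups, "WT")
  tab <- summary_table(list("DC duration" = kd))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$measurement, "DC duration")
  expect_match(tab$WT, "n = 10")
  expect_match(tab$DAAM, "n = 8")
  expect_match(tab$frl, "^ns")
  f <- withr::local_tempfile(fileext = ".md")
  write_report_md(tab, f)
  expect_match(readLines(f)[1], "measurement")
})
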