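test_that("Welch test from summaries matches t.test on reconstructed data", {
  # samples rescaled to have exactly the stated mean and SD
  exact_sample <- function(m, s, n) {
    z <- seq_len(n)
    m + s * (z - mean(z)) / sd(z)
  }
  cases <- list(c(13.4, 2.8, 7, 44.1, 4.9, 7),
                c(93.3, 2.3, 7, 93.9, 3.0, 7),
                c(50, 5, 5, 40, 10, 12))
  for (cs in cases) {
    x <- exact_sample(cs[1], cs[2], cs[3])
    y <- exact_sample(cs[4], cs[5], cs[6])
    ours <- welch_t_summary(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    ref <- t.test(x, y)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    pooled <- welch_t_summary(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6],
                              pooled = TRUE)
    ref_p <- t.test(x, y, var.equal = TRUE)
    expect_equal(pooled$t, unname(ref_p$statistic), tolerance = 1e-10)
    expect_equal(pooled$p, ref_p$p.value, tolerance = 1e-10)
  }
})

test_that("Welch conventions and errors for degenerate summaries", {
  same <- welch_t_summary(50, 3, 7, 50, 3, 7)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  both0 <- welch_t_summary(50, 0, 7, 50, 0, 7)
  expect_equal(both0$p, 1)
  expect_error(welch_t_summary(50, 0, 7, 60, 0, 7), "unbounded")
  expect_error(welch_t_summary(50, 3, 1, 60, 3, 7), "n >= 2")
})

test_that("published per-day contrasts come out as printed", {
  # NovaMin day 3: clearly different letters
  day3 <- welch_t_summary(13.4, 2.8, 7, 44.1, 4.9, 7)
  expect_lt(day3$p, 0.05)
  # composite paste day 5: same letter, no difference
  day5 <- welch_t_summary(93.3, 2.3, 7, 93.9, 3.0, 7)
  expect_gt(day5$p, 0.05)
})

test_that("summary ANOVA matches aov on moment-matched data", {
  exact_sample <- function(m, s, n) {
    z <- seq_len(n)
    m + s * (z - mean(z)) / sd(z)
  }
  means <- c(19, 32.3, 12.9); sds <- c(2.6, 3.0, 3.6); ns <- c(7, 7, 9)
  dat <- data.frame(
    y = unlist(mapply(exact_sample, means, sds, ns, SIMPLIFY = FALSE)),
    g = factor(rep(seq_along(ns), ns)))
  ref <- summary(aov(y ~ g, data = dat))[[1]]
  ours <- oneway_anova_summary(means, sds, ns)
  expect_equal(ours$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(ours$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(ours$df1, 2)
  expect_equal(ours$df2, sum(ns) - 3)
})

test_that("two-group ANOVA F is the squared pooled t statistic", {
  t_pooled <- welch_t_summary(19, 2.6, 7, 32.3, 3.0, 7, pooled = TRUE)
  a <- oneway_anova_summary(c(19, 32.3), c(2.6, 3.0), c(7, 7))
  expect_equal(a$F, t_pooled$t^2, tolerance = 1e-12)
  expect_equal(a$p, t_pooled$p, tolerance = 1e-12)
  ident <- oneway_anova_summary(c(5, 5), c(1, 1), c(7, 7))
  expect_equal(ident$F, 0)
  expect_equal(ident$p, 1)
  expect_error(oneway_anova_summary(c(5, 6), c(1, 1), c(1, 7)), "n >= 2")
})

test_that("per-day comparison table reproduces the printed letter pattern", {
  cmp <- compare_conditions(occlusion_table1(), alpha = 0.05)
  expect_equal(nrow(cmp), 21)
  # proargin and NovaMin pastes differ on every one of the seven days
  for (p in c("Colgate Pro-relief", "Sensodyne repair")) {
    sub <- cmp[cmp$paste == p, ]
    expect_equal(nrow(sub), 7)
    expect_true(all(sub$significant))
    expect_true(all(sub$letters == "a|b"))
  }
  # composite paste: day 5 is the single non-significant day
  eb <- cmp[cmp$paste == "EB@TiO2", ]
  expect_equal(eb$day[!eb$significant], 5)
})

test_that("Bonferroni adjustment is monotone and never creates significance", {
  cmp <- compare_conditions(occlusion_table1())
  expect_true(all(cmp$p_bonferroni >= cmp$p))
  expect_true(all(cmp$p_bonferroni <= 1))
  expect_true(all(cmp$p_bonferroni == pmin(1, 7 * cmp$p)))
  expect_true(all(!cmp$significant_bonferroni | cmp$significant))
})

test_that("swapping the condition labels flips t but preserves p", {
  tab <- occlusion_table1()
  swapped <- lapply(tab, function(s) {
    occlusion_series(s$paste,
                     if (s$condition == "with_saliva") "WS" else "S",
                     s$days, s$means, s$sds, s$n)
  })
  a <- compare_conditions(tab)
  b <- compare_conditions(swapped)
  key <- function(x) paste(x$paste, x$day)
  b <- b[match(key(a), key(b)), ]
  expect_equal(b$t, -a$t)
  expect_equal(b$p, a$p)
  expect_equal(b$significant, a$significant)
})

test_that("a paste missing one condition is skipped with a warning", {
  tab <- occlusion_table1()
  partial <- tab[names(tab) != "Sensodyne repair / with_saliva"]
  expect_warning(cmp <- compare_conditions(partial), "missing one condition")
  expect_equal(sort(unique(cmp$paste)), c("Colgate Pro-relief", "EB@TiO2"))
  expect_equal(nrow(cmp), 14)
})
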