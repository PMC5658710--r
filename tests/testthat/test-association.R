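test_that("median dichotomization puts ties low and both groups non-empty", {
  p4 <- tibble::tibble(pc_score = c(1, 2, 3, 4))
  g4 <- dichotomize_at_median(p4)$group
  expect_equal(as.character(g4), c("low", "low", "high", "high"))

  p3 <- tibble::tibble(pc_score = c(1, 2, 3))
  g3 <- dichotomize_at_median(p3)$group
  expect_equal(as.character(g3), c("low", "low", "high"))

  expect_error(dichotomize_at_median(tibble::tibble(pc_score = c(5, 5, 5))),
               "constant")

  # distinct values: the low group has ceiling(n/2) members
  for (n in c(5, 8, 11)) {
    g <- dichotomize_at_median(tibble::tibble(pc_score = withr::with_seed(n, rnorm(n))))$group
    expect_equal(sum(g == "low"), ceiling(n / 2))
    expect_true(all(table(g) > 0))
  }
})

test_that("log-rank matches a hand-computed risk-set table and is 0 under exchange", {
  # A: times 1,2,3 all events; B: times 4,5,6 all events.
  # time  n  nA dA  E_A = nA/n        V = nA*nB*d*(n-d) / (n^2 (n-1))
  #   1   6  3  1   0.5               3*3*1*5/(36*5) = 0.2500
  #   2   5  2  1   0.4               2*3*1*4/(25*4) = 0.2400
  #   3   4  1  1   0.25              1*3*1*3/(16*3) = 0.1875
  #   4-6: nA = 0, contributes 0
  # O_A = 3, E_A = 1.15, V = 0.6775 -> chi2 = (3-1.15)^2/0.6775
  o <- surv_outcome(time = c(1, 2, 3, 4, 5, 6), event = rep(1, 6))
  g <- factor(rep(c("low", "high"), each = 3), levels = c("low", "high"))
  s <- km_logrank(o, g)
  expect_equal(s$statistic, (3 - 1.15)^2 / 0.6775, tolerance = 1e-10)
  expect_equal(s$p_value, pchisq((3 - 1.15)^2 / 0.6775, 1, lower.tail = FALSE))

  # identical time/event vectors in both groups: statistic 0, p 1
  o2 <- surv_outcome(time = rep(c(2, 5, 7), 2), event = rep(c(1, 0, 1), 2))
  g2 <- factor(rep(c("low", "high"), 3), levels = c("low", "high"))
  s2 <- km_logrank(o2, g2)
  expect_equal(s2$statistic, 0, tolerance = 1e-12)
  expect_equal(s2$p_value, 1, tolerance = 1e-12)

  # rescaling all times leaves the statistic unchanged
  o3 <- o
  o3$time <- o3$time * 17.3
  expect_equal(km_logrank(o3, g)$statistic, s$statistic, tolerance = 1e-12)

  expect_error(km_logrank(surv_outcome(1:4, rep(0, 4)),
                          factor(c("low", "low", "high", "high"))),
               "no events")
})

test_that("Pearson summary matches the closed-form statistic and p-value", {
  y <- withr::with_seed(12, rnorm(10))
  pc <- withr::with_seed(13, rnorm(10))
  s <- pearson_summary(y, pc)
  r <- sum(scale(pc, scale = FALSE) * scale(y, scale = FALSE)) /
    sqrt(sum(scale(pc, scale = FALSE)^2) * sum(scale(y, scale = FALSE)^2))
  t_stat <- r * sqrt(8) / sqrt(1 - r^2)
  expect_equal(s$effect, r, tolerance = 1e-8)
  expect_equal(s$statistic, t_stat, tolerance = 1e-8)
  expect_equal(s$p_value, 2 * pt(-abs(t_stat), df = 8), tolerance = 1e-8)

  expect_equal(pearson_summary(y, y)$effect, 1)
  expect_error(pearson_summary(rep(1, 5), rnorm(5)), "constant")
})

test_that("t-test summary follows the Welch-Satterthwaite closed form", {
  g <- factor(rep(c("low", "high"), each = 3), levels = c("low", "high"))
  s0 <- ttest_summary(rep(c(1, 2, 3), 2), g)
  expect_equal(s0$statistic, 0)
  expect_equal(s0$p_value, 1)

  v <- c(1, 2, 3, 4, 5, 6)
  s <- ttest_summary(v, g)
  a <- v[4:6]; b <- v[1:3]
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_stat <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(s$statistic, t_stat, tolerance = 1e-8)
  expect_equal(attr(s, "df"), df, tolerance = 1e-8)
  expect_equal(s$p_value, 2 * pt(-abs(t_stat), df), tolerance = 1e-8)
  expect_equal(s$effect, 3)

  expect_error(ttest_summary(1:4, factor(c("low", "low", "low", "high"))),
               "at least 2")
})

test_that("chi-square summary matches expected counts and symmetry invariants", {
  g <- factor(rep(c("low", "high"), each = 20), levels = c("low", "high"))

  # independence: all cells 10
  lab <- rep(c(0, 1, 0, 1), each = 10)
  s0 <- chisq_summary(g, lab)
  expect_equal(s0$statistic, 0)
  expect_equal(s0$p_value, 1)
  expect_equal(s0$effect, 1)

  # perfect separation: all expected counts 10, sum (O-E)^2/E = 40
  lab2 <- rep(c(0, 1), each = 20)
  expect_message(s2 <- chisq_summary(g, lab2), "0.5")
  expect_equal(s2$statistic, 40)

  # swapping both row and column labels leaves the statistic unchanged
  lab3 <- withr::with_seed(2, rbinom(40, 1, 0.4))
  s3 <- chisq_summary(g, lab3)
  g_swap <- factor(ifelse(g == "low", "high", "low"), levels = c("low", "high"))
  s4 <- chisq_summary(g_swap, 1 - lab3)
  expect_equal(s4$statistic, s3$statistic, tolerance = 1e-12)

  expect_error(chisq_summary(factor(rep("low", 10), levels = c("low", "high")),
                             rbinom(10, 1, 0.5)),
               "margin")
})

test_that("summary plots render and are written as PNG + SVG", {
  sim <- simulate_dataset("survival", n_samples = 60, n_genes = 30, n_signal = 6,
                          effect = 2, censor_rate = 0.3, seed = 14)
  run <- run_superpc(sim$expression, sim$outcome, "survival", n_thresholds = 4,
                     n_folds = 3, seed = 14)
  d <- withr::local_tempdir()
  paths <- render_summary_plots(run, d)
  expect_true(all(file.exists(paths)))
  expect_match(basename(paths), "^km\\.(png|svg)$")
  svg_txt <- paste(readLines(paths[2], warn = FALSE), collapse = "")
  expect_match(svg_txt, "<svg")

  expect_s3_class(plot_km(run$summary), "ggplot")
})
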