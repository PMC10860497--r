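test_that("detection proportions reproduce printed-count arithmetic", {
  expect_equal(detection_proportion(4, 174), 0.023)
  expect_equal(detection_proportion(3, 410), 0.007)
  expect_equal(detection_proportion(1, 250), 0.004)
  expect_equal(detection_proportion(0, 55), 0)
  expect_equal(detection_proportion(4, 174, digits = NULL), 4 / 174)
  expect_error(detection_proportion(1, 0), "undefined")
  expect_error(detection_proportion(5, 4), "detected")
})

test_that("the pooled z test matches the textbook formula and normal tails", {
  r <- two_proportion_z(5, 100, 5, 100)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  o <- oracle_two_prop_z(10, 100, 5, 100)
  r <- two_proportion_z(10, 100, 5, 100)
  expect_equal(r$statistic, o$z, tolerance = 1e-12)
  expect_equal(r$p.value, o$p, tolerance = 1e-12)

  # cross-check against the uncorrected chi-square: X^2 = z^2
  pt <- prop.test(c(10, 5), c(100, 100), correct = FALSE)
  expect_equal(r$statistic^2, unname(pt$statistic), tolerance = 1e-12)
  expect_equal(r$p.value, pt$p.value, tolerance = 1e-12)

  expect_error(two_proportion_z(0, 10, 0, 20), "degenerate")
  expect_error(two_proportion_z(10, 10, 20, 20), "degenerate")
})

test_that("paired t matches hand computation and exposes both tails", {
  b <- c(4, 7, 1, 9, 3)
  a <- b + c(1, 2, 3, 2, 2)     # differences mean 2, sd sqrt(0.5)
  o <- oracle_paired_t(a, b)
  r2 <- paired_t(a, b, tail = "two")
  expect_equal(r2$statistic, o$t, tolerance = 1e-12)
  expect_equal(r2$df, 4)
  expect_equal(r2$p.value, o$p_two, tolerance = 1e-12)
  r1 <- paired_t(a, b, tail = "one")
  expect_equal(r1$p.value, o$p_less, tolerance = 1e-12)

  # differences (1, 2, 3): t = mean/sd/sqrt(n) = 2 / (1/sqrt(3)) = 2*sqrt(3)
  d3 <- paired_t(c(1, 2, 3), c(0, 0, 0), tail = "two")
  expect_equal(d3$statistic, 2 * sqrt(3), tolerance = 1e-12)

  # symmetric differences around zero: t = 0, two-sided p = 1
  z0 <- paired_t(c(5, 6, 7), c(6, 6, 6), tail = "two")
  expect_equal(z0$statistic, 0)
  expect_equal(z0$p.value, 1)

  # one tail is half of two tails for the hypothesized sign (a < b)
  lo <- paired_t(b - c(1, 2, 1, 2, 1), b, tail = "one")
  hi <- paired_t(b - c(1, 2, 1, 2, 1), b, tail = "two")
  expect_equal(lo$p.value, hi$p.value / 2, tolerance = 1e-12)

  expect_error(paired_t(b, b), "zero variance")
})

test_that("repeated-measures ANOVA matches the long-hand SS decomposition", {
  withr::with_seed(5, {
    m <- matrix(runif(55), nrow = 11, ncol = 5)
  })
  r <- rm_anova_oneway(m)
  o <- oracle_rm_anova(m)
  expect_equal(r$statistic, o$f, tolerance = 1e-10)
  expect_equal(r$p.value, o$p, tolerance = 1e-10)
  expect_equal(c(r$df1, r$df2), c(4, 40))

  # pure subject offsets, no level effect: F = 0
  m0 <- matrix(rep(1:6, times = 3), nrow = 6)
  r0 <- rm_anova_oneway(m0)
  expect_equal(r0$statistic, 0)

  # two levels: F = t^2 of the paired t, equal p
  withr::with_seed(9, m2 <- matrix(rnorm(16), ncol = 2))
  ra <- rm_anova_oneway(m2)
  rt <- paired_t(m2[, 1], m2[, 2], tail = "two")
  expect_equal(ra$statistic, rt$statistic^2, tolerance = 1e-10)
  expect_equal(ra$p.value, rt$p.value, tolerance = 1e-10)
})

test_that("pearson r matches the covariance formula, with its limits", {
  x <- c(1, 4, 2, 8, 5, 7, 3, 9, 6, 10, 11)
  expect_equal(pearson_r(x, x)$estimate, 1)
  expect_equal(pearson_r(x, -x)$estimate, -1)
  withr::with_seed(3, y <- x + rnorm(11, sd = 3))
  r <- pearson_r(x, y)
  o <- oracle_pearson(x, y)
  expect_equal(r$estimate, o$r, tolerance = 1e-12)
  expect_equal(r$r.squared, o$r^2, tolerance = 1e-12)
  expect_equal(r$p.value, o$p, tolerance = 1e-12)
  expect_equal(r$df, 9)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
})

test_that("all tests agree with the oracles across many random datasets", {
  withr::with_seed(101, {
    for (rep in 1:100) {
      n <- sample(4:12, 1)
      a <- rnorm(n); b <- rnorm(n)
      if (var(a - b) > 0) {
        expect_equal(paired_t(a, b, "two")$statistic, oracle_paired_t(a, b)$t,
                     tolerance = 1e-10)
      }
      if (var(a) > 0 && var(b) > 0 && n >= 3 && abs(cor(a, b)) < 1) {
        expect_equal(pearson_r(a, b)$statistic, oracle_pearson(a, b)$t,
                     tolerance = 1e-10)
      }
      k <- sample(2:5, 1)
      m <- matrix(rnorm(n * k), nrow = n)
      expect_equal(rm_anova_oneway(m)$statistic, oracle_rm_anova(m)$f,
                   tolerance = 1e-10)
      n1 <- sample(50:300, 1); n2 <- sample(50:300, 1)
      x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
      expect_equal(two_proportion_z(x1, n1, x2, n2)$statistic,
                   oracle_two_prop_z(x1, n1, x2, n2)$z, tolerance = 1e-10)
    }
  })
})

make_responses <- function() {
  quick1 <- rep(c(TRUE, FALSE), length.out = 30)
  quick2 <- rep(c(FALSE, FALSE, TRUE), length.out = 30)
  pid <- rep(sprintf("P%02d", 1:6), each = 5)
  trial <- rep(1:5, times = 6)
  slow <- trial == 1 & pid %in% c("P01", "P02", "P03")
  tibble::tibble(
    participant_id = pid,
    trial_index = trial,
    stimulus_id = rep(sprintf("Img%d_YellowOrange", 1:5), times = 6),
    noticed_any = slow | quick1 | quick2,
    free_text = "",
    slow_detected = slow,
    quick1_detected = quick1,
    quick2_detected = quick2)
}

test_that("responses round-trip through CSV with code validation", {
  df <- make_responses()
  path <- write_responses_csv(df)
  back <- read_responses(path)
  expect_equal(nrow(back), 30)
  expect_type(back$slow_detected, "logical")

  bad <- df
  bad$noticed_any[1] <- FALSE      # codes present but nothing noticed
  expect_error(read_responses(write_responses_csv(bad)), "noticed_any")

  expect_error(read_responses(write_responses_csv(df[, -4])), "lacks column")
})

test_that("detection tables conserve marginals under regrouping", {
  df <- make_responses()
  overall <- detection_table(df)
  by_stim <- detection_table(df, stimulus_id)
  by_pos <- detection_table(df, trial_index)
  expect_equal(sum(by_stim$n_trials), overall$n_trials)
  expect_equal(sum(by_stim$n_slow_detected), overall$n_slow_detected)
  expect_equal(sum(by_pos$n_quick_detected), overall$n_quick_detected)
  expect_equal(overall$n_quick_opportunities, 60)   # 30 trials x 2 features
  # a participant appears exactly once per trial position
  expect_true(all(by_pos$n_trials == length(unique(df$participant_id))))
  expect_equal(overall$slow_rate,
               detection_proportion(overall$n_slow_detected, overall$n_trials,
                                    digits = NULL))
})

test_that("detection bar plots build", {
  p <- plot_detection_rates(detection_table(make_responses(), stimulus_id),
                            stimulus_id)
  expect_s3_class(p, "ggplot")
})
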