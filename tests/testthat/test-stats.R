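test_that("group summaries report mean and SEM with n-1 denominator", {
  counts <- data.frame(group = rep(c("a", "b"), each = 3),
                       count = c(10, 10, 10, 8, 10, 12))
  s <- group_summary(counts)
  expect_equal(s$mean, c(10, 10))
  expect_equal(s$sem[s$group == "a"], 0)
  expect_equal(s$sem[s$group == "b"], 2 / sqrt(3), tolerance = 1e-12)
  single <- group_summary(data.frame(group = "x", count = 7))
  expect_equal(single$mean, 7)
  expect_equal(single$sem, 0)
  expect_false(single$sem_defined)
  expect_error(group_summary(data.frame(group = character(0), count = numeric(0))),
               "non-empty")
})

test_that("fold change is the ratio of group means", {
  expect_equal(fold_change(c(5, 5), c(5, 5)), 1)
  expect_equal(fold_change(c(50, 70), c(15, 25)), 3)
  expect_error(fold_change(c(1, 2), c(0, 0)), "zero")
})

test_that("percent reduction and its delta-method error", {
  expect_equal(percent_reduction(c(10, 10), c(10, 10))$reduction_percent, 0)
  r <- percent_reduction(rep(100, 3), rep(63, 3))
  expect_equal(r$reduction_percent, 37)
  expect_equal(r$se_percent, 0)
  # hand-propagated SE: control {90,100,110}, treated {60,63,66}
  ctl <- c(90, 100, 110); trt <- c(60, 63, 66)
  r2 <- percent_reduction(ctl, trt)
  sem_c <- sd(ctl) / sqrt(3); sem_t <- sd(trt) / sqrt(3)
  expect_equal(r2$se_percent,
               100 * sqrt((sem_t / 100)^2 + (63 * sem_c / 100^2)^2),
               tolerance = 1e-12)
  expect_error(percent_reduction(c(0, 0), c(1, 2)), "zero")
})

test_that("one-tailed pooled t-test matches the closed-form t distribution", {
  # identical groups: t = 0, one-sided p = 0.5
  expect_equal(one_tailed_t(c(1, 2, 3), c(1, 2, 3), "greater"), 0.5)
  # {1,2,3} vs {4,5,6}: pooled sd = 1, t = -3/sqrt(2/3), df = 4
  p <- one_tailed_t(c(4, 5, 6), c(1, 2, 3), "greater")
  t_stat <- 3 / sqrt(2 / 3)
  expect_equal(p, pt(t_stat, df = 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(p, 0.0106558, tolerance = 1e-4)
  expect_error(one_tailed_t(c(1), c(1, 2)), "at least 2")
})

test_that("p decreases monotonically as the group shift grows", {
  base <- c(10, 12, 14, 16)
  shifts <- c(0.5, 1, 2, 4, 8)
  ps <- vapply(shifts, function(d) one_tailed_t(base + d, base, "greater"), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("fold change, reduction and p are invariant under count rescaling", {
  a <- c(30, 45, 60); b <- c(10, 15, 20)
  for (c_scale in c(2, 10)) {
    expect_equal(fold_change(a * c_scale, b * c_scale), fold_change(a, b))
    expect_equal(percent_reduction(a * c_scale, b * c_scale)$reduction_percent,
                 percent_reduction(a, b)$reduction_percent)
    expect_equal(one_tailed_t(a * c_scale, b * c_scale, "greater"),
                 one_tailed_t(a, b, "greater"))
  }
})

test_that("pooled t-test agrees with an exact permutation oracle", {
  a <- c(12, 15, 18, 21)
  b <- c(8, 10, 11, 13)
  p_t <- one_tailed_t(a, b, "greater")
  # enumerate all 70 reassignments of the pooled values
  pool <- c(a, b)
  combs <- utils::combn(8, 4)
  t_of <- function(x, y) {
    sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
    (mean(x) - mean(y)) / (sp * sqrt(0.5))
  }
  t_obs <- t_of(a, b)
  t_perm <- apply(combs, 2, function(ix) t_of(pool[ix], pool[-ix]))
  p_perm <- mean(t_perm >= t_obs - 1e-12)
  expect_lt(abs(p_t - p_perm), 0.05)
})

test_that("compare_groups bundles the comparison consistently", {
  counts <- data.frame(group = rep(c("day5", "day1"), each = 5),
                       count = c(55, 60, 70, 58, 62, 18, 22, 20, 24, 16))
  cmp <- compare_groups(counts, "day5", "day1", direction = "greater")
  expect_equal(cmp$fold_change,
               mean(counts$count[counts$group == "day5"]) /
                 mean(counts$count[counts$group == "day1"]))
  expect_equal(cmp$p_value,
               one_tailed_t(counts$count[counts$group == "day5"],
                            counts$count[counts$group == "day1"], "greater"))
  expect_lt(cmp$p_value, 0.05)
})
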