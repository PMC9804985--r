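test_that("log10 transform: powers of ten, fractions, domain errors", {
  expect_equal(log10_transform(c(1, 10, 100)), c(0, 1, 2))
  expect_equal(log10_transform(0.3), -0.5228787, tolerance = 1e-6)
  expect_error(log10_transform(c(1, 0, 2), labels = c("a", "b", "c")),
               "non-positive.*b")
  expect_equal(log10_transform(c(0, 9), offset = 1), c(0, 1))
})

test_that("assumption gates match the independent reference values", {
  # frozen oracle values computed with an independent statistics library
  res <- check_assumptions(list(a = c(1, 2, 3, 4, 5),
                                b = c(2, 4, 6, 8, 10)))
  expect_equal(res$bartlett_p, 0.207784123346, tolerance = 1e-6)
  w <- shapiro.test(1:8)$statistic
  expect_equal(unname(w), 0.974858256373, tolerance = 1e-4)
  expect_equal(unname(res$shapiro_p["a"]), shapiro.test(c(1:5))$p.value)

  same_var <- check_assumptions(list(a = c(1, 2, 3, 4, 5),
                                     b = c(2, 3, 4, 5, 6)))
  expect_equal(same_var$bartlett_p, 1)  # identical variances: statistic 0
  expect_error(check_assumptions(list(a = 1:2, b = 1:5)), "n >= 3")
})

test_that("a treatment identical to control gives t = 0, p = 1", {
  x <- c(1.2, 3.4, 2.2, 4.1)
  res <- dunnett_test(x, list(t1 = x, t2 = x + 1))
  expect_equal(res$t[1], 0)
  expect_equal(res$p_adjusted[1], 1)
})

test_that("one-comparison Dunnett equals the pooled t-test to 1e-8", {
  for (s in 1:50) {
    set.seed(s)
    x <- rnorm(3 + s %% 7, sd = 1 + s %% 3)
    y <- rnorm(4 + s %% 5, mean = s %% 2)
    res <- dunnett_test(x, list(g = y))
    df <- length(x) + length(y) - 2
    p_oracle <- 2 * (1 - pt(abs(res$t), df))
    expect_equal(res$p_adjusted, p_oracle, tolerance = 1e-8)
    expect_equal(res$p_adjusted, res$p_unadjusted, tolerance = 1e-12)
  }
})

test_that("two-comparison Dunnett p matches a large Monte-Carlo oracle", {
  set.seed(7)
  x0 <- rnorm(10); x1 <- rnorm(9, 0.7); x2 <- rnorm(8, 0.2)
  res <- dunnett_test(x0, list(a = x1, b = x2))
  n <- c(10, 9, 8); df <- sum(n) - 3
  lambda <- sqrt(n[-1] / (n[-1] + n[1]))
  gam <- sqrt(1 - lambda^2)
  # oracle: 1e6 draws of max_j |T_j| under the joint null
  set.seed(123)
  ndraw <- 1e6
  z0 <- rnorm(ndraw)
  s <- sqrt(rchisq(ndraw, df) / df)
  tmax <- pmax(abs(lambda[1] * z0 + gam[1] * rnorm(ndraw)),
               abs(lambda[2] * z0 + gam[2] * rnorm(ndraw))) / s
  for (j in 1:2) {
    p_mc <- mean(tmax >= abs(res$t[j]))
    expect_lt(abs(res$p_adjusted[j] - p_mc), 0.005)
  }
})

test_that("Dunnett agrees with the multivariate-t reference implementation", {
  set.seed(11)
  x0 <- rnorm(6); trts <- list(a = rnorm(5, 1), b = rnorm(7, -0.5),
                               c = rnorm(4, 0.2))
  res <- dunnett_test(x0, trts)
  n <- c(6, 5, 7, 4); df <- sum(n) - 4
  lambda <- sqrt(n[-1] / (n[-1] + n[1]))
  R <- outer(lambda, lambda); diag(R) <- 1
  for (j in 1:3) {
    set.seed(99)
    p_ref <- 1 - mvtnorm::pmvt(
      lower = rep(-abs(res$t[j]), 3), upper = rep(abs(res$t[j]), 3),
      corr = R, df = df,
      algorithm = mvtnorm::GenzBretz(abseps = 1e-6, maxpts = 1e6))
    expect_equal(res$p_adjusted[j], as.numeric(p_ref), tolerance = 1e-4)
  }
})

test_that("adjusted p never drops below the per-comparison p", {
  for (s in 1:10) {
    set.seed(100 + s)
    x0 <- rnorm(6)
    trts <- lapply(seq_len(1 + s %% 3), function(i) rnorm(5, i / 3))
    names(trts) <- paste0("t", seq_along(trts))
    res <- dunnett_test(x0, trts)
    expect_true(all(res$p_adjusted >= res$p_unadjusted - 1e-10))
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(dunnett_test(c(1, 1), list(a = c(1, 1))), "variance is zero")
  expect_error(dunnett_test(1, list(a = c(1, 2))), "n >= 2")
  expect_error(dunnett_test(c(1, 2), list()), "at least one treatment")
})

test_that("compare_cohort reproduces means, sds and is order-invariant", {
  cm <- simulate_cohort_metrics(c(ctrl = 0.8, dis = 0.3),
                                c(ctrl = 10L, dis = 9L), seed = 21L)
  res <- compare_cohort(cm, "value", control = "ctrl")
  s <- res$value$group_summary
  expect_equal(s$raw_mean[s$group == "ctrl"],
               mean(cm$value[cm$group == "ctrl"]))
  expect_equal(s$raw_sd[s$group == "dis"],
               sd(cm$value[cm$group == "dis"]))

  perm <- cm[sample(nrow(cm)), ]
  res_p <- compare_cohort(perm, "value", control = "ctrl")
  expect_equal(res_p$value$dunnett, res$value$dunnett)
  expect_equal(res_p$value$bartlett_p, res$value$bartlett_p)
})

test_that("zero policies: error by default, exclusion and offset work", {
  cm <- data.frame(animal_id = sprintf("a%02d", 1:8),
                   group = rep(c("c", "d"), each = 4),
                   value = c(1, 2, 3, 4, 0, 2, 3, 4))
  expect_error(compare_cohort(cm, "value", control = "c"), "non-positive")
  expect_warning(res <- compare_cohort(cm, "value", control = "c",
                                       zero_policy = "exclude"),
                 "excluded non-positive")
  expect_equal(res$value$group_summary$n, c(4L, 3L))
  res_o <- compare_cohort(cm, "value", control = "c",
                          zero_policy = "offset", offset = 1)
  expect_equal(res_o$value$group_summary$n, c(4L, 4L))
})

test_that("a metric missing for a whole group is skipped with a warning", {
  cm <- data.frame(animal_id = sprintf("a%02d", 1:6),
                   group = rep(c("c", "d"), each = 3),
                   value = c(1, 2, 3, NA, NA, NA))
  expect_warning(res <- compare_cohort(cm, "value", control = "c"),
                 "skipped")
  expect_length(res, 0)
})
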