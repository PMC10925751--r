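test_that("min-max normalization maps responses onto [0, 1]", {
  df <- data.frame(e_max = c(2, 6, 10), hic = c(5, 5, 9))
  norm <- normalize_responses(df, cols = c("e_max", "hic"))
  expect_equal(norm$e_max, c(0, 0.5, 1))
  expect_equal(range(norm$hic), c(0, 1))
  # idempotent on the extremes of an already-[0,1] column
  again <- normalize_responses(norm, cols = "e_max")
  expect_equal(range(again$e_max), c(0, 1))
  expect_error(normalize_responses(data.frame(e_max = rep(1, 4)),
                                   cols = "e_max"), "constant")
  z <- normalize_responses(df, cols = "e_max", method = "zscore")
  expect_equal(mean(z$e_max), 0)
  expect_equal(sd(z$e_max), 1)
})

test_that("Kruskal-Wallis factor test matches the hand-computed rank formula", {
  df <- data.frame(g = rep(c("a", "b", "c"), each = 3),
                   y = c(1, 2, 3, 101, 102, 103, 201, 202, 203))
  # oracle: H = 12/(N(N+1)) sum n_i Rbar_i^2 - 3(N+1), ranks 1..9, no ties
  rbar <- c(mean(1:3), mean(4:6), mean(7:9))
  H <- 12 / (9 * 10) * sum(3 * rbar^2) - 3 * 10
  p_oracle <- pchisq(H, df = 2, lower.tail = FALSE)
  expect_equal(factor_test(df, "g", "y"), p_oracle, tolerance = 1e-12)
  expect_lt(factor_test(df, "g", "y"), 0.05)

  expect_error(factor_test(data.frame(g = rep("a", 4), y = 1:4), "g", "y"),
               "fewer than 2 groups")
  expect_error(factor_test(data.frame(g = c("a", "b", "b"), y = 1:3),
                           "g", "y"), "fewer than 2 observations")
})

test_that("rank test is invariant under monotone response transforms", {
  set.seed(23)
  df <- data.frame(g = rep(letters[1:3], each = 10),
                   y = rnorm(30) + rep(c(0, 0.5, 1), each = 10))
  p0 <- factor_test(df, "g", "y")
  df$y <- exp(df$y)
  expect_equal(factor_test(df, "g", "y"), p0, tolerance = 1e-12)
})

test_that("linear fit reproduces closed forms and the normal equations", {
  x <- 1:10
  fit <- linear_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  expect_warning(f0 <- linear_fit(x, rep(3, 10)), "degenerate")
  expect_equal(f0$r_squared, 0)

  set.seed(29)
  xn <- rnorm(10); yn <- 1.5 * xn + rnorm(10)
  f <- linear_fit(xn, yn)
  # normal-equations oracle
  X <- cbind(1, xn)
  beta <- solve(t(X) %*% X, t(X) %*% yn)
  expect_equal(f$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f$slope, beta[2], tolerance = 1e-10)
  r2 <- 1 - sum((yn - X %*% beta)^2) / sum((yn - mean(yn))^2)
  expect_equal(f$r_squared, r2, tolerance = 1e-10)

  # R^2 invariant under affine rescaling of both variables
  f2 <- linear_fit(3 * xn - 7, -2 * yn + 4)
  expect_equal(f2$r_squared, f$r_squared, tolerance = 1e-10)

  expect_error(linear_fit(rep(1, 5), 1:5), "constant x")
  expect_error(linear_fit(1:2, 1:2), "fewer than 3")
})

test_that("factor test matrix flags significance at p < 0.05 per cell", {
  set.seed(31)
  df <- data.frame(position = rep(c("r", "f", "t"), each = 12),
                   material = rep(rep(c("ru", "gl", "st"), each = 4), 3),
                   velocity = rep(c(2, 6, 10), 12),
                   size = rep(c("min", "mid", "max"), 12))
  df$e_max <- 100 * df$velocity + rnorm(36, sd = 20)
  df$hic <- rnorm(36)
  ftm <- factor_test_matrix(df, responses = c("e_max", "hic"))
  expect_equal(ftm$factor, c("position", "material", "velocity", "size"))
  expect_identical(ftm$sig_e_max[ftm$factor == "velocity"], "*")
  expect_identical(ftm$sig_e_max, ifelse(ftm$p_e_max < 0.05, "*", ""))
})
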