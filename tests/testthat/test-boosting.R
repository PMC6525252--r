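make_linear_data <- function(n = 600, seed = 51) {
  set.seed(seed)
  d <- data.frame(current = runif(n), avg_rate = runif(n),
                  bottleneck = runif(n), gc3 = runif(n),
                  log_mrna = rnorm(n), hairpins = rpois(n, 2))
  d$y <- 1 + 2 * d$current + rnorm(n, 0, 0.3)
  d
}

test_that("a single linear signal is recovered with the right slope", {
  d <- make_linear_data()
  m <- expression_score(y ~ ., d, seed = 1)
  expect_true("current" %in% unique(m$trace))
  # slope on the central 80% of the range within 10% of the truth
  g <- seq(quantile(d$current, 0.1), quantile(d$current, 0.9),
           length.out = 50)
  f <- partial_function(m, "current", g)
  slope <- coef(lm.fit(cbind(1, g), f))[2]
  expect_lt(abs(slope - 2) / 2, 0.1)
})

test_that("constant outcomes give an offset-only model", {
  d <- make_linear_data(n = 100)
  d$y <- 5
  m <- expression_score(y ~ ., d, seed = 2)
  expect_identical(m$mstop, 0L)
  expect_identical(length(selected_features(m)), 0L)
  expect_equal(unname(predict(m, d)[1]), 5)
})

test_that("training loss is non-increasing and constraints hold", {
  b <- fix_bench_small()
  d <- b$data[, setdiff(names(b$data), c("id", "harmonic_rate"))]
  m <- fix_model_small()
  expect_true(all(diff(m$loss) <= 1e-10))
  for (nm in intersect(m$config$monotone, selected_features(m))) {
    g <- seq(m$learners[[nm]]$range[1], m$learners[[nm]]$range[2],
             length.out = 1000)
    expect_true(all(diff(partial_function(m, nm, g)) >= -1e-10))
  }
  # the hairpin effect has exactly two effective parameters (a line)
  g <- 0:10
  f <- partial_function(m, "hairpins", g)
  expect_equal(unname(diff(f)), rep(unname(f[2] - f[1]), 10),
               tolerance = 1e-9)
})

test_that("scoring with unit weights reproduces the fit exactly", {
  m <- fix_model_small()
  pr <- predict(m, m$train$x)
  expect_equal(unname(as.numeric(pr)), unname(fitted(m)), tolerance = 1e-12)
  v1 <- setNames(rep(1, length(m$feature_names)), m$feature_names)
  expect_equal(as.numeric(predict(m, m$train$x, weights = v1)),
               as.numeric(pr))
  # all-zero weights give the offset
  v0 <- setNames(rep(0, length(m$feature_names)), m$feature_names)
  expect_equal(unname(as.numeric(predict(m, m$train$x, weights = v0))),
               rep(m$offset, nrow(m$train$x)))
})

test_that("absent features obey the weighting contract", {
  m <- fix_model_small()
  x <- m$train$x
  x$log_mrna <- NA_real_
  if ("log_mrna" %in% selected_features(m)) {
    expect_error(predict(m, x), "log_mrna")
  }
  s <- predict(m, x, weights = c(log_mrna = 0))
  expect_false(anyNA(s))
  expect_error(predict(m, x, weights = c(nonexistent = 1)), "unknown")
  expect_error(predict(m, x, weights = c(log_mrna = -1)), "nonnegative")
})

test_that("explained variance behaves at its edges", {
  m <- fix_model_small()
  # perfect model on noiseless data
  d <- make_linear_data(n = 100)
  y_true <- 1 + 2 * d$current
  d$y <- y_true
  m0 <- expression_score(y ~ ., d,
                         config = boosting_config(mstop_max = 400,
                                                  bootstrap = 3),
                         seed = 3)
  expect_gt(explained_variance(m0), 0.95)
  # offset-only model explains ~nothing
  d2 <- make_linear_data(n = 200, seed = 99)
  mo <- expression_score(y ~ ., d2, seed = 4, mstop = 0)
  expect_lt(abs(explained_variance(mo)), 0.05)
  expect_error(explained_variance(m, newdata = d2[1:5, ],
                                  y = rep(1, 5)), "zero variance")
})

test_that("residual and fitted accessors are coherent", {
  m <- fix_model_small()
  expect_equal(fitted(m) + residuals(m), m$train$y)
})

test_that("the simplified linear/quadratic score matches linear truths", {
  d <- make_linear_data(n = 800, seed = 61)
  d$y <- 1 + 2 * d$current - 0.5 * d$gc3 + rnorm(800, 0, 0.2)
  m <- expression_score(y ~ ., d, seed = 5)
  co <- fit_simplified(m)
  full <- predict(m, d)
  simp <- simplified_score(d, co)
  expect_gt(cor(as.numeric(full), simp), 0.99)
  # hand-checkable evaluations
  expect_equal(simplified_score(data.frame(gc3 = 0.5),
                                list(intercept = 0,
                                     linear = c(gc3 = 0),
                                     gc3_quadratic = 0)), 0)
  co2 <- list(intercept = 0, linear = c(gc3 = 4), gc3_quadratic = -4)
  gvals <- seq(0, 1, 0.01)
  s <- simplified_score(data.frame(gc3 = gvals), co2)
  expect_equal(gvals[which.max(s)], 0.5)   # balanced GC3 optimal
})
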