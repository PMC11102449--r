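test_that("R-squared follows the residual/total sum-of-squares definition", {
  expect_equal(rsq(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rsq(c(1, 2, 4), c(1, 2, 3)), 0.5)  # SS_res = 1, SS_tot = 2
  # a shifted series fits worse than the mean: negative and flagged
  expect_warning(out <- rsq(c(0, 1, 2, 3) + 10, c(0, 1, 2, 3)), "negative")
  expect_equal(out, 1 - 4 * 100 / 5)
  expect_error(rsq(c(1, 2), c(3, 3)), "constant")
  expect_error(rsq(1:3, 1:4), "equal length")
  # invariance under a common affine rescaling of both series
  sim <- c(2, 5, 3, 8); ref <- c(1, 4, 4, 9)
  expect_equal(rsq(3 * sim - 2, 3 * ref - 2), rsq(sim, ref))
})

test_that("PRCC recovers a monotone driver and rejects an inert input", {
  set.seed(31)
  n <- 200
  X <- cbind(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  y <- 3 * X[, "x1"] + rnorm(n, sd = 0.2)
  pr <- prcc(X, y)
  expect_gt(pr["x1"], 0.95)
  expect_lt(abs(pr["x2"]), 0.1)
  expect_lt(abs(pr["x3"]), 0.1)
  # sign is preserved for a decreasing driver
  y2 <- -2 * X[, "x2"] + rnorm(n, sd = 0.2)
  expect_lt(prcc(X, y2)["x2"], -0.9)
  # hand-rolled oracle for the 2-column case: partial rank correlation via
  # residuals of simple rank regressions
  X2 <- X[, 1:2]
  r1 <- rank(X2[, 1]); r2 <- rank(X2[, 2]); ry <- rank(y)
  res_a <- residuals(lm(r1 ~ r2)); res_y <- residuals(lm(ry ~ r2))
  expect_equal(unname(prcc(X2, y)[1]), cor(res_a, res_y))
  expect_error(prcc(cbind(x1 = rep(1, n), x2 = runif(n)), y), "degenerate")
})

test_that("the sensitivity driver ranks parameters of an analytic harness", {
  p <- default_parameters()
  # response built only from the sampled values: increasing in beta,
  # decreasing in r, flat in mu
  resp <- function(pp, s) {
    set.seed(s)
    3 * pp$beta - 300 * pp$r + rnorm(1, sd = 0.05)
  }
  sens <- global_sensitivity(p, c("beta", "r", "mu"), n_samples = 60,
                             seed = 2, response = resp)
  expect_s3_class(sens, "tme_sensitivity")
  expect_equal(sens$parameter[1], "beta")
  expect_gt(sens$prcc[sens$parameter == "beta"], 0.9)
  expect_lt(abs(sens$prcc[sens$parameter == "mu"]), 0.25)
  expect_lt(sens$prcc[sens$parameter == "r"], -0.9)
  expect_equal(sens$rank, 1:3)
  expect_error(global_sensitivity(p, c("beta", "r"), n_samples = 5, seed = 1,
                                  response = resp), "at least 10")
  expect_error(global_sensitivity(p, "beta", n_samples = 20, rel_range = 0,
                                  seed = 1, response = resp), "degenerate")
})

test_that("identifiability flags duplicated parameters and clears orthogonal ones", {
  p <- default_parameters()
  days <- 0:10
  # harness: beta and r enter one output through the same trajectory shape
  # (perfect collinearity); mu enters a second output with a signature
  # orthogonal to beta's
  sim <- function(pp, s) {
    list(
      out1 = (pp$beta + 170 * pp$r) * days,
      out2 = pp$mu * (days - 5)^2 + pp$beta * days
    )
  }
  id <- identifiability(p, c("beta", "r", "mu"), delta = 0.1, seed = 1,
                        simulator = sim)
  expect_s3_class(id, "tme_identifiability")
  # matrix is symmetric with unit diagonal
  expect_equal(id$min_abs_cor, t(id$min_abs_cor))
  expect_equal(unname(diag(id$min_abs_cor)), rep(1, 3))
  # beta and r move out1 along the identical direction and r is absent from
  # out2, so every defined correlation is 1: non-identifiable
  expect_true(any(id$flagged$param1 == "beta" & id$flagged$param2 == "r"))
  # mu's centered-quadratic signature is orthogonal to beta's linear one
  expect_false(any(id$flagged$param1 == "beta" & id$flagged$param2 == "mu"))
  expect_lt(id$min_abs_cor["beta", "mu"], 0.9)
})

test_that("an inert parameter is excluded from identifiability with a warning", {
  p <- default_parameters()
  days <- 0:6
  sim <- function(pp, s) list(out1 = pp$beta * days, out2 = pp$beta * days^2)
  expect_warning(
    id <- identifiability(p, c("beta", "mu"), delta = 0.1, seed = 1,
                          simulator = sim),
    "inert"
  )
  expect_equal(id$inert, "mu")
  expect_true(is.na(id$min_abs_cor["beta", "mu"]))
  expect_equal(nrow(id$flagged), 0)
})

test_that("the synthetic reference curve rises smoothly to its final volume", {
  days <- 0:18
  v <- synthetic_reference_curve(days, v_final = 400)
  expect_equal(v[1], 0)
  expect_equal(v[length(v)], 400)
  expect_true(all(diff(v) > 0))
  # a perfect model of the curve scores R^2 = 1
  expect_equal(rsq(v, v), 1)
})
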