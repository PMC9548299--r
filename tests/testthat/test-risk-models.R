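sim_features <- function(n, beta, seed = 1) {
  # logistic generative model on three standard-normal features
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * 3), ncol = 3,
                dimnames = list(NULL, c("f1", "f2", "f3")))
    p <- plogis(drop(cbind(1, X) %*% beta))
    y <- rbinom(n, 1, p)
  })
  list(features = tibble::as_tibble(X), labels = y, p = p)
}

lin_spec <- function(features = c("f1", "f2", "f3"), ...) {
  risk_model_spec("test", feature_names = features, basis = "linear",
                  horizon_hours = 24, ...)
}

test_that("epoch labels honour the open-at-zero horizon window", {
  lab <- label_epochs(c(4700, 4900, 5000), 5000, horizon_hours = 4)
  expect_equal(lab$label, c(0L, 1L, 0L))  # 5 h out, in-window, at event

  expect_equal(label_epochs(c(100, 200), NA, 4)$label, c(0L, 0L))

  # censored epochs vanish from the output
  lab <- label_epochs(c(100, 200, 300), 250, 4,
                      censored = c(FALSE, TRUE, FALSE))
  expect_equal(lab$window_end_min, c(100, 300))
  expect_equal(lab$label, c(1L, 0L))

  # horizon nesting: positives at h1 < h2 are a subset of positives at h2
  ends <- seq(15, 6000, by = 15)
  l4 <- label_epochs(ends, 5000, 4)$label
  l24 <- label_epochs(ends, 5000, 24)$label
  expect_true(all(l24[l4 == 1] == 1))
  expect_gt(sum(l24), sum(l4))
})

test_that("restricted cubic spline basis has the standard structure", {
  x <- seq(-3, 3, length.out = 101)
  knots <- c(-1, 0, 2)
  B <- rcs_basis(x, knots)
  expect_identical(ncol(B), 2L)  # k - 1 columns for k = 3 knots
  expect_equal(B[, "lin"], x)
  # zero nonlinear contribution below the first knot
  expect_true(all(B[x <= -1, "nl1"] == 0))
  # linear beyond the last knot: vanishing second differences
  xr <- c(2.5, 3.0, 3.5)
  Br <- rcs_basis(xr, knots)
  expect_equal(unname(Br[3, "nl1"] - 2 * Br[2, "nl1"] + Br[1, "nl1"]), 0,
               tolerance = 1e-9)

  d <- sim_features(50, c(0, 1, 0, 0))$features
  spec <- risk_model_spec("s", c("f1", "f2", "f3"), basis = "rcs",
                          horizon_hours = 4)
  bb <- make_basis(d, spec)
  expect_identical(ncol(bb$X), 6L)  # 2 columns per feature
  expect_identical(length(bb$knots), 3L)

  # linear basis is the identity
  lb <- make_basis(d, lin_spec())
  expect_equal(unname(lb$X), unname(as.matrix(d)))

  d$f1[3] <- Inf
  expect_error(make_basis(d, lin_spec()), "row 3")
})

test_that("logistic fits recover generating coefficients", {
  # intercept-only closed form
  sim0 <- sim_features(500, c(-1, 0, 0, 0), seed = 4)
  m0 <- fit_model(sim0$features, sim0$labels, lin_spec(character(0)))
  expect_equal(unname(m0$coefficients[1]), qlogis(mean(sim0$labels)),
               tolerance = 1e-8)

  beta <- c(-2, 1, -0.8, 0.6)
  sim <- sim_features(20000, beta, seed = 7)
  m <- fit_model(sim$features, sim$labels, lin_spec())
  expect_lt(max(abs(m$coefficients - beta) / abs(beta)), 0.10)
  expect_true(m$train_mean_p > 0 && m$train_mean_p < 1)

  expect_error(fit_model(sim$features, rep(0L, 20000), lin_spec()),
               "both classes")
})

test_that("forward stepwise picks the informative feature first", {
  sim <- sim_features(3000, c(-1, 1.2, 0, 0), seed = 9)
  m <- fit_model(sim$features, sim$labels,
                 lin_spec(selection = "forward"))
  expect_identical(m$selected[1], "f1")
  expect_false(all(c("f2", "f3") %in% m$selected))
})

test_that("relative risk is the fold-increase over the development mean", {
  sim <- sim_features(4000, c(-1.5, 0.9, -0.5, 0.4), seed = 13)
  m <- fit_model(sim$features, sim$labels, lin_spec())
  rr <- predict_relative_risk(m, sim$features)
  # normalization identity on the development set
  expect_equal(mean(rr$relative_risk), 1, tolerance = 1e-6)
  expect_true(all(rr$relative_risk >= 0))

  # all-zero slopes with intercept logit(0.5): relative risk 1 everywhere
  m2 <- m
  m2$coefficients <- c(qlogis(0.5), 0, 0, 0)
  m2$train_mean_p <- 0.5
  rr2 <- predict_relative_risk(m2, sim$features)
  expect_true(all(rr2$relative_risk == 1))

  # monotonicity in a positive-coefficient feature (linear basis)
  grid <- tibble::tibble(f1 = seq(-2, 2, 0.5), f2 = 0, f3 = 0)
  rr3 <- predict_relative_risk(m, grid)$relative_risk
  if (m$coefficients["f1"] > 0) expect_true(all(diff(rr3) > 0))

  # capping
  rr4 <- predict_relative_risk(m, sim$features, cap = 1.5)
  expect_lte(max(rr4$relative_risk), 1.5)

  expect_error(predict_relative_risk(m, tibble::tibble(f1 = 1, f2 = 2)),
               "f3")
})
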