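test_that("generated Box-Behnken design has the canonical structure", {
  d <- bbd_design(corn_factors, n_center = 5)
  expect_equal(nrow(d), 17)
  expect_equal(nrow(bbd_design(corn_factors, n_center = 1)), 13)
  coded <- code_point(corn_factors, d[, corn_factors$name])
  n_zero <- rowSums(abs(coded) < 1e-12)
  expect_equal(sum(n_zero == 3), 5)           # center replicates
  expect_true(all(n_zero[n_zero != 3] == 1))  # every edge run: one factor at 0
  # actual-value multiset equals the bundled 17-run experiment
  key <- function(m) sort(apply(round(m, 6), 1, paste, collapse = "/"))
  expect_identical(key(d), key(corn_design[, corn_factors$name]))
  expect_silent(validate_bbd(d, corn_factors))
  # linear coded columns orthogonal to each other and to interactions
  X <- cbind(coded, coded[, 1] * coded[, 2], coded[, 1] * coded[, 3],
             coded[, 2] * coded[, 3])
  expect_equal(max(abs(crossprod(X)[1:3, ] - diag(c(8, 8, 8, 0, 0, 0))[1:3, ])),
               0)
})

test_that("coding transform round-trips and maps anchors correctly", {
  expect_equal(code_point(corn_factors, c(1.25, 2.25, 27.5)), c(0, 0, 0))
  expect_equal(code_point(corn_factors, c(1.35, 2.30, 27.44)),
               c(0.4, 0.066667, -0.008), tolerance = 1e-5)
  set.seed(7)
  for (i in 1:20) {
    x <- runif(3, c(0.8, 1, 15), c(1.7, 3.5, 40))
    expect_equal(uncode_point(corn_factors, code_point(corn_factors, x)), x,
                 tolerance = 1e-12)
  }
})

test_that("noiseless synthetic surfaces are recovered to numerical precision", {
  set.seed(42)
  for (i in 1:5) {
    beta <- rnorm(10, sd = 5)
    d <- sim_bbd_responses(corn_factors, beta, sd = 0, seed = i)
    fit <- fit_quadratic(d, "Y")
    expect_equal(unname(fit$coefficients), beta, tolerance = 1e-9)
    expect_lt(fit$residual_ss, 1e-16 * max(1, fit$total_ss))
  }
})

test_that("ANOVA decomposition identities hold on every corn response", {
  for (fit in corn_fits) {
    a <- anova(fit)
    ss <- function(src) a$ss[a$source == src]
    expect_equal(ss("Model") + ss("Residual"), ss("Cor total"),
                 tolerance = 1e-6 * ss("Cor total"))
    expect_equal(ss("Lack of fit") + ss("Pure error"), ss("Residual"),
                 tolerance = 1e-6)
    expect_equal(a$df[a$source == "Model"] + a$df[a$source == "Residual"],
                 a$df[a$source == "Cor total"])
    expect_equal(attr(a, "r2"), ss("Model") / ss("Cor total"), tolerance = 1e-12)
    # orthogonal-column shortcut: linear partial SS = 8 * coefficient^2
    for (k in 1:3) {
      nm <- fit$factors$name[k]
      expect_equal(a$ss[a$source == nm], 8 * unname(fit$coefficients[nm])^2,
                   tolerance = 1e-8)
    }
  }
})

test_that("quadratic-term partial SS are non-additive on this design", {
  a <- anova(corn_fits$DH)
  quad_ss <- sum(a$ss[grepl("\\^2$", a$source)])
  lin_int_ss <- sum(a$ss[a$source %in% c(corn_factors$name,
                                         "enzyme_dosage:hydrolysis_time",
                                         "enzyme_dosage:solid_liquid_ratio",
                                         "hydrolysis_time:solid_liquid_ratio")])
  model_ss <- a$ss[a$source == "Model"]
  expect_gt(abs(quad_ss + lin_int_ss - model_ss), 0.01)
})

test_that("prediction at the coded origin equals the intercept", {
  for (fit in corn_fits) {
    expect_equal(predict(fit, coded = c(0, 0, 0)),
                 unname(fit$coefficients[1]), tolerance = 1e-12)
  }
  beta <- rep(0, 10)
  d <- sim_bbd_responses(corn_factors, beta, sd = 0, seed = 1)
  fit0 <- fit_quadratic(d, "Y")
  expect_equal(predict(fit0, coded = c(0.3, -0.7, 0.2)), 0, tolerance = 1e-9)
  # actual-unit and coded-unit prediction agree
  expect_equal(predict(corn_fits$DH, actual = c(1.35, 2.30, 27.44)),
               predict(corn_fits$DH, coded = opt_coded), tolerance = 1e-12)
})

test_that("linear-coefficient estimates are unbiased under replicated noise", {
  beta <- c(50, 2, 7, 6, 1.5, -0.5, -1.8, 3, -7, -0.5)
  sigma <- 2
  est <- t(vapply(1:100, function(s) {
    d <- sim_bbd_responses(corn_factors, beta, sd = sigma, seed = s)
    unname(fit_quadratic(d, "Y")$coefficients[2:4])
  }, numeric(3)))
  # OLS on orthogonal +/-1 columns: var = sigma^2 / 8 per linear coefficient
  expect_true(all(abs(colMeans(est) - beta[2:4]) < 3 * sigma / sqrt(8 * 100)))
})

test_that("desirability optimization solves a known single-response problem", {
  # concave quadratic with interior analytic maximum: y = 10 - (x1-.3)^2 - ...
  beta <- c(10 - 0, 0.6, -0.4, 0.2, 0, 0, 0, -1, -1, -1)
  # stationary point of b0 + b.x - x.x: x* = b/2
  xstar <- c(0.3, -0.2, 0.1)
  beta[1] <- 10
  beta[2:4] <- 2 * xstar
  d <- sim_bbd_responses(corn_factors, beta, sd = 0, seed = 1)
  fit <- fit_quadratic(d, "Y")
  # anchors chosen above the surface maximum so d stays strictly increasing
  # (observed-range anchors would clip d at 1 around the peak, making the
  # argmax a plateau rather than a point)
  opt <- optimize_desirability(list(fit), anchors = list(c(0, 12)))
  expect_equal(opt$point_coded, xstar, tolerance = 1e-4)
  expect_equal(unname(opt$predicted), predict(fit, coded = xstar),
               tolerance = 1e-6)
})

test_that("desirability is invariant to a common rescaling of the weights", {
  o1 <- optimize_desirability(corn_fits, weights = c(1, 1, 1, 1))
  o2 <- optimize_desirability(corn_fits, weights = c(2, 2, 2, 2))
  expect_equal(o1$point_coded, o2$point_coded, tolerance = 1e-6)
  expect_equal(o1$desirability, o2$desirability, tolerance = 1e-6)
  expect_true(all(abs(o1$point_coded) <= 1))
  expect_true(o1$desirability >= 0 && o1$desirability <= 1)
})

test_that("fit and ANOVA are invariant to run order", {
  set.seed(5)
  shuf <- corn_design[sample(nrow(corn_design)), ]
  attr(shuf, "factors") <- corn_factors
  fit2 <- fit_quadratic(shuf, "DH")
  expect_equal(fit2$coefficients, corn_fits$DH$coefficients, tolerance = 1e-10)
  a1 <- anova(corn_fits$DH); a2 <- anova(fit2)
  expect_equal(a2$ss, a1$ss, tolerance = 1e-8)
})

test_that("degenerate designs are rejected", {
  expect_error(bbd_factors(c("a", "b"), low = c(0, 0), high = c(1, 1)),
               "3 factors")
  expect_error(fit_quadratic(corn_design[1:8, ], "DH",
                             factors = corn_factors), "10 runs")
  # collapsing a factor to its center makes the matrix rank-deficient
  flat <- corn_design
  flat$enzyme_dosage <- 1.25
  attr(flat, "factors") <- corn_factors
  expect_error(fit_quadratic(flat, "DH"), "rank-deficient")
})
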