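test_that("2-SD standardization centers and scales as advertised", {
  s <- standardize_predictor(c(0, 0.1, 0.2))
  expect_equal(s$x_std, c(-0.5, 0, 0.5))
  expect_equal(s$sd, 0.1)
  set.seed(8)
  for (i in 1:10) {
    x <- stats::rnorm(50, stats::runif(1, -5, 5), stats::runif(1, 0.1, 10))
    z <- standardize_predictor(x)$x_std
    expect_lt(abs(mean(z)), 1e-12)
    expect_equal(stats::sd(z), 0.5, tolerance = 1e-12)
  }
  expect_error(standardize_predictor(rep(0.3, 10)), "no variance")
})

test_that("probability of direction counts the dominant sign", {
  expect_equal(probability_of_direction(c(1, 2, 3)), 100)
  expect_equal(probability_of_direction(c(-2, -1, 1, 2)), 50)
  # a draw exactly at zero splits between the sides
  expect_equal(probability_of_direction(c(0, 1, 1, 1)), 87.5)
  # 9719 of 10000 draws sharing the median's sign reads as 97.19
  draws <- c(rep(1, 9719), rep(-1, 281))
  expect_equal(probability_of_direction(draws), 97.19)
})

test_that("split R-hat matches the formula oracle on constructed chains", {
  # identical constant chains: guarded to 1 with a warning
  expect_warning(r <- rhat(cbind(rep(2, 100), rep(2, 100))), "identical")
  expect_equal(r, 1)
  # iid same-distribution chains mix perfectly
  set.seed(303)
  expect_lt(rhat(matrix(stats::rnorm(4e4), ncol = 4)), 1.01)
  # well-separated chains blow past the 1.1 convergence line
  sep <- cbind(stats::rnorm(500, 0), stats::rnorm(500, 10))
  expect_gt(rhat(sep), 1.5)
  # numerical agreement with an independent application of the formula
  # (rank-normalize the split chains, then the classic Gelman-Rubin ratio)
  chains <- cbind(stats::rnorm(400, 0, 1), stats::rnorm(400, 0.4, 1.3))
  split <- cbind(chains[1:200, ], chains[201:400, ])
  z <- stats::qnorm((rank(split) - 0.375) / (length(split) + 0.25))
  expect_equal(rhat(chains), psrf_formula(matrix(z, nrow = 200)),
               tolerance = 1e-12)
  expect_error(rhat(list(1:10, 1:9)), "equal lengths")
})

test_that("effect classification follows the CrI and pd rules", {
  expect_equal(classify_effect(0.28, 3.74, 97.19), "meaningful")
  expect_equal(classify_effect(-1.76, 2.64, 62.22), "none")
  # CrI straddles zero but pd >= 89: the rules conflict, report as such
  expect_equal(classify_effect(-0.73, 0.07, 91.33), "indeterminate")
  expect_equal(classify_effect(-122.86, -18.45, 98.67), "meaningful")
  # excludes zero with pd barely under 95 reads as moderate support
  expect_equal(classify_effect(0.1, 2.0, 93), "moderate")
  # non-convergence always wins
  expect_equal(classify_effect(0.28, 3.74, 97.19, converged = FALSE),
               "indeterminate")
})

test_that("gaussian fit without random effects matches the OLS oracle", {
  set.seed(19)
  n <- 120
  x <- stats::runif(n, 0, 0.23)
  z <- standardize_predictor(x)$x_std
  y <- 60 + 2 * z + stats::rnorm(n, 0, 4)
  dat <- data.frame(individual_id = sprintf("b%03d", 1:n),
                    migration_year = rep(2019:2022, 30),
                    departure_doy = y, gamefarm_fraction = x)
  fit <- fit_ancestry_model(dat, "departure_doy", chains = 2, iter = 4000,
                            burn_in = 1000, seed = 3,
                            random_effects = FALSE)
  ols <- stats::lm(y ~ z)
  expect_lt(abs(coef(fit)[["beta"]] - coef(ols)[["z"]]),
            3 * fit$summary$mcse_beta)
  expect_lt(abs(coef(fit)[["alpha"]] - coef(ols)[["(Intercept)"]]),
            3 * fit$summary$mcse_beta * 2)
  expect_true(fit$summary$converged)
})

test_that("known-sigma gaussian posterior matches the conjugate form", {
  set.seed(23)
  n <- 150
  sigma <- 3
  x <- stats::runif(n, 0, 0.23)
  z <- standardize_predictor(x)$x_std
  y <- 10 + 1.5 * z + stats::rnorm(n, 0, sigma)
  dat <- data.frame(individual_id = sprintf("b%03d", 1:n),
                    migration_year = 2020,
                    departure_doy = y, gamefarm_fraction = x)
  fit <- suppressWarnings(
    fit_ancestry_model(dat, "departure_doy", chains = 2, iter = 5000,
                       burn_in = 1000, seed = 3, random_effects = FALSE,
                       fixed_sigma = sigma))
  # closed-form normal posterior with prior N(0, (10 sd(y))^2) on (alpha, beta)
  X <- cbind(1, z)
  prior_prec <- diag(2) / (10 * stats::sd(y))^2
  V <- solve(crossprod(X) / sigma^2 + prior_prec)
  m <- V %*% (crossprod(X, y) / sigma^2)
  bd <- unlist(lapply(fit$draws, function(d) as.matrix(d)[, "beta"]))
  expect_lt(abs(mean(bd) - m[2]), 3 * fit$summary$mcse_beta)
  expect_equal(stats::var(bd), V[2, 2], tolerance = 0.1)
})

test_that("a zero-count Poisson response shows no ancestry effect", {
  dat <- data.frame(individual_id = sprintf("b%02d", 1:40),
                    migration_year = rep(2019:2022, 10),
                    n_stopovers = 0L,
                    gamefarm_fraction = stats::runif(40, 0, 0.23))
  fit <- suppressWarnings(
    fit_ancestry_model(dat, "n_stopovers", family = "poisson", chains = 2,
                       iter = 3000, burn_in = 1000, seed = 7))
  expect_lte(fit$summary$cri_low, 0)
  expect_gte(fit$summary$cri_high, 0)
  expect_true(fit$summary$effect_class %in% c("none", "indeterminate"))
})

test_that("fits are reproducible and expose coherent methods", {
  set.seed(77)
  truth <- simulation_truth(n_individuals = 40, seed = 15)
  ph <- simulate_phenology(truth)
  f1 <- fit_ancestry_model(ph, "departure_doy", chains = 2, iter = 2000,
                           burn_in = 500, seed = 11)
  f2 <- fit_ancestry_model(ph, "departure_doy", chains = 2, iter = 2000,
                           burn_in = 500, seed = 11)
  expect_identical(as.matrix(f1$draws[[1]]), as.matrix(f2$draws[[1]]))
  expect_identical(f1$summary, f2$summary)
  # pd and CrI are mutually consistent for an equal-tailed 90% interval
  s <- f1$summary
  if (s$cri_low > 0 || s$cri_high < 0) expect_gte(s$pd, 95)
  # methods
  expect_named(coef(f1), c("alpha", "beta"))
  pr <- predict(f1, c(0, 0.1, 0.2))
  expect_equal(nrow(pr), 3)
  expect_true(all(pr$lower <= pr$fit & pr$fit <= pr$upper))
  expect_length(residuals(f1), f1$n)
  tb <- summary(f1)
  expect_equal(tb$beta, s$beta)
  # rows with a missing response are dropped with a message
  ph2 <- ph
  ph2$departure_doy[1:3] <- NA
  expect_message(
    f3 <- fit_ancestry_model(ph2, "departure_doy", chains = 2, iter = 1500,
                             burn_in = 500, seed = 11),
    "dropping 3")
  expect_equal(f3$n, nrow(ph) - 3)
})
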