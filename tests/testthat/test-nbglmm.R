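# simulate NB2 mixed-model data with known parameters
sim_nbmm <- function(n_groups = 10, n_per = 500, beta = c(2, -0.5), theta = 5,
                     sigma2 = 0.25, seed = 1) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = n_per)
  x <- rnorm(n_groups * n_per)
  u <- rnorm(n_groups, 0, sqrt(sigma2))
  mu <- exp(beta[1] + beta[2] * x + u[g])
  tibble::tibble(
    group_id = sprintf("g%02d", g), x = x,
    y = rnbinom(n_groups * n_per, size = theta, mu = mu)
  )
}

test_that("the intercept-only fit returns the log sample mean exactly", {
  set.seed(2)
  d <- tibble::tibble(
    group_id = "only",
    y = rnbinom(300, size = 3, mu = 20)
  )
  glm_fit <- fit_nb_glm(d, y ~ 1)
  expect_equal(glm_fit$coefficients$estimate[1], log(mean(d$y)), tolerance = 1e-8)

  # the mixed fitter with a single group pins the variance and agrees
  expect_warning(
    mm <- fit_nb_glmm(d, y ~ 1, group = "group_id"),
    "fewer than 2 groups"
  )
  expect_equal(mm$re_variance, 0)
  expect_true(mm$boundary)
  expect_equal(mm$coefficients$estimate[1], log(mean(d$y)), tolerance = 1e-6)
})

test_that("parameters are recovered from self-simulated mixed data", {
  d <- sim_nbmm(seed = 42)
  fit <- fit_nb_glmm(d, y ~ x, quad_points = 15)
  expect_true(fit$converged)
  cf <- fit$coefficients
  expect_lt(abs(cf$estimate[1] - 2.0) / cf$std.error[1], 3)
  expect_lt(abs(cf$estimate[2] + 0.5) / cf$std.error[2], 3)
  expect_lt(abs(fit$theta - 5) / 5, 0.25)
  expect_gt(fit$re_variance, 0.05)
  expect_lt(fit$re_variance, 1)

  # quadrature convergence: 15 vs 25 nodes barely move the estimates
  fit25 <- fit_nb_glmm(d, y ~ x, quad_points = 25)
  expect_lt(max(abs(fit$coefficients$estimate - fit25$coefficients$estimate)), 1e-3)
})

test_that("the marginal fit agrees with an independent mixed-model fitter", {
  skip_if_not_installed("glmmTMB")
  d <- sim_nbmm(n_groups = 8, n_per = 200, seed = 7)
  fit <- fit_nb_glmm(d, y ~ x, quad_points = 15)
  tmb <- glmmTMB::glmmTMB(y ~ x + (1 | group_id),
    data = d, family = glmmTMB::nbinom2
  )
  expect_equal(fit$loglik, as.numeric(stats::logLik(tmb)), tolerance = 1e-3)
  expect_equal(
    fit$coefficients$estimate,
    unname(glmmTMB::fixef(tmb)$cond),
    tolerance = 1e-3
  )
  expect_equal(fit$theta, glmmTMB::sigma(tmb), tolerance = 1e-2)
})

test_that("without group effects the mixed fit collapses to the NB GLM", {
  d <- sim_nbmm(n_groups = 10, n_per = 200, sigma2 = 0, seed = 8)
  fit <- fit_nb_glmm(d, y ~ x, quad_points = 15)
  glm_fit <- fit_nb_glm(d, y ~ x)
  expect_lt(abs(fit$loglik - glm_fit$loglik), 1e-4)
  # nested models: the marginal likelihood can never fall below the GLM's
  expect_gte(fit$loglik, glm_fit$loglik - 1e-6)
})

test_that("AIC supports the random intercept exactly when it is present", {
  d <- sim_nbmm(n_groups = 10, n_per = 300, sigma2 = 0.5, seed = 9)
  mm <- fit_nb_glmm(d, y ~ x)
  gl <- fit_nb_glm(d, y ~ x)
  expect_lt(mm$AIC, gl$AIC)
})

test_that("Poisson-generated counts drive the dispersion to the Poisson limit", {
  set.seed(10)
  d <- tibble::tibble(
    group_id = rep(c("a", "b"), each = 400),
    x = rnorm(800)
  )
  d$y <- rpois(800, exp(1.5 + 0.4 * d$x))
  gl <- fit_nb_glm(d, y ~ x)
  expect_gt(gl$theta, 50)
  pois <- glm(y ~ x, data = d, family = poisson())
  expect_equal(gl$coefficients$estimate, unname(coef(pois)), tolerance = 0.02)
})

test_that("the gamma comparison fit behaves as a gamma GLM", {
  d <- tibble::tibble(group_id = "a", y = rep(7.5, 50), x = rnorm(50))
  fit <- fit_gamma_glm(d, y ~ 1)
  expect_equal(fit$coefficients$estimate[1], log(7.5), tolerance = 1e-8)

  set.seed(11)
  shape <- 4
  d2 <- tibble::tibble(x = rnorm(500))
  d2$y <- rgamma(500, shape = shape, rate = shape / exp(1 + 0.3 * d2$x))
  fit2 <- fit_gamma_glm(d2, y ~ x)
  expect_lt(abs(fit2$coefficients$estimate[2] - 0.3) / fit2$coefficients$std.error[2], 3)
  expect_lt(abs(fit2$shape - shape) / shape, 0.3)

  d2$y[1] <- 0
  expect_error(fit_gamma_glm(d2, y ~ x), "strictly positive")
})

test_that("simulation-based GOF is deterministic and self-consistent", {
  d <- sim_nbmm(n_groups = 6, n_per = 150, seed = 12)
  d$season <- factor(rep(c("dry", "wet"), length.out = nrow(d)))
  fit <- fit_nb_glmm(d, y ~ x)
  g1 <- simulate_gof(fit, d, n_sims = 30, groupings = "season", seed = 5)
  g2 <- simulate_gof(fit, d, n_sims = 30, groupings = "season", seed = 5)
  expect_identical(g1$sims, g2$sims)
  expect_true(all(g1$sims >= 0 & g1$sims == round(g1$sims)))
  expect_s3_class(g1$summary, "tbl_df")
  expect_lt(g1$gof_stat, 0.2) # the model fits its own data

  # refit on one simulated response vector: estimates within 3 SE
  d_ref <- d
  d_ref$y <- g1$sims[, 1]
  refit <- fit_nb_glmm(d_ref, y ~ x)
  dev <- abs(refit$coefficients$estimate - fit$coefficients$estimate) /
    refit$coefficients$std.error
  expect_true(all(dev < 3))

  g0 <- simulate_gof(fit, d, n_sims = 0)
  expect_equal(ncol(g0$sims), 0)
  expect_null(g0$summary)
})

test_that("the coefficient table is ordered, rounded and flagged", {
  fit <- list(
    coefficients = tibble::tibble(
      term = c("seasonwet", "(Intercept)", "log_lion_use_s", "proximitynear"),
      estimate = c(-0.3091, 9.4712, -0.1034, 0.2614),
      std.error = c(0.0249, 0.1391, 0.0193, 0.0801),
      statistic = c(-12.4257, 67.987, -5.352, 3.268),
      p.value = c(1e-34, 0, 2 * pnorm(-5.352), 0.0011)
    )
  )
  tabl <- coefficient_table(fit)
  expect_equal(
    tabl$term,
    c("(Intercept)", "log_lion_use_s", "seasonwet", "proximitynear")
  )
  expect_equal(tabl$estimate[2], -0.103)
  expect_equal(tabl$se[2], 0.019)
  # z = -5.352 lands in the p < 0.001 bucket and is flagged
  expect_lt(tabl$p[2], 0.001)
  expect_true(tabl$bold[2])
  expect_false("breedingnon_breeding" %in% tabl$term)
})

test_that("centering and scaling predictors leaves inference unchanged", {
  d <- sim_nbmm(n_groups = 6, n_per = 200, seed = 13)
  d$x2 <- (d$x - 1.7) / 2.5
  f1 <- fit_nb_glmm(d, y ~ x, quad_points = 15)
  f2 <- fit_nb_glmm(d, y ~ x2, quad_points = 15)
  expect_equal(f2$coefficients$estimate[2], f1$coefficients$estimate[2] * 2.5,
    tolerance = 1e-4
  )
  expect_equal(f2$coefficients$statistic[2], f1$coefficients$statistic[2],
    tolerance = 1e-3
  )
})

test_that("invalid responses are rejected", {
  d <- tibble::tibble(group_id = rep(c("a", "b"), 5), y = c(1.5, rep(2, 9)), x = rnorm(10))
  expect_error(fit_nb_glmm(d, y ~ x), "non-negative integers")
  d$y <- c(-1, rep(2, 9))
  expect_error(fit_nb_glm(d, y ~ x), "non-negative integers")
})
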