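#' Negative-binomial mixed model with a group random intercept
#'
#' Fits `y ~ NB2(mu, theta)` with `log(mu) = X b + u_g`,
#' `u_g ~ Normal(0, sigma2_g)`, by maximizing the marginal likelihood.  The
#' per-group integral over the random intercept is approximated by adaptive
#' Gauss-Hermite quadrature: the integrand's mode and curvature are located
#' by Newton iteration for every group at every likelihood evaluation, and
#' `quad_points` Hermite nodes are centred and scaled there.  The NB2
#' ("quadratic") parameterization has variance `mu + mu^2 / theta`.
#' Standard errors come from the inverse of the observed information
#' (numerical Hessian of the marginal log likelihood); z-scores and
#' two-sided normal p-values follow.  Starting values are the
#' fixed-effects-only negative binomial fit with a small initial
#' random-intercept variance.
#'
#' @param data model data frame; the response must be non-negative
#'   integers.
#' @param formula fixed-effects formula, e.g.
#'   `response ~ log_lion_use_s + season + proximity`.
#' @param group name of the grouping column (random intercept); at least 2
#'   groups are required for the variance to be estimable.  With a single
#'   group the variance is pinned to zero with a warning.
#' @param quad_points number of Gauss-Hermite nodes (default 15).
#' @param start_sigma2 initial random-intercept variance.
#' @param fix_sigma2 optional: hold the random-intercept variance at this
#'   value instead of estimating it (the quadrature machinery still runs;
#'   holding it near zero must reproduce the fixed-effects likelihood, a
#'   useful degeneracy check).
#' @return an object of class `nb_glmm`: coefficient table, `theta`,
#'   `re_variance`, per-group intercept modes, log likelihood, AIC,
#'   convergence and boundary flags.
#' @export
fit_nb_glmm <- function(data, formula, group = "group_id", quad_points = 15,
                        start_sigma2 = 0.1, fix_sigma2 = NULL) {
  data <- drop_empty_levels(data)
  mf <- model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  check_count_response(y)
  gf <- factor(data[[group]])
  G <- nlevels(gf)
  gi <- as.integer(gf)
  p <- ncol(X)
  single_group <- G < 2
  if (single_group) {
    warn("fewer than 2 groups: random-intercept variance pinned at zero")
  }
  start_fit <- suppressWarnings(MASS::glm.nb(formula, data = data))
  b0 <- coef(start_fit)
  theta0 <- start_fit$theta
  gh <- pracma::gaussHermite(quad_points)
  u_cache <- rep(0, G)
  lgy1 <- lgamma(y + 1) # constant across likelihood evaluations

  # marginal negative log likelihood; Newton mode-finding vectorized
  # across groups via rowsum().  mu/(theta+mu) is computed as
  # plogis(eta + u - log(theta)) so extreme linear predictors stay finite.
  nll <- function(par) {
    beta <- par[seq_len(p)]
    theta <- exp(par[p + 1])
    sig <- exp(par[p + 2])
    eta <- drop(X %*% beta)
    if (!all(is.finite(eta))) {
      return(1e12)
    }
    u <- u_cache
    for (it in 1:25) {
      r <- stats::plogis(eta + u[gi] - par[p + 1])
      g1 <- drop(rowsum(y - (y + theta) * r, gi)) - u / sig^2
      g2 <- pmin(-drop(rowsum((y + theta) * r * (1 - r), gi)) - 1 / sig^2, -1e-300)
      step <- pmax(pmin(-g1 / g2, 3), -3)
      u <- u + step
      if (!all(is.finite(u))) {
        return(1e12)
      }
      # step-based stop: with very large counts the gradient's floating
      # noise floor exceeds any absolute gradient tolerance
      if (max(abs(step)) < 1e-10) break
    }
    u_cache <<- u
    r <- stats::plogis(eta + u[gi] - par[p + 1])
    g2 <- pmin(-drop(rowsum((y + theta) * r * (1 - r), gi)) - 1 / sig^2, -1e-300)
    tau <- 1 / sqrt(-g2)
    # all nodes at once: uk is (groups x nodes), expanded to observations.
    # The NB2 log pmf is written out so the gamma-function terms (which do
    # not depend on the node) are computed once per evaluation:
    # log f = lgamma(y+th) - lgamma(th) - lgamma(y+1)
    #         + th*(log th - log(th+mu)) + y*(log mu - log(th+mu))
    uk <- sweep(sqrt(2) * tau %o% gh$x, 1, u, "+")
    et <- pmin(matrix(eta, length(eta), quad_points) + uk[gi, , drop = FALSE], 700)
    lgc <- lgamma(y + theta) - lgamma(theta) - lgy1
    lt <- par[p + 1]
    mx <- pmax(et, lt)
    lse <- mx + log(exp(et - mx) + exp(lt - mx)) # log(theta + mu), stable
    lp <- lgc + theta * (lt - lse) + y * (et - lse)
    hk <- rowsum(lp, gi) +
      dnorm(uk, 0, sig, log = TRUE) +
      matrix(gh$x^2 + log(gh$w), G, quad_points, byrow = TRUE)
    m <- apply(hk, 1, max)
    ll <- sum(log(sqrt(2) * tau) + m + log(rowSums(exp(hk - m))))
    if (!is.finite(ll)) {
      return(1e12)
    }
    -ll
  }

  # with one group the model degenerates to the fixed-effects NB fit
  nll_fixed <- function(par) {
    beta <- par[seq_len(p)]
    theta <- exp(par[p + 1])
    -sum(stats::dnbinom(y, size = theta, mu = exp(drop(X %*% beta)), log = TRUE))
  }

  if (single_group) {
    par0 <- unname(c(b0, log(theta0)))
    opt <- nlminb(par0, nll_fixed,
      lower = c(rep(-Inf, p), log(1e-4)), upper = c(rep(Inf, p), log(1e8)),
      control = list(iter.max = 500, eval.max = 2000)
    )
    hess <- optimHess(opt$par, nll_fixed)
    par_full <- c(opt$par, log(1e-8))
    re_var <- 0
    boundary <- TRUE
    k <- p + 1
  } else {
    ls0 <- if (is.null(fix_sigma2)) log(sqrt(start_sigma2)) else log(sqrt(fix_sigma2))
    ls_lo <- if (is.null(fix_sigma2)) log(1e-6) else ls0
    ls_hi <- if (is.null(fix_sigma2)) log(1e3) else ls0
    par0 <- unname(c(b0, log(theta0), ls0))
    opt <- nlminb(par0, nll,
      lower = c(rep(-Inf, p), log(1e-4), ls_lo),
      upper = c(rep(Inf, p), log(1e8), ls_hi),
      control = list(iter.max = 500, eval.max = 2000)
    )
    par_full <- opt$par
    hess <- if (is.null(fix_sigma2)) {
      optimHess(par_full, nll)
    } else {
      # the held variance parameter has no curvature; differentiate only
      # over the free parameters and pad its row/column
      hf <- optimHess(par_full[seq_len(p + 1)], function(q) nll(c(q, ls0)))
      hp <- matrix(NA_real_, p + 2, p + 2)
      hp[seq_len(p + 1), seq_len(p + 1)] <- hf
      hp
    }
    re_var <- exp(2 * par_full[p + 2])
    boundary <- par_full[p + 2] < log(1e-6) + 1e-6
    k <- if (is.null(fix_sigma2)) p + 2 else p + 1
  }
  free <- which(!is.na(hess[, 1]))
  vcov_all <- matrix(NA_real_, length(par_full), length(par_full))
  vcov_all[free, free] <- tryCatch(solve(hess[free, free]), error = function(e) {
    warn("observed information is singular; standard errors unavailable")
    matrix(NA_real_, length(free), length(free))
  })
  se <- sqrt(pmax(diag(vcov_all), 0))[seq_len(p)]
  est <- par_full[seq_len(p)]
  z <- est / se
  coefs <- tibble(
    term = colnames(X), estimate = est, std.error = se,
    statistic = z, p.value = 2 * pnorm(-abs(z))
  )
  ll <- -opt$objective
  theta <- exp(par_full[p + 1])
  # random-intercept modes at the optimum
  if (single_group) {
    re_modes <- setNames(0, levels(gf))
  } else {
    nll(par_full)
    re_modes <- setNames(u_cache, levels(gf))
  }
  structure(
    list(
      coefficients = coefs, theta = theta,
      theta_se = theta * sqrt(pmax(diag(vcov_all), 0))[p + 1],
      re_variance = re_var, re_modes = re_modes,
      loglik = ll, df = k + if (single_group) 0 else 0, n_par = k,
      AIC = 2 * k - 2 * ll,
      converged = opt$convergence == 0, boundary = boundary,
      n_obs = length(y), n_groups = G,
      formula = formula, group = group, quad_points = quad_points,
      X = X, y = y, group_factor = gf, vcov = vcov_all, par = par_full
    ),
    class = "nb_glmm"
  )
}

# unused factor levels would create all-zero (aliased) model-matrix columns
drop_empty_levels <- function(data) {
  for (v in names(data)) {
    if (is.factor(data[[v]])) data[[v]] <- droplevels(data[[v]])
  }
  data
}

check_count_response <- function(y) {
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    abort("response must be non-negative integers (round the motion variance first)")
  }
}

#' Negative-binomial GLM (no random effect)
#'
#' Fixed-effects-only comparison fit, used to test whether the group
#' random intercept is supported by AIC.
#'
#' @inheritParams fit_nb_glmm
#' @return an object of class `nb_glm`.
#' @export
fit_nb_glm <- function(data, formula) {
  data <- drop_empty_levels(data)
  y <- stats::model.response(model.frame(formula, data))
  check_count_response(y)
  fit <- suppressWarnings(MASS::glm.nb(formula, data = data))
  sm <- summary(fit)$coefficients
  structure(
    list(
      coefficients = tibble(
        term = rownames(sm), estimate = unname(sm[, 1]),
        std.error = unname(sm[, 2]), statistic = unname(sm[, 3]),
        p.value = unname(sm[, 4])
      ),
      theta = fit$theta, loglik = as.numeric(logLik(fit)),
      n_par = attr(logLik(fit), "df"),
      AIC = AIC(fit), fitted = fitted(fit), y = y,
      converged = fit$converged, n_obs = length(y), formula = formula,
      glm_fit = fit
    ),
    class = "nb_glm"
  )
}

#' Gamma GLM with log link
#'
#' Comparison fit on the strictly positive (un-rounded) motion variance,
#' used only for the goodness-of-fit contrast against the negative
#' binomial model.
#'
#' @inheritParams fit_nb_glmm
#' @return an object of class `gamma_glm` (includes the estimated shape).
#' @export
fit_gamma_glm <- function(data, formula) {
  data <- drop_empty_levels(data)
  y <- stats::model.response(model.frame(formula, data))
  if (any(y <= 0)) abort("gamma GLM requires a strictly positive response")
  # suppressWarnings: a (near-)perfect fit makes glm's gamma AIC and the
  # ML shape iteration emit NaN warnings before the fallback below
  fit <- suppressWarnings(glm(formula, data = data, family = Gamma(link = "log")))
  shape <- tryCatch(suppressWarnings(MASS::gamma.shape(fit)$alpha),
    error = function(e) {
      disp <- fit$deviance / fit$df.residual
      if (disp <= 0) Inf else 1 / disp
    }
  )
  sm <- if (is.finite(shape)) {
    summary(fit, dispersion = 1 / shape)$coefficients
  } else {
    summary(fit, dispersion = 1e-12)$coefficients
  }
  structure(
    list(
      coefficients = tibble(
        term = rownames(sm), estimate = unname(sm[, 1]),
        std.error = unname(sm[, 2]), statistic = unname(sm[, 3]),
        p.value = unname(sm[, 4])
      ),
      shape = shape, loglik = as.numeric(logLik(fit)),
      AIC = AIC(fit), fitted = fitted(fit), y = y,
      converged = fit$converged, n_obs = length(y), formula = formula,
      glm_fit = fit
    ),
    class = "gamma_glm"
  )
}

ks_distance <- function(obs, sim) {
  pts <- sort(unique(c(obs, sim)))
  max(abs(ecdf(obs)(pts) - ecdf(sim)(pts)))
}

#' Simulation-based goodness of fit
#'
#' Draws `n_sims` response vectors from a fitted model (for the mixed
#' model, group intercepts are redrawn each simulation) and compares the
#' simulated and observed distributions within subsets defined by the
#' levels of categorical predictors (e.g. the season x vegetation
#' combinations).  The summary reports per-group quantiles of observed and
#' simulated values and a per-group Kolmogorov-Smirnov distance; the
#' overall statistic is the size-weighted mean KS distance (smaller is a
#' better fit).
#'
#' @param fit an `nb_glmm`, `nb_glm` or `gamma_glm`.
#' @param data the data frame the model was fit to.
#' @param n_sims number of simulated response vectors.
#' @param groupings character vector of categorical columns in `data`.
#' @param seed RNG seed; a fixed seed gives identical output.
#' @return an object of class `gof_simulation` with elements `sims`
#'   (n_obs x n_sims), `summary`, `gof_stat`.
#' @export
simulate_gof <- function(fit, data, n_sims = 100,
                         groupings = c("season", "vegetation"), seed = 1) {
  set.seed(seed)
  n <- fit$n_obs
  sims <- matrix(numeric(0), nrow = n, ncol = 0)
  if (n_sims > 0) {
    sims <- matrix(NA_real_, n, n_sims)
    for (s in seq_len(n_sims)) {
      sims[, s] <- simulate_response(fit)
    }
  }
  groupings <- intersect(groupings, names(data))
  grp <- if (length(groupings) > 0) {
    interaction(data[groupings], sep = " x ", drop = TRUE)
  } else {
    factor(rep("all", n))
  }
  summary <- NULL
  gof_stat <- NA_real_
  if (n_sims > 0) {
    qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
    summary <- bind_rows(lapply(levels(grp), function(lv) {
      i <- grp == lv
      tibble(
        group = lv, n = sum(i),
        quantile = qs,
        observed = as.numeric(quantile(fit$y[i], qs)),
        simulated = as.numeric(quantile(sims[i, ], qs)),
        ks = ks_distance(fit$y[i], as.vector(sims[i, ]))
      )
    }))
    per_group <- distinct(summary, .data$group, .data$n, .data$ks)
    gof_stat <- sum(per_group$ks * per_group$n) / sum(per_group$n)
  }
  structure(
    list(
      sims = sims, groups = grp, observed = fit$y,
      summary = summary, gof_stat = gof_stat, n_sims = n_sims, seed = seed
    ),
    class = "gof_simulation"
  )
}

simulate_response <- function(fit) {
  if (inherits(fit, "nb_glmm")) {
    u <- rnorm(fit$n_groups, 0, sqrt(fit$re_variance))
    mu <- exp(drop(fit$X %*% fit$coefficients$estimate) +
      u[as.integer(fit$group_factor)])
    rnbinom(fit$n_obs, size = fit$theta, mu = mu)
  } else if (inherits(fit, "nb_glm")) {
    rnbinom(fit$n_obs, size = fit$theta, mu = fit$fitted)
  } else if (inherits(fit, "gamma_glm")) {
    rgamma(fit$n_obs, shape = fit$shape, rate = fit$shape / fit$fitted)
  } else {
    abort("unknown fit class")
  }
}

# canonical presentation order of fixed-effect terms
term_rank <- function(term) {
  pats <- c(
    "^\\(Intercept\\)$", "^log_lion_use", "^dist_tributary", "^dist_river",
    "^dist_boundary", "^dist_road", "^landuse", "^season", "^vegetation",
    "^pups", "^breeding", "^proximity"
  )
  r <- rep(length(pats) + 1, length(term))
  for (k in seq_along(pats)) r[grepl(pats[k], term) & r > length(pats)] <- k
  r
}

#' Formatted coefficient table
#'
#' Coefficient estimates with standard errors, z-scores and p-values,
#' rounded to 3 decimals, ordered canonically (intercept, competitor
#' utilization, distances, protection designation, season, vegetation,
#' reproductive and breeding status, proximity) and flagged (`bold`) where
#' p < 0.01.
#'
#' @param fit a fitted model with a `coefficients` element.
#' @return a tibble with `term`, `estimate`, `se`, `z`, `p`, `bold`.
#' @export
coefficient_table <- function(fit) {
  cf <- fit$coefficients
  cf <- cf[order(term_rank(cf$term)), ]
  tibble(
    term = cf$term,
    estimate = round(cf$estimate, 3),
    se = round(cf$std.error, 3),
    z = round(cf$statistic, 3),
    p = round(cf$p.value, 3),
    bold = cf$p.value < 0.01
  )
}
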