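#' Tidy a fitted movement model
#'
#' @param x an `nb_glmm`, `nb_glm` or `gamma_glm` fit.
#' @param ... unused.
#' @return one row per fixed-effect term with `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.nb_glmm <- function(x, ...) x$coefficients

#' @rdname tidy.nb_glmm
#' @export
tidy.nb_glm <- function(x, ...) x$coefficients

#' @rdname tidy.nb_glmm
#' @export
tidy.gamma_glm <- function(x, ...) x$coefficients

#' One-row model summary
#'
#' @param x an `nb_glmm` or `nb_glm` fit.
#' @param ... unused.
#' @return a one-row tibble with fit statistics.
#' @export
glance.nb_glmm <- function(x, ...) {
  tibble(
    logLik = x$loglik, AIC = x$AIC, theta = x$theta,
    re_variance = x$re_variance, n_obs = x$n_obs, n_groups = x$n_groups,
    converged = x$converged, boundary = x$boundary
  )
}

#' @rdname glance.nb_glmm
#' @export
glance.nb_glm <- function(x, ...) {
  tibble(
    logLik = x$loglik, AIC = x$AIC, theta = x$theta,
    n_obs = x$n_obs, converged = x$converged
  )
}

#' @export
print.nb_glmm <- function(x, ...) {
  cat(sprintf(
    "Negative-binomial mixed model (adaptive Gauss-Hermite, %d nodes)\n",
    x$quad_points
  ))
  cat(sprintf(
    "  %d obs, %d groups; theta = %.3f; random-intercept var = %.4f%s\n",
    x$n_obs, x$n_groups, x$theta, x$re_variance,
    if (x$boundary) " (boundary)" else ""
  ))
  cat(sprintf("  logLik = %.2f, AIC = %.2f%s\n", x$loglik, x$AIC,
    if (!x$converged) "  [NOT CONVERGED]" else ""))
  print(coefficient_table(x), n = Inf)
  invisible(x)
}

#' @export
print.nb_glm <- function(x, ...) {
  cat(sprintf(
    "Negative-binomial GLM: %d obs; theta = %.3f; AIC = %.2f\n",
    x$n_obs, x$theta, x$AIC
  ))
  print(coefficient_table(x), n = Inf)
  invisible(x)
}

#' @export
print.gamma_glm <- function(x, ...) {
  cat(sprintf(
    "Gamma GLM (log link): %d obs; shape = %.3f; AIC = %.2f\n",
    x$n_obs, x$shape, x$AIC
  ))
  print(coefficient_table(x), n = Inf)
  invisible(x)
}

#' @export
print.gof_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulation-based GOF: %d sims, %d groups, weighted KS = %.4f\n",
    x$n_sims, nlevels(x$groups), x$gof_stat
  ))
  invisible(x)
}
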