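#' Brownian bridge density parameters at an intermediate time
#'
#' Conditional distribution of position at time `t` on a Brownian bridge
#' between fixes `p0` (at `t0`) and `p1` (at `t1`) observed with isotropic
#' Gaussian location error `delta`: the mean is the linear interpolation
#' along the chord and the variance (per coordinate) is
#' `T * a * (1 - a) * sigma2 + (1 - a)^2 * delta^2 + a^2 * delta^2` with
#' `a = (t - t0) / (t1 - t0)` and `T = t1 - t0` in seconds.
#'
#' @param p0,p1 numeric length-2 endpoints, meters.
#' @param t0,t1 endpoint times (POSIXct or numeric seconds), `t1 > t0`.
#' @param t evaluation time(s) in `[t0, t1]`.
#' @param sigma2 Brownian motion variance, m^2 s^-1.
#' @param delta location error SD, meters.
#' @return list with `mean` (matrix, one row per `t`) and `var` (vector,
#'   m^2 per coordinate).
#' @export
bridge_density_params <- function(p0, p1, t0, t1, t, sigma2, delta = 1) {
  t0 <- as.numeric(t0); t1 <- as.numeric(t1); t <- as.numeric(t)
  if (t1 <= t0) abort("bridge requires t1 > t0")
  if (any(t < t0 | t > t1)) abort("evaluation time outside [t0, t1]")
  tt <- t1 - t0
  a <- (t - t0) / tt
  m <- cbind(p0[1] + a * (p1[1] - p0[1]), p0[2] + a * (p1[2] - p0[2]))
  v <- tt * a * (1 - a) * sigma2 + ((1 - a)^2 + a^2) * delta^2
  list(mean = m, var = v)
}

# Per-fix leave-one-out statistics for a track run.  Interior fix i is
# scored under the bridge between its neighbours i-1 and i+1:
#   var_i(sigma2) = a_i * sigma2 + c_i,  a_i = T_i * alpha_i * (1 - alpha_i),
#   c_i = ((1 - alpha_i)^2 + alpha_i^2) * delta^2,
#   d2_i = squared distance from fix i to the interpolated bridge mean.
# Valid for i in 2..(n-1); positions 1 and n are NA.
loo_stats <- function(t, x, y, delta) {
  n <- length(t)
  t <- as.numeric(t)
  a <- c2 <- d2 <- rep(NA_real_, n)
  i <- seq(2, n - 1)
  tt <- t[i + 1] - t[i - 1]
  al <- (t[i] - t[i - 1]) / tt
  a[i] <- tt * al * (1 - al)
  c2[i] <- ((1 - al)^2 + al^2) * delta^2
  mx <- x[i - 1] + al * (x[i + 1] - x[i - 1])
  my <- y[i - 1] + al * (y[i + 1] - y[i - 1])
  d2[i] <- (x[i] - mx)^2 + (y[i] - my)^2
  list(a = a, c = c2, d2 = d2)
}

# Leave-one-out term indices for segment [s, e]: s+1, s+3, ... <= e-1.
loo_idx <- function(s, e) seq.int(s + 1, by = 2, length.out = (e - s) %/% 2)

# Batched maximum-likelihood fit of one Brownian motion variance per
# segment.  All segments must have the same term count k; `idx` is an
# (n_seg x k) matrix of indices into the loo_stats vectors.  The likelihood
# is maximized by an iteratively zoomed grid on log10(sigma2); ties break
# toward smaller sigma2.  Returns sigma2, the bivariate-normal log
# likelihood at the optimum, and an at-upper-bound flag.
fit_segments_batch <- function(idx, st, bounds, n_grid = 17, n_zoom = 5) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  a <- matrix(st$a[idx], nrow(idx))
  cc <- matrix(st$c[idx], nrow(idx))
  d2 <- matrix(st$d2[idx], nrow(idx))
  k <- ncol(idx)
  lo0 <- log10(bounds[1]); hi0 <- log10(bounds[2])
  lo <- rep(lo0, nrow(idx)); hi <- rep(hi0, nrow(idx))
  fr <- seq(0, 1, length.out = n_grid)
  ll <- matrix(0, nrow(idx), n_grid)
  best <- numeric(nrow(idx))
  for (it in seq_len(n_zoom)) {
    for (g in seq_len(n_grid)) {
      s2 <- 10^(lo + fr[g] * (hi - lo))
      v <- pmax(a * s2 + cc, 1e-300)
      ll[, g] <- -(rowSums(log(v) + d2 / (2 * v)) + k * log(2 * pi))
    }
    j <- max.col(ll, ties.method = "first")
    ctr <- lo + fr[j] * (hi - lo)
    hw <- (hi - lo) / (n_grid - 1)
    lo <- pmax(lo0, ctr - hw)
    hi <- pmin(hi0, ctr + hw)
    best <- ll[cbind(seq_along(j), j)]
  }
  s2 <- 10^((lo + hi) / 2)
  list(
    sigma2 = s2, loglik = best, n_terms = k,
    at_upper = s2 > bounds[2] * 10^(-2 / (n_grid - 1))
  )
}

#' Static Brownian motion variance by leave-one-out maximum likelihood
#'
#' Estimates a single Brownian motion variance for a track segment: every
#' odd-indexed interior fix is scored under the Brownian bridge density of
#' its two (even-indexed) neighbours, so that no fix helps predict itself,
#' and the product of those bivariate normal densities is maximized over
#' `sigma2` within `bounds` (on the log scale; ties toward smaller values).
#'
#' @param fixes fix table (columns `t`, `x`, `y`) with at least 3 rows.
#' @param delta location error SD, meters.
#' @param bounds `c(min, max)` for sigma2, m^2 s^-1.
#' @return the estimate (m^2 s^-1) with attributes `loglik`, `n_terms` and
#'   `at_upper_bound`; a warning is raised if the optimizer is pinned at the
#'   upper bound.
#' @export
static_sigma2_mle <- function(fixes, delta = 1, bounds = c(1e-10, 1e7)) {
  n <- nrow(fixes)
  if (is.null(n) || n < 3) abort("need at least 3 fixes to estimate sigma2")
  st <- loo_stats(fixes$t, fixes$x, fixes$y, delta)
  fit <- fit_segments_batch(matrix(loo_idx(1, n), nrow = 1), st, bounds)
  if (fit$at_upper) warn("sigma2 estimate pinned at upper bound")
  structure(fit$sigma2,
    loglik = fit$loglik, n_terms = fit$n_terms,
    at_upper_bound = fit$at_upper
  )
}

# Leave-one-out log likelihood of a segment at a given sigma2 (used by the
# model-selection and sanity tests; same terms as static_sigma2_mle).
loo_loglik <- function(fixes, sigma2, delta = 1) {
  st <- loo_stats(fixes$t, fixes$x, fixes$y, delta)
  i <- loo_idx(1, nrow(fixes))
  v <- pmax(st$a[i] * sigma2 + st$c[i], 1e-300)
  sum(-log(2 * pi * v) - st$d2[i] / (2 * v))
}

#' Change-point model selection within one window
#'
#' Fits the candidate motion-variance models for a window of `w`
#' consecutive fixes: a no-break model (one variance for the whole window)
#' and one-break models with the breakpoint at every fix that leaves at
#' least `margin` fixes on each side of it.  All candidates are scored on
#' the same leave-one-out terms (the window's scored fixes at fixed
#' parity): a break at fix `b` only partitions those terms, with the
#' variances of the two sides estimated separately, so the likelihoods are
#' nested and comparable.  Candidates are ranked by BIC (k = 1 or 2
#' variance parameters; sample size = number of leave-one-out terms); the
#' winning model's segment variances are assigned to the window's fixes
#' (the breakpoint fix joins the left segment).
#'
#' @param window_fixes fix table of exactly `w` rows, `w >= 2 * margin + 1`.
#' @param margin minimum number of fixes flanking a breakpoint.
#' @param delta location error SD, meters.
#' @param bounds sigma2 search bounds, m^2 s^-1.
#' @return list with `sigma2` (length-w assignment vector, m^2 s^-1),
#'   `model` (`"no_break"` or the breakpoint position), and `candidates`
#'   (tibble of per-model log likelihood, term count, k and BIC).
#' @export
window_breakpoint_fit <- function(window_fixes, margin, delta = 1,
                                  bounds = c(1e-10, 1e7)) {
  w <- nrow(window_fixes)
  if (w < 2 * margin + 1) abort("window must span at least 2*margin + 1 fixes")
  st <- loo_stats(window_fixes$t, window_fixes$x, window_fixes$y, delta)
  terms <- loo_idx(1, w)
  k <- length(terms)
  full <- fit_segments_batch(matrix(terms, nrow = 1), st, bounds)
  cand <- tibble(
    model = "no_break", breakpoint = NA_integer_,
    loglik = full$loglik, n_terms = k, k = 1
  )
  fits <- list(no_break = list(sigma2 = rep(full$sigma2, w)))
  for (b in break_positions(w, margin)) {
    kl <- sum(terms <= b)
    fl <- fit_segments_batch(matrix(terms[seq_len(kl)], nrow = 1), st, bounds)
    fr <- fit_segments_batch(matrix(terms[seq(kl + 1, k)], nrow = 1), st, bounds)
    cand <- bind_rows(cand, tibble(
      model = sprintf("break_%d", b), breakpoint = b,
      loglik = fl$loglik + fr$loglik, n_terms = k, k = 2
    ))
    fits[[sprintf("break_%d", b)]] <-
      list(sigma2 = c(rep(fl$sigma2, b), rep(fr$sigma2, w - b)))
  }
  cand$bic <- cand$k * log(cand$n_terms) - 2 * cand$loglik
  win <- which.min(cand$bic) # first minimum: ties favour the simpler model
  list(
    sigma2 = fits[[cand$model[win]]]$sigma2,
    model = cand$model[win],
    candidates = cand
  )
}

# admissible breakpoint fixes in a window of w fixes: at least `margin`
# fixes strictly on each side, and at least one leave-one-out term on each
# side of the partition
break_positions <- function(w, margin) {
  b <- seq_len(w)
  terms <- loo_idx(1, w)
  keep <- (b - 1) >= margin & (w - b) >= margin &
    vapply(b, function(bb) sum(terms <= bb) >= 1 && sum(terms > bb) >= 1, logical(1))
  b[keep]
}

#' Time-varying Brownian motion variance along a track (dynamic bridge)
#'
#' Slides a window of `window` fixes one fix at a time along each burst of
#' each track, performs change-point model selection in every window (see
#' [window_breakpoint_fit()]), and averages, for every fix, the variance
#' assignments from all windows that cover it (unweighted mean, margin
#' positions included).  The first and last fix of a burst are covered by
#' exactly one window.
#'
#' @param fixes fix table; processed independently per `group_id` (and
#'   `burst`, if present).  Every burst must have at least `window` fixes.
#' @param window odd window size in fixes (`>= 2 * margin + 1`).
#' @param margin margin size in fixes (`>= 2`).
#' @param delta location error SD, meters.
#' @param time_unit seconds per reporting unit for `sigma2`: 1 reports
#'   m^2 s^-1, 3600 reports m^2 h^-1.
#' @param bounds sigma2 search bounds, m^2 s^-1.
#' @return the fix table with columns `sigma2` (m^2 per `time_unit`) and
#'   `n_windows` appended.
#' @export
dynamic_variance <- function(fixes, window = 15, margin = 5, delta = 1,
                             time_unit = 1, bounds = c(1e-10, 1e7)) {
  stopifnot(margin >= 2, window >= 5)
  if (!"burst" %in% names(fixes)) fixes <- mutate(fixes, burst = 1L)
  fixes |>
    group_by(.data$group_id, .data$burst) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < window) {
        abort(sprintf(
          "burst of %d fixes is shorter than the window (%d); merge bursts or reduce the window",
          nrow(d), window
        ))
      }
      mv <- dynamic_variance_run(d, window, margin, delta, bounds)
      d$sigma2 <- mv$sigma2 * time_unit
      d$n_windows <- mv$n_windows
      d
    }) |>
    ungroup()
}

# Single-burst engine.  Every window shares the same local term layout, so
# the full-window fit and each break partition's left/right fits are run
# as one batched pass over all window positions; per-window BIC selection
# and fix-level averaging then work on the cached fits.
dynamic_variance_run <- function(d, w, m, delta, bounds) {
  n <- nrow(d)
  st <- loo_stats(d$t, d$x, d$y, delta)
  starts <- seq_len(n - w + 1)
  nw <- length(starts)
  terms <- loo_idx(1, w) # local scored-fix positions, shared by all windows
  k <- length(terms)
  idx <- outer(starts - 1, terms, "+")
  breaks <- break_positions(w, m)
  full <- fit_segments_batch(idx, st, bounds)
  bic <- matrix(NA_real_, nw, 1 + length(breaks))
  bic[, 1] <- log(k) - 2 * full$loglik
  s2l <- s2r <- matrix(NA_real_, nw, length(breaks))
  for (j in seq_along(breaks)) {
    kl <- sum(terms <= breaks[j])
    fl <- fit_segments_batch(idx[, seq_len(kl), drop = FALSE], st, bounds)
    fr <- fit_segments_batch(idx[, seq(kl + 1, k), drop = FALSE], st, bounds)
    s2l[, j] <- fl$sigma2
    s2r[, j] <- fr$sigma2
    bic[, j + 1] <- 2 * log(k) - 2 * (fl$loglik + fr$loglik)
  }
  winner <- max.col(-bic, ties.method = "first")
  sums <- counts <- numeric(n)
  for (i in seq_along(starts)) {
    s <- starts[i]
    rng <- s:(s + w - 1)
    if (winner[i] == 1) {
      val <- rep(full$sigma2[i], w)
    } else {
      b <- breaks[winner[i] - 1]
      val <- c(rep(s2l[i, winner[i] - 1], b), rep(s2r[i, winner[i] - 1], w - b))
    }
    sums[rng] <- sums[rng] + val
    counts[rng] <- counts[rng] + 1
  }
  list(sigma2 = sums / counts, n_windows = as.integer(counts))
}
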