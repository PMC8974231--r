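# simulated Brownian-motion track: n fixes, step interval dt seconds,
# true diffusion sigma2 (m^2/s), optional location error added
bm_track <- function(n, sigma2, dt = 43200, seed = 1, group_id = "a",
                     loc_error = 0, t0 = 0) {
  set.seed(seed)
  x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(sigma2 * dt))))
  y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(sigma2 * dt))))
  tibble::tibble(
    group_id = group_id,
    t = t0 + (seq_len(n) - 1) * dt,
    x = x + rnorm(n, 0, loc_error),
    y = y + rnorm(n, 0, loc_error)
  )
}

# piecewise Brownian motion with a diffusion change at fix `at`
bm_track_jump <- function(n, sigma2_a, sigma2_b, at, dt = 43200, seed = 1) {
  set.seed(seed)
  s2 <- c(rep(sigma2_a, at - 1), rep(sigma2_b, n - at))
  x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(s2 * dt))))
  y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(s2 * dt))))
  tibble::tibble(group_id = "a", t = (seq_len(n) - 1) * dt, x = x, y = y)
}

# independent leave-one-out log likelihood, written directly from the
# bridge density definition (oracle for the packaged estimator)
oracle_loo_loglik <- function(fx, sigma2, delta) {
  n <- nrow(fx)
  ll <- 0
  for (i in seq(2, n - 1, by = 2)) {
    tt <- fx$t[i + 1] - fx$t[i - 1]
    a <- (fx$t[i] - fx$t[i - 1]) / tt
    mx <- fx$x[i - 1] + a * (fx$x[i + 1] - fx$x[i - 1])
    my <- fx$y[i - 1] + a * (fx$y[i + 1] - fx$y[i - 1])
    v <- tt * a * (1 - a) * sigma2 + ((1 - a)^2 + a^2) * delta^2
    ll <- ll + dnorm(fx$x[i], mx, sqrt(v), log = TRUE) +
      dnorm(fx$y[i], my, sqrt(v), log = TRUE)
  }
  ll
}

# dense grid-search oracle for the static variance estimator
oracle_grid_argmax <- function(fx, delta, grid = 10^seq(-8, 6, by = 0.01)) {
  ll <- vapply(grid, function(s2) oracle_loo_loglik(fx, s2, delta), numeric(1))
  grid[which.max(ll)]
}

# small fixed toy track used by several estimator tests
toy_track_5 <- function() {
  tibble::tibble(
    group_id = "toy",
    t = c(0, 43200, 86400, 129600, 172800),
    x = c(0, 1200, 1800, 3500, 4100),
    y = c(0, -300, 900, 1500, 2600)
  )
}

# tiny ud_raster built directly from an (nx x ny) value matrix
manual_ud <- function(values, cell = 100, group_id = "g", interval = "2018",
                      normalize = TRUE) {
  g <- riskmove::make_grid(
    0, nrow(values) * cell - cell / 2,
    0, ncol(values) * cell - cell / 2, cell
  )
  if (normalize) values <- values / sum(values)
  riskmove:::new_ud_raster(g, values, group_id, interval)
}
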