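two_fix_track <- function(dx = 4000, dy = 0, dt = 43200) {
  tibble::tibble(
    group_id = "g", t = c(0, dt), x = c(0, dx), y = c(0, dy)
  )
}

test_that("a rasterized bridge is a normalized density on its support", {
  tr <- two_fix_track()
  mv <- tibble::tibble(sigma2 = c(0, 0))
  ud <- rasterize_ud(tr, mv, cell = 200, dt = 600, delta = 1)
  expect_equal(sum(ud$values), 1, tolerance = 1e-9)
  # sigma2 = 0, delta = 1: mass concentrated in the cell rows straddling
  # the chord (y = 0 lies on a cell edge, so two rows share it)
  d <- tidy(ud)
  on_chord <- d$value[abs(d$y) < 201 & d$x > -201 & d$x < 4201]
  expect_gt(sum(on_chord), 0.99)
})

test_that("a symmetric bridge yields a symmetric utilization distribution", {
  tr <- two_fix_track(dx = 3000)
  mv <- tibble::tibble(sigma2 = c(0.5, 0.5))
  ud <- rasterize_ud(tr, mv, cell = 250, dt = 600, delta = 1)
  v <- ud$values
  # reflect about the chord midpoint in x
  mid <- (1500 - ud$grid$x0) / ud$grid$cell
  i <- seq_len(ud$grid$nx)
  mirror <- round(2 * mid - i + 1)
  ok <- mirror >= 1 & mirror <= ud$grid$nx
  expect_lt(max(abs(v[i[ok], ] - v[mirror[ok], ])), 1e-9)
})

test_that("bridge cell masses match a Monte-Carlo oracle", {
  tr <- two_fix_track(dx = 2000, dt = 14400)
  s2 <- 0.3
  mv <- tibble::tibble(sigma2 = c(s2, s2))
  grid <- make_grid(-3000, 5000, -4000, 4000, 500)
  ud <- rasterize_ud(tr, mv, grid = grid, dt = 30, delta = 1)

  set.seed(99)
  n_draw <- 1e6
  tt <- runif(n_draw, 0, 14400)
  a <- tt / 14400
  vv <- 14400 * a * (1 - a) * s2 + ((1 - a)^2 + a^2)
  px <- rnorm(n_draw, a * 2000, sqrt(vv))
  py <- rnorm(n_draw, 0, sqrt(vv))
  ci <- floor((px - grid$x0) / grid$cell) + 1
  ri <- floor((py - grid$y0) / grid$cell) + 1
  mc <- matrix(0, grid$nx, grid$ny)
  keep <- ci >= 1 & ci <= grid$nx & ri >= 1 & ri <= grid$ny
  tabs <- table(factor(ci[keep], levels = 1:grid$nx), factor(ri[keep], levels = 1:grid$ny))
  mc <- tabs / n_draw
  se <- sqrt(mc * (1 - mc) / n_draw)
  dev <- abs(ud$values - mc)
  expect_lt(max(dev / pmax(se, 1e-7)), 3)
})

test_that("rasterize_ud rejects a grid that truncates the bridge", {
  tr <- two_fix_track(dx = 8000)
  mv <- tibble::tibble(sigma2 = c(5, 5))
  small <- make_grid(0, 1000, -500, 500, 250)
  expect_error(
    rasterize_ud(tr, mv, grid = small, dt = 600, delta = 1),
    "grid too small"
  )
})

test_that("isopleths take the smallest highest-density cell set", {
  # uniform distribution over 100 cells: 95% level needs 95 cells
  u <- manual_ud(matrix(1, 10, 10))
  iso <- isopleth_cells(u, 0.95)
  expect_equal(sum(iso$cells), 95)

  # seeded random surface equals the brute-force sort-and-accumulate set
  set.seed(5)
  vals <- matrix(rexp(400), 20, 20)
  u2 <- manual_ud(vals)
  iso2 <- isopleth_cells(u2, 0.95)
  v <- as.vector(u2$values)
  o <- order(v, decreasing = TRUE)
  k <- which(cumsum(v[o]) >= 0.95)[1]
  brute <- v >= v[o[k]]
  expect_equal(as.vector(iso2$cells), brute)

  # nestedness across levels
  for (lv in c(0.2, 0.5, 0.8)) {
    inner <- isopleth_cells(u2, lv)$cells
    outer <- isopleth_cells(u2, 0.95)$cells
    expect_true(all(outer[inner]))
  }
})

test_that("risk surfaces are cell-wise sums of group distributions", {
  set.seed(6)
  u1 <- manual_ud(matrix(rexp(100), 10, 10), group_id = "p1")
  u2 <- manual_ud(matrix(rexp(100), 10, 10), group_id = "p2")
  rs <- build_risk_surface(list(u1, u2), "2018")
  expect_equal(rs$values, u1$values + u2$values)
  expect_equal(rs$contributing_groups, c("p1", "p2"))
  expect_equal(sum(rs$values), 2, tolerance = 1e-9)

  # identical inputs double everywhere; a single input is the identity
  rs2 <- build_risk_surface(list(u1, u1))
  expect_equal(rs2$values, 2 * u1$values)
  expect_equal(build_risk_surface(list(u1))$values, u1$values)

  # disjoint supports: total mass equals the number of groups
  a <- matrix(0, 10, 10); a[1:5, ] <- 1
  b <- matrix(0, 10, 10); b[6:10, ] <- 1
  rs3 <- build_risk_surface(list(manual_ud(a), manual_ud(b)))
  expect_equal(sum(rs3$values), 2, tolerance = 1e-9)

  other <- riskmove:::new_ud_raster(make_grid(0, 500, 0, 500, 50), matrix(1 / 100, 10, 10))
  expect_error(build_risk_surface(list(u1, other)), "shared grid")
})

test_that("study areas merge overlapping isopleths", {
  sq <- function(r1, r2, c1, c2) {
    m <- matrix(FALSE, 20, 20)
    m[r1:r2, c1:c2] <- TRUE
    m
  }
  g <- make_grid(0, 1950, 0, 1950, 100)
  iso <- function(cells) list(grid = g, cells = cells, level = 0.95)

  # overlapping squares merge into one polygon with area < sum of parts
  sa1 <- delineate_study_area(list(iso(sq(1, 10, 1, 10)), iso(sq(6, 15, 6, 15))))
  expect_equal(sa1$n_polygons, 1)
  expect_lt(sum(sa1$cells), 200)

  # disjoint squares stay separate
  sa2 <- delineate_study_area(list(iso(sq(1, 5, 1, 5)), iso(sq(10, 15, 10, 15))))
  expect_equal(sa2$n_polygons, 2)

  # no isopleths: the study area is just the exception zone
  zone <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  sa3 <- delineate_study_area(list(), exceptions = list(zone))
  expect_equal(sa3$n_polygons, 0)
  fx <- tibble::tibble(group_id = "d", t = 1, x = 50, y = 50)
  ff <- filter_fixes(fx, sa3)
  expect_true(ff$included)
  expect_equal(ff$reason, "exception")
})

test_that("fix filtering is boundary-inclusive, labelled and idempotent", {
  g <- make_grid(0, 950, 0, 950, 100)
  cells <- matrix(FALSE, 10, 10)
  cells[3:6, 3:6] <- TRUE # polygon spanning [200,600) x [200,600)
  sa <- delineate_study_area(list(list(grid = g, cells = cells, level = 0.95)))

  fx <- tibble::tibble(
    group_id = "d", t = 1:4,
    x = c(400, 50, 200, 600), # centroid, outside, left edge, right edge
    y = c(400, 50, 400, 400)
  )
  ff <- filter_fixes(fx, sa)
  expect_equal(ff$included, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(ff$reason[2], "outside")

  # idempotent on the included subset; counts partition the input
  inc <- dplyr::filter(ff, included)
  again <- filter_fixes(inc, sa)
  expect_true(all(again$included))
  expect_equal(sum(ff$included) + sum(!ff$included), nrow(fx))
})

test_that("risk extraction uses half-open cell ownership", {
  vals <- matrix(seq_len(100), 10, 10)
  u <- manual_ud(vals, cell = 100, normalize = FALSE)
  # cell centre
  expect_equal(extract_risk(u, 150, 50), vals[2, 1])
  # on a shared edge: the cell starting at the edge owns the point
  expect_equal(extract_risk(u, 100, 50), vals[2, 1])
  expect_equal(extract_risk(u, 99.999, 50), vals[1, 1])
  # constant surface is constant anywhere
  uc <- manual_ud(matrix(4, 10, 10), normalize = FALSE)
  expect_equal(extract_risk(uc, c(10, 500, 910), c(10, 500, 910)), rep(4, 3))
  expect_error(extract_risk(u, 5000, 50), "outside")
})

test_that("isopleth areas are stable under grid and time refinement", {
  # diffusion strong enough that the bridge SD spans several cells
  fx <- bm_track(30, sigma2 = 50, dt = 14400, seed = 77)
  mv <- dynamic_variance(fx, window = 15, margin = 5, delta = 1)
  area <- function(cell, dt) {
    ud <- rasterize_ud(fx, mv, cell = cell, dt = dt, delta = 1)
    isopleth_cells(ud, 0.95)$area
  }
  a1 <- area(200, 1200)
  a2 <- area(100, 600)
  expect_lt(abs(a2 - a1) / a1, 0.05)
})
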