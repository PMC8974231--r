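test_that("proximity classification applies the time window and threshold", {
  dog <- tibble::tibble(
    group_id = "d", t = as.POSIXct("2018-06-01 08:00", tz = "UTC"), x = 0, y = 0
  )
  lion_at <- function(dt_h, dist) {
    tibble::tibble(
      group_id = "p", t = dog$t + dt_h * 3600, x = dist, y = 0
    )
  }
  # competitor 1500 m away within the window
  expect_equal(as.character(classify_proximity(dog, lion_at(2, 1500))$proximity), "near")
  # same distance but outside +/- 3 h: far, flagged as unmatched
  r <- classify_proximity(dog, lion_at(5, 1500))
  expect_equal(as.character(r$proximity), "far")
  expect_true(r$no_match)
  # threshold is inclusive at exactly 2 km
  expect_equal(as.character(classify_proximity(dog, lion_at(0, 2000))$proximity), "near")
  expect_equal(as.character(classify_proximity(dog, lion_at(0, 2000.1))$proximity), "far")
})

test_that("proximity is invariant to competitor fix order and time direction", {
  set.seed(8)
  dog <- tibble::tibble(
    group_id = "d",
    t = as.POSIXct("2018-06-01", tz = "UTC") + seq(0, 86400 * 5, by = 43200),
    x = runif(11, 0, 5000), y = runif(11, 0, 5000)
  )
  lion <- tibble::tibble(
    group_id = "p",
    t = as.POSIXct("2018-06-01", tz = "UTC") + seq(0, 86400 * 5, by = 14400),
    x = runif(31, 0, 5000), y = runif(31, 0, 5000)
  )
  base <- classify_proximity(dog, lion)
  shuf <- classify_proximity(dog, lion[sample(nrow(lion)), ])
  expect_equal(base$proximity, shuf$proximity)
  expect_equal(base$min_dist, shuf$min_dist)
  # reversing the competitor series changes nothing: the window is symmetric
  rev <- classify_proximity(dog, lion[rev(seq_len(nrow(lion))), ])
  expect_equal(base$min_dist, rev$min_dist)
})

test_that("season boundaries match the stated calendar rule", {
  expect_equal(as.character(season_of("2018-12-15")), "wet")
  expect_equal(as.character(season_of("2018-05-01")), "wet")
  expect_equal(as.character(season_of("2018-05-02")), "dry")
  expect_equal(as.character(season_of("2018-08-10")), "dry")
  expect_equal(as.character(season_of("2018-12-01")), "wet")
  expect_equal(as.character(season_of("2018-11-30")), "dry")

  # the rule partitions the calendar; 152 wet days in a non-leap year
  days <- seq(as.Date("2018-01-01"), as.Date("2018-12-31"), by = "day")
  s <- season_of(days)
  expect_false(any(is.na(s)))
  expect_equal(sum(s == "wet"), 152)
})

test_that("feature distances are minimum point-to-segment distances", {
  ns_line <- cbind(c(0, 0), c(-5000, 5000))
  expect_equal(distance_to_features(3000, 0, list(ns_line)), 3000)
  expect_equal(distance_to_features(0, 1000, list(ns_line)), 0)
  # two parallel roads: the nearer one wins
  roads <- list(cbind(c(1000, 1000), c(-5000, 5000)), cbind(c(5000, 5000), c(-5000, 5000)))
  expect_equal(distance_to_features(0, 0, roads), 1000)
  expect_error(distance_to_features(0, 0, list()), "empty feature set")
})

# minimal synthetic inputs for table assembly: one 3x3 study area cell
# block, a constant risk surface, one competitor fix stream
assembly_inputs <- function(rs_values = NULL) {
  g <- make_grid(0, 2950, 0, 2950, 100)
  cells <- matrix(TRUE, 30, 30)
  sa <- delineate_study_area(list(list(grid = g, cells = cells, level = 0.95)))
  vals <- if (is.null(rs_values)) matrix(0.25, 30, 30) else rs_values
  rs <- riskmove:::new_ud_raster(g, vals, "all", "2018",
    class = c("risk_surface", "ud_raster")
  )
  t0 <- as.POSIXct("2018-03-01 08:00", tz = "UTC")
  dog_mv <- tibble::tibble(
    group_id = "pack_a",
    t = t0 + (0:9) * 43200,
    x = seq(500, 2400, length.out = 10), y = seq(500, 2400, length.out = 10),
    sigma2 = c(13000.4, 22000.5, 18000.49, 500.5, 0.4, 7000, 9000.51, 100, 50, 60000)
  )
  lion <- tibble::tibble(
    group_id = "pride", t = t0 + (0:9) * 43200, x = 10000, y = 10000
  )
  landscape <- list(
    park = cbind(c(0, 3000, 3000, 0), c(0, 0, 3000, 3000)),
    gma = cbind(c(-1000, 4000, 4000, -1000), c(-1000, -1000, 4000, 4000)),
    rivers = list(cbind(c(0, 3000), c(2900, 2900))),
    tributaries = list(cbind(c(0, 3000), c(100, 100))),
    roads = list(cbind(c(-500, -500), c(0, 3000))),
    vegetation = list(
      grid = make_grid(0, 2950, 0, 2950, 1000),
      classes = matrix(1L, 3, 3)
    ),
    veg_levels = c("closed", "open_canopy", "grassland")
  )
  list(
    dog_mv = dog_mv, sa = sa, rs = list("2018" = rs),
    intervals = enumerate_intervals("2018-01-01", "2018-12-31", "annual"),
    lion = lion,
    schedules = list(
      breeding = tibble::tibble(
        group_id = "pack_a", start = as.Date("2018-01-01"),
        end = as.Date("2018-12-31"), status = "breeding"
      ),
      pups = tibble::tibble(
        group_id = "pack_a", start = as.Date("2018-06-15"), end = as.Date("2018-12-31")
      )
    ),
    landscape = landscape
  )
}

test_that("the model table carries rounded responses and scaled predictors", {
  ai <- assembly_inputs()
  tab <- assemble_table(
    ai$dog_mv, ai$sa, ai$rs, ai$intervals, ai$lion, ai$schedules, ai$landscape
  )
  expect_equal(nrow(tab), 10)
  # rounding half away from zero
  expect_equal(tab$response[1], 13000L)
  expect_equal(tab$response[2], 22001L)
  expect_equal(tab$response[5], 0L)
  # scaled copies of varying predictors have mean 0, sd 1
  for (v in c("dist_tributary_s", "dist_river_s", "dist_boundary_s", "dist_road_s")) {
    expect_equal(mean(tab[[v]]), 0, tolerance = 1e-9)
    expect_equal(sd(tab[[v]]), 1, tolerance = 1e-9)
  }
  # constant risk surface: log competitor use is log(0.25) everywhere and
  # its scaled copy collapses to zero instead of dividing by sd 0
  expect_equal(unique(tab$log_lion_use), log(0.25))
  expect_equal(unique(tab$log_lion_use_s), 0)
  # no competitor within the window: far, but retained
  expect_true(all(tab$proximity == "far"))
  # pack state follows the schedules (all fixes in March: no pups)
  expect_true(all(tab$pups == "absent"))
  expect_true(all(tab$breeding == "breeding"))
  # distances agree with direct computation
  expect_equal(tab$dist_tributary, abs(ai$dog_mv$y - 100))
})

test_that("non-positive competitor usage errors unless an epsilon is given", {
  vals <- matrix(0.25, 30, 30)
  vals[, 1:15] <- 0 # zero usage below y = 1500 (the track's first half)
  ai <- assembly_inputs(rs_values = vals)
  expect_error(
    assemble_table(ai$dog_mv, ai$sa, ai$rs, ai$intervals, ai$lion, ai$schedules, ai$landscape),
    "epsilon"
  )
  tab <- assemble_table(
    ai$dog_mv, ai$sa, ai$rs, ai$intervals, ai$lion, ai$schedules, ai$landscape,
    epsilon = 1e-6
  )
  expect_equal(sort(unique(tab$log_lion_use)), sort(c(log(1e-6), log(0.25 + 1e-6))))
})

test_that("generalized variance inflation factors match the determinant formula", {
  set.seed(9)
  n <- 200
  d <- tibble::tibble(
    y = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n)
  )
  d$b2 <- d$a * 0.8 + d$b * 0.6 # correlated pair
  g <- gvif(d, y ~ a + b2 + c)
  # independent evaluation straight from the correlation determinants
  X <- as.matrix(d[c("a", "b2", "c")])
  R <- cor(X)
  for (i in 1:3) {
    expect_equal(
      g$gvif[i],
      det(R[i, i, drop = FALSE]) * det(R[-i, -i, drop = FALSE]) / det(R),
      tolerance = 1e-12
    )
  }
  # orthogonal predictors: GVIF of 1
  d2 <- tibble::tibble(y = rnorm(8), a = rep(c(-1, 1), 4), b = rep(c(-1, -1, 1, 1), 2))
  g2 <- gvif(d2, y ~ a + b)
  expect_equal(g2$gvif, c(1, 1), tolerance = 1e-12)

  # duplicated column: rank-deficiency error naming the aliased column
  d$dup <- d$a
  expect_error(gvif(d, y ~ a + dup + c), "aliased.*dup")

  # invariant to linear rescaling of any single column
  d$a10 <- d$a * 10 + 3
  expect_equal(
    gvif(d, y ~ a + b2 + c)$gvif,
    gvif(d, y ~ a10 + b2 + c)$gvif,
    tolerance = 1e-10
  )
})

test_that("multi-column terms agree with the car implementation", {
  skip_if_not_installed("car")
  set.seed(10)
  n <- 300
  d <- data.frame(
    y = rnorm(n),
    a = rnorm(n),
    f = factor(sample(letters[1:4], n, TRUE)),
    b = rnorm(n)
  )
  fit <- stats::lm(y ~ a + f + b, data = d)
  ours <- gvif(d, y ~ a + f + b)
  theirs <- car::vif(fit)
  expect_equal(ours$gvif, unname(theirs[, "GVIF"]), tolerance = 1e-8)
  expect_equal(ours$df, unname(theirs[, "Df"]))
})
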