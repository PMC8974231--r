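#' Classify short-term competitor proximity at focal fixes
#'
#' For every focal (e.g. wild dog) fix, finds the minimum Euclidean
#' distance to any competitor (e.g. lion) fix recorded within a time window
#' of total width `2 * half_window` hours centred on the focal fix, and
#' classifies the fix as `near` (min distance <= `threshold`, boundary
#' inclusive) or `far`.  Focal fixes with no competitor fix in the window
#' are classified `far` with a `no_match` flag, since far is the model's
#' reference state.
#'
#' @param dog_fixes focal fix table (`t`, `x`, `y`).
#' @param lion_fixes competitor fix table (`t`, `x`, `y`), any order.
#' @param half_window half width of the matching window, hours.
#' @param threshold near/far distance threshold, meters.
#' @return tibble with `proximity` (factor, reference `far`), `min_dist`
#'   (m, `NA` if no match), `matched_t` (time of closest competitor fix)
#'   and `no_match`.
#' @export
classify_proximity <- function(dog_fixes, lion_fixes, half_window = 3,
                               threshold = 2000) {
  lion <- arrange(as_tibble(lion_fixes), .data$t)
  lt <- as.numeric(lion$t)
  dtt <- as.numeric(dog_fixes$t)
  w <- half_window * 3600
  lo <- findInterval(dtt - w, lt, left.open = TRUE) + 1
  hi <- findInterval(dtt + w, lt)
  n <- length(dtt)
  min_dist <- rep(NA_real_, n)
  matched <- as.POSIXct(rep(NA_real_, n), origin = "1970-01-01", tz = "UTC")
  for (i in seq_len(n)) {
    if (lo[i] > hi[i]) next
    idx <- lo[i]:hi[i]
    dd <- sqrt((lion$x[idx] - dog_fixes$x[i])^2 + (lion$y[idx] - dog_fixes$y[i])^2)
    j <- which.min(dd)
    min_dist[i] <- dd[j]
    matched[i] <- lion$t[idx[j]]
  }
  no_match <- is.na(min_dist)
  tibble(
    proximity = factor(
      ifelse(!no_match & min_dist <= threshold, "near", "far"),
      levels = c("far", "near")
    ),
    min_dist = min_dist, matched_t = matched, no_match = no_match
  )
}

#' Season of a date
#'
#' Wet season runs December 1 through May 1 (both inclusive, wrapping the
#' year end); May 2 through November 30 is dry.
#'
#' @param d Date vector (or coercible).
#' @return factor with levels `dry` (reference), `wet`.
#' @export
season_of <- function(d) {
  d <- as.Date(d)
  m <- as.integer(format(d, "%m"))
  day <- as.integer(format(d, "%d"))
  wet <- m == 12 | m <= 4 | (m == 5 & day == 1)
  factor(ifelse(wet, "wet", "dry"), levels = c("dry", "wet"))
}

#' Minimum distance from points to a set of line or polygon features
#'
#' Minimum Euclidean distance from each point to any segment of any
#' feature.  Features are two-column vertex matrices (polylines); pass a
#' closed ring to measure distance to a polygon's boundary line (the
#' convention used for "distance to the park boundary").  Points on a
#' feature have distance 0.
#'
#' @param x,y point coordinates, meters.
#' @param features list of two-column matrices (vertices in order).
#' @return numeric vector of distances, meters.
#' @export
distance_to_features <- function(x, y, features) {
  if (length(features) == 0) abort("empty feature set")
  best <- rep(Inf, length(x))
  for (f in features) {
    f <- as.matrix(f)
    for (s in seq_len(nrow(f) - 1)) {
      x1 <- f[s, 1]; y1 <- f[s, 2]; x2 <- f[s + 1, 1]; y2 <- f[s + 1, 2]
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      tt <- if (len2 > 0) pmax(0, pmin(1, ((x - x1) * dx + (y - y1) * dy) / len2)) else 0
      d2 <- (x - (x1 + tt * dx))^2 + (y - (y1 + tt * dy))^2
      best <- pmin(best, d2)
    }
  }
  sqrt(best)
}

# close a polygon matrix into a ring (first vertex repeated)
close_ring <- function(poly) {
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  poly
}

# land-use class of points given a landscape (park polygon nested in a GMA
# polygon, unprotected outside); boundary points take the inner class
landuse_of <- function(x, y, landscape) {
  in_park <- point_in_polygon(x, y, landscape$park)
  in_gma <- point_in_polygon(x, y, landscape$gma)
  factor(
    ifelse(in_park, "NP", ifelse(in_gma, "GMA", "unprotected")),
    levels = c("GMA", "NP", "unprotected")
  )
}

# vegetation class of points from the integer-coded class raster
vegetation_of <- function(x, y, landscape) {
  vg <- landscape$vegetation
  ci <- pmin(pmax(cell_col(vg$grid, x), 1), vg$grid$nx)
  ri <- pmin(pmax(cell_row(vg$grid, y), 1), vg$grid$ny)
  factor(landscape$veg_levels[vg$classes[cbind(ci, ri)]],
    levels = landscape$veg_levels
  )
}

# schedule lookup: status ranges per group; default when no range covers d
schedule_status <- function(group_id, d, ranges, default) {
  d <- as.Date(d)
  out <- rep(default, length(d))
  if (!is.null(ranges) && nrow(ranges) > 0) {
    for (r in seq_len(nrow(ranges))) {
      hit <- group_id == ranges$group_id[r] &
        d >= as.Date(ranges$start[r]) & d <= as.Date(ranges$end[r])
      out[hit] <- ranges$status[r]
    }
  }
  out
}

#' Assemble the per-fix model table
#'
#' Builds one row per included focal fix: the integer response (motion
#' variance rounded half away from zero), extracted long-term competitor
#' usage and its natural log, the near/far proximity class, season,
#' reproductive covariates, land-use and vegetation classes, distances to
#' landscape features, and centred/scaled copies (`*_s`) of all continuous
#' predictors (computed on the assembled table).
#'
#' @param dog_mv focal fix table with `sigma2` (from [dynamic_variance()]).
#' @param study_area a [delineate_study_area()] result; fixes outside it
#'   (and outside exception zones) are dropped.
#' @param risk_surfaces named list of `risk_surface` objects, one per
#'   interval label.
#' @param intervals interval table from [enumerate_intervals()].
#' @param lion_fixes competitor fixes for proximity classification.
#' @param schedules list with elements `breeding` (columns `group_id`,
#'   `start`, `end`, `status` in `breeding`/`non_breeding`) and `pups`
#'   (columns `group_id`, `start`, `end`; presence ranges).
#' @param landscape landscape list (park/gma polygons, rivers, tributaries,
#'   roads, vegetation raster) as produced by [simulate_landscape()].
#' @param half_window,threshold proximity parameters, see
#'   [classify_proximity()].
#' @param epsilon optional positive offset for `log(lion_use + epsilon)`;
#'   by default a non-positive extracted usage raises an error.
#' @return tibble of model rows (reference levels: land use GMA, closed
#'   vegetation, dry season, pups absent, breeding, proximity far).
#' @export
assemble_table <- function(dog_mv, study_area, risk_surfaces, intervals,
                           lion_fixes, schedules, landscape,
                           half_window = 3, threshold = 2000,
                           epsilon = NULL) {
  d <- filter_fixes(dog_mv, study_area)
  d <- filter(d, .data$included)
  if (nrow(d) == 0) abort("no focal fixes inside the study area")
  dd <- as.Date(d$t)
  d$interval <- NA_character_
  for (i in seq_len(nrow(intervals))) {
    hit <- dd >= intervals$start[i] & dd <= intervals$end[i]
    d$interval[hit] <- intervals$label[i]
  }
  d <- filter(d, !is.na(.data$interval))
  missing_rs <- setdiff(unique(d$interval), names(risk_surfaces))
  if (length(missing_rs) > 0) {
    abort(sprintf("no risk surface for interval(s): %s",
                  paste(missing_rs, collapse = ", ")))
  }
  d$lion_use <- NA_real_
  for (lab in unique(d$interval)) {
    sel <- d$interval == lab
    d$lion_use[sel] <- extract_risk(risk_surfaces[[lab]], d$x[sel], d$y[sel])
  }
  if (any(d$lion_use <= 0)) {
    if (is.null(epsilon)) {
      abort(sprintf(
        "%d fix(es) have non-positive competitor usage; set `epsilon` to use log(use + epsilon)",
        sum(d$lion_use <= 0)
      ))
    }
    d$log_lion_use <- log(d$lion_use + epsilon)
  } else {
    d$log_lion_use <- log(d$lion_use)
  }
  prox <- classify_proximity(d, lion_fixes, half_window, threshold)
  d <- bind_cols(d, prox)
  d$season <- season_of(d$t)
  d$breeding <- factor(
    schedule_status(d$group_id, d$t, schedules$breeding, "breeding"),
    levels = c("breeding", "non_breeding")
  )
  pup_ranges <- schedules$pups
  if (!is.null(pup_ranges) && nrow(pup_ranges) > 0) pup_ranges$status <- "present"
  d$pups <- factor(
    schedule_status(d$group_id, d$t, pup_ranges, "absent"),
    levels = c("absent", "present")
  )
  d$landuse <- landuse_of(d$x, d$y, landscape)
  d$vegetation <- vegetation_of(d$x, d$y, landscape)
  d$dist_tributary <- distance_to_features(d$x, d$y, landscape$tributaries)
  d$dist_river <- distance_to_features(d$x, d$y, landscape$rivers)
  d$dist_boundary <- distance_to_features(d$x, d$y, list(close_ring(landscape$park)))
  d$dist_road <- distance_to_features(d$x, d$y, landscape$roads)
  d$response <- as.integer(round_half_up(d$sigma2))
  cont <- c("log_lion_use", "dist_tributary", "dist_river", "dist_boundary", "dist_road")
  for (v in cont) {
    s <- sd(d[[v]])
    # a constant predictor is centred to zero rather than divided by sd 0
    d[[paste0(v, "_s")]] <- if (s > 0) (d[[v]] - mean(d[[v]])) / s else d[[v]] * 0
  }
  d
}

#' Generalized variance inflation factors
#'
#' Collinearity diagnostic valid for multi-column (categorical) terms:
#' for each term, `GVIF = det(R11) * det(R22) / det(R)` where `R` is the
#' correlation matrix of all fixed-effect columns (intercept excluded),
#' `R11` the block for the term's columns and `R22` for the rest.
#' `GVIF^(1/(2*df))` is also reported for comparability across terms.
#'
#' @param data model data frame.
#' @param formula fixed-effects formula (the response is ignored).
#' @return tibble with `term`, `df`, `gvif`, `gvif_adj`.
#' @export
gvif <- function(data, formula) {
  data <- drop_empty_levels(data)
  mf <- model.frame(formula, data)
  mm <- model.matrix(formula, mf)
  assign <- attr(mm, "assign")
  keep <- assign != 0
  X <- mm[, keep, drop = FALSE]
  assign <- assign[keep]
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1) {
    aliased <- colnames(cbind(1, X))[qx$pivot[seq(qx$rank + 1, ncol(X) + 1)]]
    abort(sprintf("rank-deficient model matrix; aliased columns: %s",
                  paste(aliased, collapse = ", ")))
  }
  labs <- attr(terms(formula, data = data), "term.labels")
  R <- cor(X)
  detR <- det(R)
  out <- lapply(unique(assign), function(a) {
    i <- which(assign == a)
    g <- det(R[i, i, drop = FALSE]) * det(R[-i, -i, drop = FALSE]) / detR
    tibble(term = labs[a], df = length(i), gvif = g,
           gvif_adj = g^(1 / (2 * length(i))))
  })
  bind_rows(out)
}
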