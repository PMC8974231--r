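#' Read GPS telemetry tracks from a delimited file
#'
#' Reads a CSV of GPS fixes (columns `id`, `timestamp`, `x`, `y`, all
#' coordinates in a projected metric system), validates it, and returns a
#' tidy fix table ordered by time within each group.  Timestamps are parsed
#' as UTC; local fix times are treated as metadata only.  If the file
#' carries `lon`/`lat` columns instead of `x`/`y`, supply `origin` to
#' project onto a local tangent plane in meters.
#'
#' @param path path to a delimited text file.
#' @param species label attached to every fix, e.g. `"dog"` or `"lion"`.
#' @param loc_error GPS location error in meters (must be positive);
#'   recorded in the `loc_error` column and used downstream as the bridge
#'   location-error standard deviation.
#' @param origin optional `c(lon, lat)` used to project geographic input.
#' @return a tibble with columns `group_id`, `species`, `t` (POSIXct, UTC),
#'   `x`, `y`, `loc_error`, sorted by time within group.
#' @export
read_tracks <- function(path, species = "dog", loc_error = 1, origin = NULL) {
  stopifnot(is.numeric(loc_error), loc_error > 0)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("id", "timestamp") %in% names(raw))) {
    abort("track file must have columns id, timestamp and x,y (or lon,lat)")
  }
  if (all(c("lon", "lat") %in% names(raw)) && !all(c("x", "y") %in% names(raw))) {
    if (is.null(origin)) abort("geographic input (lon/lat) requires `origin`")
    xy <- project_lonlat(raw$lon, raw$lat, origin)
    raw$x <- xy$x
    raw$y <- xy$y
  }
  if (!all(c("x", "y") %in% names(raw))) {
    abort("track file must have columns x,y (projected meters) or lon,lat")
  }
  fixes <- tibble(
    group_id = as.character(raw$id),
    species = species,
    t = as.POSIXct(raw$timestamp, tz = "UTC"),
    x = as.numeric(raw$x),
    y = as.numeric(raw$y),
    loc_error = loc_error
  )
  validate_tracks(fixes)
}

#' Validate and order a fix table
#'
#' Sorts fixes by time within group, checks coordinates are finite and
#' rejects duplicated timestamps within a group.
#'
#' @param fixes a fix table with columns `group_id`, `t`, `x`, `y`.
#' @return the sorted tibble.
#' @export
validate_tracks <- function(fixes) {
  stopifnot(all(c("group_id", "t", "x", "y") %in% names(fixes)))
  if (any(!is.finite(fixes$x)) || any(!is.finite(fixes$y))) {
    abort("non-finite coordinates in fix table")
  }
  fixes <- arrange(as_tibble(fixes), .data$group_id, .data$t)
  dup <- fixes |>
    group_by(.data$group_id) |>
    filter(duplicated(.data$t)) |>
    ungroup()
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicated timestamp for group '%s' at %s",
      dup$group_id[1], format(dup$t[1], tz = "UTC", usetz = TRUE)
    ))
  }
  fixes
}

#' Write a fix table back to CSV
#'
#' Inverse of [read_tracks()]: ids, timestamps (to the second, ISO-8601 UTC)
#' and coordinates (to 0.01 m) survive a round trip.  A `burst` column, if
#' present, is preserved.
#'
#' @param fixes fix table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(fixes, path) {
  out <- tibble(
    id = fixes$group_id,
    timestamp = format(fixes$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x = round(fixes$x, 2),
    y = round(fixes$y, 2)
  )
  if ("burst" %in% names(fixes)) out$burst <- fixes$burst
  readr::write_csv(out, path)
  invisible(path)
}

# local tangent-plane projection of lon/lat (degrees) to meters about origin
project_lonlat <- function(lon, lat, origin) {
  r_earth <- 6378137
  to_rad <- pi / 180
  list(
    x = r_earth * cos(origin[2] * to_rad) * (lon - origin[1]) * to_rad,
    y = r_earth * (lat - origin[2]) * to_rad
  )
}

#' Partition tracks into bursts at large time gaps
#'
#' Splits each group's fix sequence wherever consecutive fixes are separated
#' by more than `max_gap` hours, so that Brownian bridges are never fit
#' across long collar gaps.  Bursts with fewer than 2 fixes are dropped
#' (counted in the `n_dropped` attribute and reported via a message).
#'
#' @param fixes fix table (see [read_tracks()]).
#' @param max_gap maximum within-burst gap, hours.  The default 36 h
#'   corresponds to three missed twice-daily fixes.
#' @param quiet suppress the dropped-fix message.
#' @return the fix table with an integer `burst` column (unique within
#'   group), singleton bursts removed.
#' @export
split_bursts <- function(fixes, max_gap = 36, quiet = FALSE) {
  stopifnot(max_gap > 0)
  fixes <- validate_tracks(fixes)
  out <- fixes |>
    group_by(.data$group_id) |>
    mutate(
      gap_h = c(0, diff(as.numeric(.data$t)) / 3600),
      burst = cumsum(.data$gap_h > max_gap)
    ) |>
    group_by(.data$group_id, .data$burst) |>
    mutate(.burst_n = n()) |>
    ungroup()
  n_dropped <- sum(out$.burst_n < 2)
  out <- out |>
    filter(.data$.burst_n >= 2) |>
    select(-"gap_h", -".burst_n") |>
    group_by(.data$group_id) |>
    mutate(burst = match(.data$burst, unique(.data$burst))) |>
    ungroup()
  if (n_dropped > 0 && !quiet) {
    inform(sprintf("split_bursts: dropped %d singleton fix(es)", n_dropped))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Enumerate calendar-aligned aggregation intervals
#'
#' Lists every whole calendar year (`scale = "annual"`) or calendar half
#' (`scale = "semiannual"`; Jan 1 - Jun 30 and Jul 1 - Dec 31) fully
#' contained in a deployment period.  These are the intervals over which
#' competitor space-use rasters are aggregated.
#'
#' @param deploy_start,deploy_end Date (or coercible) deployment bounds.
#' @param scale `"annual"` or `"semiannual"`.
#' @return tibble with columns `label`, `start`, `end`, `scale`, ascending.
#' @export
enumerate_intervals <- function(deploy_start, deploy_end,
                                scale = c("annual", "semiannual")) {
  scale <- match.arg(scale)
  deploy_start <- as.Date(deploy_start)
  deploy_end <- as.Date(deploy_end)
  stopifnot(deploy_start <= deploy_end)
  y0 <- as.integer(format(deploy_start, "%Y"))
  y1 <- as.integer(format(deploy_end, "%Y"))
  out <- list()
  for (y in y0:y1) {
    if (scale == "annual") {
      cand <- tibble(
        label = as.character(y),
        start = as.Date(sprintf("%d-01-01", y)),
        end = as.Date(sprintf("%d-12-31", y))
      )
    } else {
      cand <- tibble(
        label = c(sprintf("%dH1", y), sprintf("%dH2", y)),
        start = as.Date(c(sprintf("%d-01-01", y), sprintf("%d-07-01", y))),
        end = as.Date(c(sprintf("%d-06-30", y), sprintf("%d-12-31", y)))
      )
    }
    out[[length(out) + 1]] <- cand
  }
  out <- bind_rows(out) |>
    filter(.data$start >= deploy_start, .data$end <= deploy_end) |>
    mutate(scale = scale)
  out
}

#' Convert a time span to a location count at a fixed sampling interval
#'
#' Fence-post conversion used to translate biologically motivated margin and
#' window durations into location counts for the dynamic bridge model: a
#' span of `duration_hours` sampled every `fix_interval_hours` covers
#' `duration/interval + 1` locations.  A 48-h margin and one-week window at
#' twice-daily (12-h) sampling give 5 and 15 locations.
#'
#' @param duration_hours span in hours.
#' @param fix_interval_hours sampling interval in hours.
#' @return integer location count.
#' @export
duration_to_locations <- function(duration_hours, fix_interval_hours) {
  stopifnot(duration_hours > 0, fix_interval_hours > 0)
  as.integer(floor(duration_hours / fix_interval_hours) + 1)
}
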