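#' Regular analysis grid
#'
#' A planar grid of square cells in projected meters.  Cell ownership is
#' half-open: a point belongs to the cell whose interval
#' `[x0 + (i-1)*cell, x0 + i*cell)` contains it (and likewise in y).
#'
#' @param xmin,xmax,ymin,ymax extent to cover, meters.
#' @param cell cell side, meters.
#' @return an object of class `rm_grid` with fields `x0`, `y0`, `cell`,
#'   `nx`, `ny`.
#' @export
make_grid <- function(xmin, xmax, ymin, ymax, cell = 500) {
  stopifnot(cell > 0, xmax > xmin, ymax > ymin)
  x0 <- floor(xmin / cell) * cell
  y0 <- floor(ymin / cell) * cell
  structure(
    list(
      x0 = x0, y0 = y0, cell = cell,
      nx = ceiling((xmax - x0) / cell),
      ny = ceiling((ymax - y0) / cell)
    ),
    class = "rm_grid"
  )
}

# half-open cell column/row of points; 0 or n+1 when outside the extent
cell_col <- function(grid, x) floor((x - grid$x0) / grid$cell) + 1
cell_row <- function(grid, y) floor((y - grid$y0) / grid$cell) + 1

same_grid <- function(a, b, tol = 1e-6) {
  abs(a$x0 - b$x0) < tol && abs(a$y0 - b$y0) < tol &&
    abs(a$cell - b$cell) < tol && a$nx == b$nx && a$ny == b$ny
}

new_ud_raster <- function(grid, values, group_id = NA_character_,
                          interval = NA_character_, class = "ud_raster") {
  structure(
    list(grid = grid, values = values, group_id = group_id, interval = interval),
    class = class
  )
}

#' @export
print.ud_raster <- function(x, ...) {
  cat(sprintf(
    "<%s> %s / %s: %d x %d cells of %g m, total mass %.6f\n",
    class(x)[1], x$group_id, x$interval, x$grid$nx, x$grid$ny,
    x$grid$cell, sum(x$values)
  ))
  invisible(x)
}

#' Tidy a utilization or risk raster into a cell table
#'
#' @param x a `ud_raster` or `risk_surface`.
#' @param ... unused.
#' @return tibble with cell-centre coordinates and values.
#' @export
tidy.ud_raster <- function(x, ...) {
  g <- x$grid
  vals <- as.vector(x$values)
  tibble(
    x = g$x0 + (rep(seq_len(g$nx), g$ny) - 0.5) * g$cell,
    y = g$y0 + (rep(seq_len(g$ny), each = g$nx) - 0.5) * g$cell,
    value = vals
  )
}

#' Rasterize a track into a utilization distribution
#'
#' Accumulates the Brownian bridge occupancy density of every consecutive
#' fix pair (within a burst) on a grid.  Each segment's diffusion is the
#' mean of the two endpoint motion variances; the bridge density is
#' evaluated at uniformly spaced times (approximately `dt` apart, weighted
#' by the time step), integrated exactly over cells via normal CDF
#' differences, and the final raster is normalized to total mass 1.
#'
#' @param fixes fix table for one group (columns `t`, `x`, `y`, optional
#'   `burst`).
#' @param mv motion-variance table aligned with `fixes` (column `sigma2`,
#'   m^2 per `time_unit`), e.g. from [dynamic_variance()].
#' @param grid an [make_grid()] grid, or `NULL` to build one covering the
#'   track plus 3 predictive standard deviations.
#' @param cell cell size in meters when `grid` is `NULL`.
#' @param dt nominal time step of the bridge evaluation, seconds.
#' @param delta location error SD, meters.
#' @param time_unit seconds per unit of `mv$sigma2`.
#' @param group_id,interval labels stored on the result.
#' @return a `ud_raster` whose values sum to 1.
#' @export
rasterize_ud <- function(fixes, mv, grid = NULL, cell = 500, dt = 300,
                         delta = 1, time_unit = 1,
                         group_id = fixes$group_id[1],
                         interval = NA_character_) {
  stopifnot(dt > 0, nrow(fixes) == nrow(mv) || nrow(fixes) == length(mv))
  s2 <- (if (is.numeric(mv)) mv else mv$sigma2) / time_unit # back to m^2/s
  if (!"burst" %in% names(fixes)) fixes$burst <- 1L
  tnum <- as.numeric(fixes$t)
  n <- nrow(fixes)
  seg <- which(fixes$burst[-n] == fixes$burst[-1] &
    fixes$group_id[-n] == fixes$group_id[-1])
  if (length(seg) == 0) abort("no bridge segments (need >= 2 fixes per burst)")
  seg_T <- tnum[seg + 1] - tnum[seg]
  seg_s2 <- (s2[seg] + s2[seg + 1]) / 2
  max_sd <- sqrt(max(seg_T * 0.25 * seg_s2 + delta^2))
  if (is.null(grid)) {
    pad <- 3 * max_sd + cell
    grid <- make_grid(
      min(fixes$x) - pad, max(fixes$x) + pad,
      min(fixes$y) - pad, max(fixes$y) + pad, cell
    )
  }
  g <- grid
  xedge <- g$x0 + (0:g$nx) * g$cell
  yedge <- g$y0 + (0:g$ny) * g$cell
  vals <- matrix(0, g$nx, g$ny)
  total_w <- 0
  for (j in seq_along(seg)) {
    i <- seg[j]
    tt <- seg_T[j]
    npts <- max(1L, as.integer(round(tt / dt)))
    wt <- tt / npts
    al <- (seq_len(npts) - 0.5) / npts
    mx <- fixes$x[i] + al * (fixes$x[i + 1] - fixes$x[i])
    my <- fixes$y[i] + al * (fixes$y[i + 1] - fixes$y[i])
    vv <- tt * al * (1 - al) * seg_s2[j] + ((1 - al)^2 + al^2) * delta^2
    sdv <- sqrt(vv)
    for (p in seq_len(npts)) {
      r <- 6 * sdv[p]
      c1 <- max(1L, cell_col(g, mx[p] - r)); c2 <- min(g$nx, cell_col(g, mx[p] + r))
      r1 <- max(1L, cell_row(g, my[p] - r)); r2 <- min(g$ny, cell_row(g, my[p] + r))
      if (c1 > c2 || r1 > r2) next
      px <- diff(pnorm(xedge[c1:(c2 + 1)], mx[p], sdv[p]))
      py <- diff(pnorm(yedge[r1:(r2 + 1)], my[p], sdv[p]))
      vals[c1:c2, r1:r2] <- vals[c1:c2, r1:r2] + outer(px, py) * wt
    }
    total_w <- total_w + tt
  }
  inside <- sum(vals) / total_w
  if (1 - inside >= 1e-3) {
    abort(sprintf(
      "grid too small: %.2f%% of bridge mass falls outside; extend to at least [%g, %g] x [%g, %g]",
      100 * (1 - inside),
      min(fixes$x) - 3 * max_sd, max(fixes$x) + 3 * max_sd,
      min(fixes$y) - 3 * max_sd, max(fixes$y) + 3 * max_sd
    ))
  }
  new_ud_raster(g, vals / sum(vals), group_id, interval)
}

#' Highest-density isopleth of a utilization distribution
#'
#' Returns the smallest set of highest-value cells whose cumulative
#' probability reaches `level` (ties beyond the required mass are resolved
#' by cell order, keeping the set minimal).  The isopleth polygon is the (implicit) dissolved union of the
#' selected cell rectangles, so membership tests agree exactly with the
#' probability accounting.
#'
#' @param ud a `ud_raster`.
#' @param level coverage fraction in (0, 1), e.g. 0.95.
#' @return list with `grid`, logical matrix `cells`, `level`, the realized
#'   `coverage` and `area` (m^2).
#' @export
isopleth_cells <- function(ud, level = 0.95) {
  stopifnot(level > 0, level < 1)
  v <- as.vector(ud$values)
  o <- order(v, decreasing = TRUE) # stable: ties resolved by cell index
  cs <- cumsum(v[o])
  kmin <- which(cs >= level - 1e-12)[1]
  cells <- matrix(FALSE, ud$grid$nx, ud$grid$ny)
  cells[o[seq_len(kmin)]] <- TRUE
  cells <- cells & ud$values > 0
  list(
    grid = ud$grid, cells = cells, level = level,
    coverage = sum(v[cells]), area = sum(cells) * ud$grid$cell^2
  )
}

#' Sum group utilization rasters into an encounter-risk surface
#'
#' Cell-wise sum of the utilization distributions of all monitored
#' competitor groups over one aggregation interval; the resulting surface
#' is the long-term usage intensity extracted at focal-animal fixes.
#'
#' @param uds list of `ud_raster` objects on one shared grid.
#' @param interval interval label for the surface.
#' @return a `risk_surface` (subclass of `ud_raster`) with
#'   `contributing_groups` recorded.
#' @export
build_risk_surface <- function(uds, interval = NA_character_) {
  stopifnot(length(uds) >= 1)
  g <- uds[[1]]$grid
  for (u in uds[-1]) {
    if (!same_grid(g, u$grid)) abort("utilization rasters are not on a shared grid")
  }
  vals <- Reduce(`+`, lapply(uds, function(u) u$values))
  out <- new_ud_raster(g, vals,
    group_id = "all", interval = interval,
    class = c("risk_surface", "ud_raster")
  )
  out$contributing_groups <- vapply(uds, function(u) u$group_id, character(1))
  out
}

#' Delineate the study area from competitor isopleths
#'
#' Merges the (cell-based) isopleths of all monitored competitor groups
#' into a study area within which competitor space use is well described,
#' plus optional exception zones (well-monitored competitor-free areas)
#' kept as separate admissible polygons.
#'
#' @param isopleths list of [isopleth_cells()] results on one shared grid.
#' @param exceptions list of polygons (two-column vertex matrices, meters).
#' @return a `study_area` with the merged cell mask, the number of
#'   connected polygons, and the exception zones.
#' @export
delineate_study_area <- function(isopleths, exceptions = list()) {
  if (length(isopleths) == 0) {
    return(structure(
      list(grid = NULL, cells = NULL, n_polygons = 0, exceptions = exceptions),
      class = "study_area"
    ))
  }
  g <- isopleths[[1]]$grid
  for (ip in isopleths[-1]) {
    if (!same_grid(g, ip$grid)) abort("isopleths are not on a shared grid")
  }
  cells <- Reduce(`|`, lapply(isopleths, function(ip) ip$cells))
  structure(
    list(
      grid = g, cells = cells,
      n_polygons = count_components(cells),
      exceptions = exceptions
    ),
    class = "study_area"
  )
}

# 4-neighbour connected components of a logical matrix (flood fill)
count_components <- function(cells) {
  lab <- matrix(0L, nrow(cells), ncol(cells))
  comp <- 0L
  for (j in seq_len(ncol(cells))) {
    for (i in seq_len(nrow(cells))) {
      if (cells[i, j] && lab[i, j] == 0L) {
        comp <- comp + 1L
        stack <- list(c(i, j))
        while (length(stack) > 0) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          if (p[1] < 1 || p[2] < 1 || p[1] > nrow(cells) || p[2] > ncol(cells)) next
          if (!cells[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
          lab[p[1], p[2]] <- comp
          stack <- c(stack, list(
            c(p[1] - 1, p[2]), c(p[1] + 1, p[2]),
            c(p[1], p[2] - 1), c(p[1], p[2] + 1)
          ))
        }
      }
    }
  }
  comp
}

# point-in-polygon (even-odd ray casting), boundary-inclusive within tol
point_in_polygon <- function(px, py, poly, tol = 1e-9) {
  nx <- nrow(poly)
  vx <- poly[, 1]; vy <- poly[, 2]
  out <- logical(length(px))
  for (p in seq_along(px)) {
    x <- px[p]; y <- py[p]
    inside <- FALSE
    on_edge <- FALSE
    j <- nx
    for (i in seq_len(nx)) {
      xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
      # boundary test: point within tol of segment i-j
      dx <- xj - xi; dy <- yj - yi
      len2 <- dx * dx + dy * dy
      tt <- if (len2 > 0) max(0, min(1, ((x - xi) * dx + (y - yi) * dy) / len2)) else 0
      if ((x - (xi + tt * dx))^2 + (y - (yi + tt * dy))^2 <= tol^2 + tol * sqrt(len2)) {
        on_edge <- TRUE
        break
      }
      if ((yi > y) != (yj > y) && x < (xj - xi) * (y - yi) / (yj - yi) + xi) {
        inside <- !inside
      }
      j <- i
    }
    out[p] <- inside || on_edge
  }
  out
}

# cell membership with closed-set semantics: points exactly on a cell edge
# count as inside if either adjacent cell is in the mask
in_cell_mask <- function(grid, cells, x, y, tol = 1e-9) {
  fx <- (x - grid$x0) / grid$cell
  fy <- (y - grid$y0) / grid$cell
  cands <- function(f) {
    c0 <- floor(f) + 1
    lapply(seq_along(f), function(i) {
      cc <- c0[i]
      if (abs(f[i] - round(f[i])) < tol) cc <- c(cc, cc - 1)
      cc
    })
  }
  cx <- cands(fx); cy <- cands(fy)
  vapply(seq_along(x), function(i) {
    any(vapply(cx[[i]], function(ci) {
      any(vapply(cy[[i]], function(ri) {
        ci >= 1 && ri >= 1 && ci <= grid$nx && ri <= grid$ny && cells[ci, ri]
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
}

#' Filter focal-animal fixes to the study area
#'
#' Retains a fix iff it lies inside (or on the boundary of) the merged
#' study-area polygons or inside an exception zone.  The result carries a
#' per-fix inclusion flag and reason, so the operation is idempotent on the
#' included subset and `included + excluded = input`.
#'
#' @param fixes fix table.
#' @param sa a [delineate_study_area()] result.
#' @return `fixes` with logical `included` and `reason`
#'   (`"study_area"`, `"exception"` or `"outside"`) columns; exclusion
#'   counts in the `exclusion_log` attribute.
#' @export
filter_fixes <- function(fixes, sa) {
  n <- nrow(fixes)
  in_sa <- if (is.null(sa$cells)) {
    rep(FALSE, n)
  } else {
    in_cell_mask(sa$grid, sa$cells, fixes$x, fixes$y)
  }
  in_ex <- rep(FALSE, n)
  for (poly in sa$exceptions) {
    in_ex <- in_ex | point_in_polygon(fixes$x, fixes$y, poly)
  }
  reason <- ifelse(in_sa, "study_area", ifelse(in_ex, "exception", "outside"))
  out <- mutate(as_tibble(fixes), included = in_sa | in_ex, reason = reason)
  attr(out, "exclusion_log") <- as.list(table(reason))
  out
}

#' Extract risk-surface values at fixes
#'
#' Value of the grid cell containing each point (no interpolation);
#' half-open cell ownership, so a point on a shared edge belongs to the
#' cell starting there.
#'
#' @param rs a `risk_surface` (or `ud_raster`).
#' @param x,y point coordinates, meters.
#' @return numeric vector of cell values.
#' @export
extract_risk <- function(rs, x, y) {
  g <- rs$grid
  ci <- cell_col(g, x)
  ri <- cell_row(g, y)
  bad <- ci < 1 | ci > g$nx | ri < 1 | ri > g$ny
  if (any(bad)) {
    abort(sprintf(
      "%d point(s) outside the raster extent (filter fixes to the study area first)",
      sum(bad)
    ))
  }
  rs$values[cbind(ci, ri)]
}
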