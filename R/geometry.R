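# Planar geometry on the equal-area grid: convex-hull clipping and
# dispersal buffers. Distances are Euclidean in km between cell centres.

#' Clip a predicted range to a buffered minimum convex polygon
#'
#' Distribution models overpredict; the classic guard is to erase predicted
#' presences farther than `buffer_km` from the convex hull of the known
#' occurrences. One occurrence degrades the hull to a point, two (or any
#' collinear set) to a segment.
#'
#' @param range_cells Predicted presence cell ids.
#' @param occurrence_cells Known occurrence cell ids (>= 1).
#' @param grid Grid tibble giving cell centres.
#' @param buffer_km Buffer width in km (default 200, i.e. 20 km per decade
#'   over a century).
#' @return The subset of `range_cells` within the buffered hull.
#' @export
clip_to_buffered_mcp <- function(range_cells, occurrence_cells, grid,
                                 buffer_km = 200) {
  if (length(occurrence_cells) == 0) abort("no occurrence cells")
  check_cells(c(range_cells, occurrence_cells), grid, "range")
  if (length(range_cells) == 0) return(integer())
  oc <- grid[match(unique(occurrence_cells), grid$cell_id), ]
  rc <- grid[match(range_cells, grid$cell_id), ]
  d <- dist_to_convex_hull(rc$x, rc$y, oc$x, oc$y)
  range_cells[d <= buffer_km]
}

# Distance from points (px, py) to the convex hull of (hx, hy); 0 inside.
dist_to_convex_hull <- function(px, py, hx, hy) {
  pts <- unique(cbind(hx, hy))
  if (nrow(pts) == 1) {
    return(sqrt((px - pts[1, 1])^2 + (py - pts[1, 2])^2))
  }
  hull_idx <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[hull_idx, , drop = FALSE]
  if (nrow(hull) <= 2 || is_collinear(pts)) {
    # degenerate (collinear) hull: distance to the spanning segment
    dm <- as.matrix(dist(pts))
    far <- which(dm == max(dm), arr.ind = TRUE)[1, ]
    a <- pts[far[1], ]; b <- pts[far[2], ]
    return(point_segment_dist(px, py, a[1], a[2], b[1], b[2]))
  }
  n <- nrow(hull)
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    crs <- (hull[j, 1] - hull[i, 1]) * (py - hull[i, 2]) -
           (hull[j, 2] - hull[i, 2]) * (px - hull[i, 1])
    # chull returns vertices clockwise; interior is on the right (cross <= 0)
    inside <- inside & (crs <= 1e-9)
  }
  d <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- pmin(d, point_segment_dist(px, py, hull[i, 1], hull[i, 2],
                                    hull[j, 1], hull[j, 2]))
  }
  d[inside] <- 0
  d
}

is_collinear <- function(pts, tol = 1e-9) {
  if (nrow(pts) <= 2) return(TRUE)
  a <- pts[1, ]; b <- pts[2, ]
  crs <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
  all(abs(crs) < tol)
}

# Vectorized distance from points to the segment [a, b].
point_segment_dist <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

#' Apply a dispersal scenario to a projected future range
#'
#' Full dispersal keeps the unconstrained projection; no dispersal keeps
#' only cells already occupied today; limited dispersal keeps future cells
#' within `buffer_km` of the current range. The results nest:
#' none ⊆ limited ⊆ full.
#'
#' @param current_cells Current range cell ids.
#' @param future_cells Unconstrained projected future cell ids.
#' @param scenario One of `"full"`, `"limited"`, `"none"`.
#' @param grid Grid tibble (needed for `"limited"`).
#' @param buffer_km Reachable distance in km for the limited scenario.
#' @return The constrained future cell ids.
#' @export
apply_dispersal <- function(current_cells, future_cells,
                            scenario = c("full", "limited", "none"),
                            grid = NULL, buffer_km = 200) {
  scenario <- match.arg(scenario)
  switch(scenario,
    full = future_cells,
    none = intersect(future_cells, current_cells),
    limited = {
      if (length(current_cells) == 0 || length(future_cells) == 0) {
        return(intersect(future_cells, current_cells))
      }
      if (is.null(grid)) abort("limited dispersal needs the grid")
      cur <- grid[match(current_cells, grid$cell_id), ]
      fut <- grid[match(future_cells, grid$cell_id), ]
      dmin <- apply(cross_dist(fut$x, fut$y, cur$x, cur$y), 1, min)
      future_cells[dmin <= buffer_km]
    }
  )
}
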