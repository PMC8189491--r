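#' Assign planar points to the tracts containing them
#'
#' Maps each point to the tract whose polygon contains it, scanning tracts in
#' lexicographic `tract_id` order with a bounding-box prefilter; a point on a
#' shared boundary therefore goes to the lexicographically smallest owning
#' tract. Points outside every polygon come back as `NA` and their count is
#' recorded in `attr(, "n_unassigned")`.
#'
#' @param points numeric matrix or data.frame with two columns (x, y in km).
#' @param tracts a `tract_set` tiling the region.
#' @return character vector of tract ids (NA = unassigned), one per point.
#' @export
assign_points_to_tracts <- function(points, tracts) {
  stopifnot(inherits(tracts, "tract_set"))
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop_invalid("`points` must have two columns")
  n <- nrow(pts)
  out <- rep(NA_character_, n)
  ids <- sort(tracts$tracts$tract_id)
  for (id in ids) {
    ring <- tracts$polygons[[id]]
    todo <- which(is.na(out) &
                    pts[, 1L] >= min(ring[, 1L]) & pts[, 1L] <= max(ring[, 1L]) &
                    pts[, 2L] >= min(ring[, 2L]) & pts[, 2L] <= max(ring[, 2L]))
    if (!length(todo)) next
    inside <- pracma::inpolygon(pts[todo, 1L], pts[todo, 2L],
                                ring[, 1L], ring[, 2L], boundary = TRUE)
    out[todo[inside]] <- id
  }
  n_un <- sum(is.na(out))
  if (n_un > 0) {
    message(sprintf("assign_points_to_tracts: %d point(s) outside all tracts", n_un))
  }
  structure(out, n_unassigned = n_un)
}

# cached cell-center -> tract assignment for a raster/tract pair
raster_tract_assignment <- function(raster, tracts) {
  cc <- raster_cell_centers(raster)
  grid_pts <- cbind(rep(cc$x, each = nrow(raster$grid)),
                    rep(cc$y, times = ncol(raster$grid)))
  # grid_pts is column-major over [row, col], matching as.vector(grid)
  suppressMessages(assign_points_to_tracts(grid_pts, tracts))
}
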