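#' NLCD land-cover legend used by the synthetic raster
#'
#' The 20 sub-classes of the National Land Cover Database legend, with their
#' integer class codes.
#'
#' @return data.frame with `code` (integer) and `class` (name).
#' @export
landcover_classes <- function() {
  data.frame(
    code = c(11L, 12L, 21L, 22L, 23L, 24L, 31L, 41L, 42L, 43L,
             51L, 52L, 71L, 72L, 73L, 74L, 81L, 82L, 90L, 95L),
    class = c("open_water", "perennial_ice_snow", "developed_open",
              "developed_low", "developed_medium", "developed_high",
              "barren", "forest_deciduous", "forest_evergreen",
              "forest_mixed", "dwarf_scrub", "shrub", "grassland",
              "sedge", "lichens", "moss", "pasture_hay",
              "cultivated_crops", "woody_wetlands", "herbaceous_wetlands"),
    stringsAsFactors = FALSE
  )
}

# mix typical of an urbanised study region; zero-weight classes never occur
default_class_weights <- function() {
  w <- c(open_water = 0.03, perennial_ice_snow = 0, developed_open = 0.10,
         developed_low = 0.18, developed_medium = 0.20, developed_high = 0.12,
         barren = 0.02, forest_deciduous = 0.08, forest_evergreen = 0.05,
         forest_mixed = 0.04, dwarf_scrub = 0, shrub = 0.03, grassland = 0.05,
         sedge = 0, lichens = 0, moss = 0, pasture_hay = 0.04,
         cultivated_crops = 0.04, woody_wetlands = 0.01,
         herbaceous_wetlands = 0.01)
  w
}

# row-normalised box-blur band matrix (window radius r) for a length-n axis
box_blur_matrix <- function(n, r) {
  m <- abs(outer(seq_len(n), seq_len(n), "-")) <= r
  m / rowSums(m)
}

#' Generate a synthetic categorical land-cover raster
#'
#' Covers the tract-set bounding box with a square-cell grid and assigns each
#' cell one of the 20 NLCD sub-class codes. Each positive-weight class gets an
#' independent Gumbel noise field; with `clumping > 0` the fields are
#' box-blurred (radius `clumping` cells) and re-standardised, and the class of
#' a cell is the argmax of field + log(weight). At `clumping = 0` this is the
#' Gumbel-max trick, i.e. exact i.i.d. categorical sampling with
#' probabilities proportional to `class_weights`; larger `clumping` yields
#' spatially autocorrelated patches with the same large-scale mix.
#'
#' @param tracts a `tract_set`; the raster covers its bounding box.
#' @param cell_km cell edge length in km (> 0).
#' @param class_weights named non-negative weights over
#'   `landcover_classes()$class`; at least one positive.
#' @param clumping non-negative blur radius in cells; 0 = i.i.d. cells.
#' @param seed integer RNG seed.
#' @return A `landcover_raster`: list with `grid` (integer matrix of class
#'   codes, rows = y from the south edge up, cols = x), `cell_km`, `origin`
#'   (xmin, ymin of the grid), and `legend` (the class table).
#' @export
generate_landcover <- function(tracts, cell_km = 0.2,
                               class_weights = default_class_weights(),
                               clumping = 6, seed = 1) {
  stopifnot(inherits(tracts, "tract_set"))
  assert_scalar_num(cell_km, "cell_km")
  if (cell_km <= 0) stop_invalid("`cell_km` must be > 0")
  assert_scalar_num(clumping, "clumping")
  if (clumping < 0) stop_invalid("`clumping` must be >= 0")
  legend <- landcover_classes()
  w <- rep(0, nrow(legend))
  names(w) <- legend$class
  if (is.null(names(class_weights))) {
    stop_invalid("`class_weights` must be named by land-cover class")
  }
  unknown <- setdiff(names(class_weights), legend$class)
  if (length(unknown)) {
    stop_invalid("unknown land-cover classes: %s", paste(unknown, collapse = ", "))
  }
  w[names(class_weights)] <- class_weights
  if (any(w < 0) || all(w == 0)) {
    stop_invalid("`class_weights` must be non-negative with at least one positive entry")
  }

  bb <- tracts$bbox
  nx <- max(1L, ceiling((bb["xmax"] - bb["xmin"]) / cell_km))
  ny <- max(1L, ceiling((bb["ymax"] - bb["ymin"]) / cell_km))
  active <- which(w > 0)

  with_seed(seed, {
    r <- round(clumping)
    best <- matrix(-Inf, ny, nx)
    code <- matrix(legend$code[active[1L]], ny, nx)
    if (r > 0) {
      by <- box_blur_matrix(ny, r)
      bx <- box_blur_matrix(nx, r)
    }
    for (a in active) {
      u <- matrix(runif(ny * nx), ny, nx)
      field <- -log(-log(u))  # standard Gumbel
      if (r > 0) {
        field <- by %*% field %*% t(bx)
        field <- (field - mean(field)) / sd(field)
      }
      score <- field + log(w[a])
      upd <- score > best
      best[upd] <- score[upd]
      code[upd] <- legend$code[a]
    }
    structure(
      list(grid = code, cell_km = cell_km,
           origin = c(x = unname(bb["xmin"]), y = unname(bb["ymin"])),
           legend = legend),
      class = "landcover_raster"
    )
  })
}

#' @export
print.landcover_raster <- function(x, ...) {
  cat(sprintf("<landcover_raster> %d x %d cells of %.3g km, %d classes present\n",
              nrow(x$grid), ncol(x$grid), x$cell_km,
              length(unique(as.vector(x$grid)))))
  invisible(x)
}

# x/y coordinates (km) of all cell centers, row-major over [row, col]
raster_cell_centers <- function(raster) {
  ny <- nrow(raster$grid); nx <- ncol(raster$grid)
  cx <- raster$origin["x"] + (seq_len(nx) - 0.5) * raster$cell_km
  cy <- raster$origin["y"] + (seq_len(ny) - 0.5) * raster$cell_km
  list(x = unname(cx), y = unname(cy))
}
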