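#' Per-tract land-cover class proportions
#'
#' Attributes every raster cell to the tract containing its center and
#' reports, per tract, the proportion of attributed cells in each of the 20
#' land-cover sub-classes. Proportions row-sum to 1. A tract capturing no
#' cell centers (possible for slivers smaller than a cell) is flagged in
#' `attr(, "degenerate_tracts")` and given the region-wide mean proportions
#' so the design matrix stays complete.
#'
#' @param raster a `landcover_raster` covering the tract polygons.
#' @param tracts a `tract_set`.
#' @return a `feature_table`, one column per sub-class name, provenance
#'   `landcover`.
#' @export
landcover_proportions <- function(raster, tracts) {
  stopifnot(inherits(raster, "landcover_raster"), inherits(tracts, "tract_set"))
  ids <- tracts$tracts$tract_id
  assign <- raster_tract_assignment(raster, tracts)
  codes <- as.vector(raster$grid)
  legend <- raster$legend
  keep <- !is.na(assign)
  tab <- table(factor(assign[keep], levels = ids),
               factor(codes[keep], levels = legend$code))
  counts <- matrix(as.integer(tab), nrow = length(ids),
                   dimnames = list(ids, legend$class))
  tot <- rowSums(counts)
  degenerate <- ids[tot == 0]
  prop <- counts / ifelse(tot == 0, 1, tot)
  if (length(degenerate)) {
    overall <- colSums(counts) / sum(counts)
    prop[tot == 0, ] <- rep(overall, each = length(degenerate))
    message(sprintf("landcover_proportions: %d tract(s) captured no cell centers; using region-wide means",
                    length(degenerate)))
  }
  out <- data.frame(tract_id = ids, prop, stringsAsFactors = FALSE,
                    check.names = FALSE, row.names = NULL)
  ft <- feature_table(out, provenance = "landcover")
  attr(ft, "degenerate_tracts") <- degenerate
  ft
}

# logical matrix: does each cell have >= 1 neighbor (4- or 8-neighborhood)
# belonging to `target`? Cells beyond the grid edge count as non-target.
has_neighbor_of <- function(is_target, neighborhood = 4) {
  ny <- nrow(is_target); nx <- ncol(is_target)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- is_target
  up    <- pad[1:ny, 2:(nx + 1L)]
  down  <- pad[3:(ny + 2L), 2:(nx + 1L)]
  left  <- pad[2:(ny + 1L), 1:nx]
  right <- pad[2:(ny + 1L), 3:(nx + 2L)]
  out <- up | down | left | right
  if (neighborhood == 8) {
    out <- out |
      pad[1:ny, 1:nx] | pad[1:ny, 3:(nx + 2L)] |
      pad[3:(ny + 2L), 1:nx] | pad[3:(ny + 2L), 3:(nx + 2L)]
  }
  out
}

#' Land-cover pixel-adjacency features
#'
#' Three per-tract features describing the spatial arrangement (not just the
#' amount) of developed and forest land:
#' \itemize{
#'   \item `highdev_adj_highdev` — proportion of high-intensity developed
#'     pixels with at least one high-intensity developed neighbor;
#'   \item `highdev_adj_forest` — proportion of high-intensity developed
#'     pixels with at least one forest neighbor;
#'   \item `forest_adj_forest` — proportion of forest pixels with at least
#'     one forest neighbor.
#' }
#' Forest is the union of the deciduous, evergreen and mixed sub-classes. A
#' focal pixel qualifies if any pixel of its 4-neighborhood (configurable to
#' 8) is of the target class; tracts with no focal pixels score 0.
#'
#' @param raster a `landcover_raster`.
#' @param tracts a `tract_set`.
#' @param developed_classes,forest_classes class-name groups.
#' @param neighborhood 4 (von Neumann, default) or 8 (Moore).
#' @return a `feature_table` with three columns, provenance `landcover`.
#' @export
adjacency_features <- function(raster, tracts,
                               developed_classes = "developed_high",
                               forest_classes = c("forest_deciduous",
                                                  "forest_evergreen",
                                                  "forest_mixed"),
                               neighborhood = 4) {
  stopifnot(inherits(raster, "landcover_raster"), inherits(tracts, "tract_set"))
  if (!neighborhood %in% c(4, 8)) stop_invalid("`neighborhood` must be 4 or 8")
  legend <- raster$legend
  dev_codes <- legend$code[legend$class %in% developed_classes]
  for_codes <- legend$code[legend$class %in% forest_classes]
  is_dev <- matrix(raster$grid %in% dev_codes, nrow(raster$grid))
  is_for <- matrix(raster$grid %in% for_codes, nrow(raster$grid))
  nb_dev <- has_neighbor_of(is_dev, neighborhood)
  nb_for <- has_neighbor_of(is_for, neighborhood)

  ids <- tracts$tracts$tract_id
  assign <- raster_tract_assignment(raster, tracts)
  fa <- factor(assign, levels = ids)

  prop_by_tract <- function(focal, qualifies) {
    nf <- tapply(as.vector(focal), fa, sum)
    nq <- tapply(as.vector(focal & qualifies), fa, sum)
    nf[is.na(nf)] <- 0; nq[is.na(nq)] <- 0
    ifelse(nf == 0, 0, nq / nf)
  }

  out <- data.frame(
    tract_id = ids,
    highdev_adj_highdev = as.numeric(prop_by_tract(is_dev, nb_dev)),
    highdev_adj_forest = as.numeric(prop_by_tract(is_dev, nb_for)),
    forest_adj_forest = as.numeric(prop_by_tract(is_for, nb_for)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  feature_table(out, provenance = "landcover")
}
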