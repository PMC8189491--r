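# Independent brute-force oracles. These deliberately share no code with the
# package implementations: plain loops, no data.table, own point-in-polygon.

# per-tract per-keyword normalized counts from an event list with token sets
oracle_normalized_counts <- function(events, keywords, ids) {
  out <- matrix(0, length(ids), length(keywords),
                dimnames = list(ids, keywords))
  for (id in ids) {
    ev <- events[vapply(events, function(e) e$tract_id == id, TRUE)]
    if (!length(ev)) next
    for (k in keywords) {
      hits <- sum(vapply(ev, function(e) k %in% e$tokens, TRUE))
      out[id, k] <- hits / length(ev)
    }
  }
  out
}

# all-pairs nearest neighbors by centroid distance, ties lexicographic
oracle_nearest_neighbors <- function(tracts, m) {
  tr <- tracts$tracts
  res <- list()
  for (i in seq_len(nrow(tr))) {
    d <- sqrt((tr$centroid_x - tr$centroid_x[i])^2 +
                (tr$centroid_y - tr$centroid_y[i])^2)
    ord <- order(d, tr$tract_id)
    res[[tr$tract_id[i]]] <- tr$tract_id[ord][seq_len(m)]
  }
  res
}

# neighbor averaging by explicit loops
oracle_smooth <- function(values, neighbor_lists) {
  out <- values
  for (id in rownames(values)) {
    nb <- neighbor_lists[[id]]
    for (j in colnames(values)) {
      out[id, j] <- mean(values[nb, j])
    }
  }
  out
}

# pixel-adjacency features by explicit pixel enumeration (4-neighborhood)
oracle_adjacency <- function(grid, assign_mat, dev_codes, forest_codes, ids) {
  ny <- nrow(grid); nx <- ncol(grid)
  res <- matrix(0, length(ids), 3,
                dimnames = list(ids, c("hh", "hf", "ff")))
  for (id in ids) {
    n_dev <- n_hh <- n_hf <- n_for <- n_ff <- 0
    for (r in seq_len(ny)) for (c in seq_len(nx)) {
      if (is.na(assign_mat[r, c]) || assign_mat[r, c] != id) next
      nb <- c()
      if (r > 1) nb <- c(nb, grid[r - 1, c])
      if (r < ny) nb <- c(nb, grid[r + 1, c])
      if (c > 1) nb <- c(nb, grid[r, c - 1])
      if (c < nx) nb <- c(nb, grid[r, c + 1])
      if (grid[r, c] %in% dev_codes) {
        n_dev <- n_dev + 1
        if (any(nb %in% dev_codes)) n_hh <- n_hh + 1
        if (any(nb %in% forest_codes)) n_hf <- n_hf + 1
      }
      if (grid[r, c] %in% forest_codes) {
        n_for <- n_for + 1
        if (any(nb %in% forest_codes)) n_ff <- n_ff + 1
      }
    }
    res[id, ] <- c(if (n_dev) n_hh / n_dev else 0,
                   if (n_dev) n_hf / n_dev else 0,
                   if (n_for) n_ff / n_for else 0)
  }
  res
}

# convex-polygon containment via edge cross-products (boundary inclusive);
# valid for the generator's trapezoids, which are convex and CCW
oracle_point_in_quad <- function(px, py, ring, eps = 1e-9) {
  n <- nrow(ring) - 1L
  for (i in seq_len(n)) {
    ex <- ring[i + 1, 1] - ring[i, 1]
    ey <- ring[i + 1, 2] - ring[i, 2]
    cross <- ex * (py - ring[i, 2]) - ey * (px - ring[i, 1])
    if (cross < -eps) return(FALSE)
  }
  TRUE
}

oracle_assign_points <- function(points, tracts) {
  ids <- tracts$tracts$tract_id
  out <- rep(NA_character_, nrow(points))
  for (p in seq_len(nrow(points))) {
    owners <- ids[vapply(ids, function(id) {
      oracle_point_in_quad(points[p, 1], points[p, 2], tracts$polygons[[id]])
    }, TRUE)]
    if (length(owners)) out[p] <- min(owners)
  }
  out
}

# cell-center coordinates recomputed from the raster header (column-major
# over [row, col], matching as.vector(grid))
raster_cell_centers_for_test <- function(raster) {
  ny <- nrow(raster$grid); nx <- ncol(raster$grid)
  cx <- raster$origin[["x"]] + (seq_len(nx) - 0.5) * raster$cell_km
  cy <- raster$origin[["y"]] + (seq_len(ny) - 0.5) * raster$cell_km
  cbind(rep(cx, each = ny), rep(cy, times = nx))
}

# select_keywords stop rule: index of first non-relevant label
oracle_prefix_length <- function(relevant) {
  n <- 0L
  for (r in relevant) {
    if (!r) break
    n <- n + 1L
  }
  n
}
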