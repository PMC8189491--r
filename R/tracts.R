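#' Generate a synthetic set of census tracts
#'
#' Builds a jittered rectangular tiling of a square region into `n_tracts`
#' interior-disjoint polygons standing in for census tracts. Rows of the
#' tiling are horizontal strips; each strip is cut into trapezoidal cells by
#' slanted vertical edges, so the polygons tile the region exactly for any
#' jitter. Tracts carry a state code assigned in contiguous spatial blocks and
#' a log-normally distributed population.
#'
#' Defaults approximate the geography of urban US census tracts: a median
#' tract area of about 2.45 km2 (the default `region_size` is chosen so the
#' mean cell area equals 2.45 km2) and a median population of 3652.
#'
#' @param n_tracts number of tracts (>= 2).
#' @param region_size side length of the square region in km. Default
#'   `sqrt(n_tracts * 2.45)` so tracts average 2.45 km2.
#' @param jitter vertex jitter as a fraction of cell size, in `[0, 0.5)`.
#'   0 gives an exact rectangular grid.
#' @param seed integer RNG seed.
#' @param n_states number of state blocks (contiguous runs of tracts); the
#'   default caps at the number of tracts.
#' @param pop_median,pop_sdlog log-normal population parameters; populations
#'   are rounded and floored at 1.
#' @return A `tract_set`: list with `tracts` (data.frame of `tract_id`,
#'   `state_code`, `population`, `area_km2`, `centroid_x`, `centroid_y`),
#'   `polygons` (named list of closed two-column rings, km), and `bbox`
#'   (`xmin, ymin, xmax, ymax`).
#' @examples
#' ts <- generate_tracts(9, region_size = 6, jitter = 0.2, seed = 1)
#' sum(ts$tracts$area_km2)  # == 36, the region area
#' @export
generate_tracts <- function(n_tracts, region_size = NULL, jitter = 0.25,
                            seed = 1, n_states = min(4, n_tracts),
                            pop_median = 3652, pop_sdlog = 0.5) {
  if (!is.numeric(n_tracts) || length(n_tracts) != 1L || is.na(n_tracts) ||
      n_tracts < 2 || n_tracts != round(n_tracts)) {
    stop_invalid("`n_tracts` must be an integer >= 2")
  }
  n_tracts <- as.integer(n_tracts)
  region_size <- region_size %||% sqrt(n_tracts * 2.45)
  assert_scalar_num(region_size, "region_size")
  if (region_size <= 0) stop_invalid("`region_size` must be > 0")
  assert_scalar_num(jitter, "jitter")
  if (jitter < 0 || jitter >= 0.5) stop_invalid("`jitter` must be in [0, 0.5)")
  if (n_states < 1 || n_states > n_tracts) {
    stop_invalid("`n_states` must be between 1 and `n_tracts`")
  }

  with_seed(seed, {
    # split n_tracts into nr rows of near-equal cell counts
    nr <- max(1L, round(sqrt(n_tracts)))
    base <- n_tracts %/% nr
    extra <- n_tracts %% nr
    row_counts <- rep(base, nr) + c(rep(1L, extra), rep(0L, nr - extra))

    h <- region_size / nr
    # horizontal strip boundaries, interior ones jittered as whole lines
    ys <- (0:nr) * h
    if (nr > 1L && jitter > 0) {
      ys[2:nr] <- ys[2:nr] + runif(nr - 1L, -jitter, jitter) * h
    }

    polygons <- vector("list", n_tracts)
    idx <- 0L
    for (r in seq_len(nr)) {
      k <- row_counts[r]
      w <- region_size / k
      xb <- xt <- (0:k) * w
      if (k > 1L && jitter > 0) {
        xb[2:k] <- xb[2:k] + runif(k - 1L, -jitter, jitter) * w
        xt[2:k] <- xt[2:k] + runif(k - 1L, -jitter, jitter) * w
      }
      y0 <- ys[r]; y1 <- ys[r + 1L]
      for (c in seq_len(k)) {
        idx <- idx + 1L
        ring <- rbind(
          c(xb[c],      y0),
          c(xb[c + 1L], y0),
          c(xt[c + 1L], y1),
          c(xt[c],      y1),
          c(xb[c],      y0)
        )
        polygons[[idx]] <- ring
      }
    }

    ids <- sprintf("T%04d", seq_len(n_tracts))
    names(polygons) <- ids
    cent <- t(vapply(polygons, ring_centroid, numeric(2)))
    areas <- vapply(polygons, ring_area, numeric(1))

    # contiguous blocks of the row-major order -> spatially coherent states
    state_idx <- ceiling(seq_len(n_tracts) / (n_tracts / n_states))
    state_idx <- pmin(state_idx, n_states)
    pop <- pmax(1, round(rlnorm(n_tracts, meanlog = log(pop_median),
                                sdlog = pop_sdlog)))

    tracts <- data.frame(
      tract_id = ids,
      state_code = sprintf("S%02d", state_idx),
      population = as.integer(pop),
      area_km2 = unname(areas),
      centroid_x = unname(cent[, 1L]),
      centroid_y = unname(cent[, 2L]),
      stringsAsFactors = FALSE
    )
    structure(
      list(tracts = tracts, polygons = polygons,
           bbox = c(xmin = 0, ymin = 0, xmax = region_size, ymax = region_size)),
      class = "tract_set"
    )
  })
}

#' @export
print.tract_set <- function(x, ...) {
  cat(sprintf("<tract_set> %d tracts, %d states, region %.2f x %.2f km\n",
              nrow(x$tracts), length(unique(x$tracts$state_code)),
              x$bbox["xmax"] - x$bbox["xmin"], x$bbox["ymax"] - x$bbox["ymin"]))
  invisible(x)
}

#' Number of tracts in a tract set
#' @param x a `tract_set`.
#' @export
n_tracts <- function(x) {
  stopifnot(inherits(x, "tract_set"))
  nrow(x$tracts)
}

#' Restrict a tract set to a subset of tract ids
#'
#' @param x a `tract_set`.
#' @param ids character vector of tract ids to keep (order preserved from `x`).
#' @return a `tract_set` containing only the requested tracts.
#' @export
subset_tracts <- function(x, ids) {
  stopifnot(inherits(x, "tract_set"))
  missing <- setdiff(ids, x$tracts$tract_id)
  if (length(missing)) {
    stop_invalid("unknown tract ids: %s", paste(missing, collapse = ", "))
  }
  keep <- x$tracts$tract_id %in% ids
  structure(
    list(tracts = x$tracts[keep, , drop = FALSE],
         polygons = x$polygons[x$tracts$tract_id[keep]],
         bbox = x$bbox),
    class = "tract_set"
  )
}
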