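#' Write / read tracts as a GeoJSON FeatureCollection
#'
#' One Polygon feature per tract with properties `tract_id`, `state_code`,
#' `population`, `area_km2`. Coordinates are the planar km coordinates of the
#' synthetic region (not lon/lat).
#'
#' @param x a `tract_set`.
#' @param path file path.
#' @export
write_tracts_geojson <- function(x, path) {
  stopifnot(inherits(x, "tract_set"))
  features <- lapply(seq_len(nrow(x$tracts)), function(i) {
    row <- x$tracts[i, ]
    ring <- x$polygons[[row$tract_id]]
    list(
      type = "Feature",
      properties = list(tract_id = row$tract_id, state_code = row$state_code,
                        population = row$population, area_km2 = row$area_km2),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(j) ring[j, ])))
    )
  })
  fc <- list(type = "FeatureCollection",
             bbox = as.list(unname(x$bbox)),
             features = features)
  # I(17): round-trip-exact significant digits for coordinates
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_tracts_geojson
#' @export
read_tracts_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  feats <- fc$features
  polygons <- list()
  rows <- lapply(feats, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) unlist(p)))
    id <- f$properties$tract_id
    polygons[[id]] <<- ring
    cent <- ring_centroid(ring)
    data.frame(tract_id = id, state_code = f$properties$state_code,
               population = as.integer(f$properties$population),
               area_km2 = as.numeric(f$properties$area_km2),
               centroid_x = cent[1], centroid_y = cent[2],
               stringsAsFactors = FALSE)
  })
  tracts <- do.call(rbind, rows)
  bbox <- unlist(fc$bbox)
  structure(list(tracts = tracts, polygons = polygons,
                 bbox = c(xmin = bbox[1], ymin = bbox[2],
                          xmax = bbox[3], ymax = bbox[4])),
            class = "tract_set")
}

#' Write / read a land-cover raster as an ESRI ASCII grid
#'
#' Single-band integer class codes in the plain-text `.asc` format
#' (ncols/nrows/xllcorner/yllcorner/cellsize header, rows north to south),
#' with the class legend in a JSON sidecar `<path>.legend.json`.
#'
#' @param x a `landcover_raster`.
#' @param path `.asc` file path.
#' @export
write_landcover_asc <- function(x, path) {
  stopifnot(inherits(x, "landcover_raster"))
  g <- x$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.10g", x$origin["x"]),
    sprintf("yllcorner %.10g", x$origin["y"]),
    sprintf("cellsize %.10g", x$cell_km),
    "NODATA_value -9999"
  ), con)
  # ASCII grids store the top (northern) row first; grid row 1 is the south
  for (r in rev(seq_len(nrow(g)))) {
    writeLines(paste(g[r, ], collapse = " "), con)
  }
  jsonlite::write_json(landcover_classes(), paste0(path, ".legend.json"),
                       digits = NA)
  invisible(path)
}

#' @rdname write_landcover_asc
#' @export
read_landcover_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  vals <- stats::setNames(vapply(hdr, function(h) as.numeric(h[2]), 0),
                          vapply(hdr, `[`, "", 1))
  nx <- as.integer(vals["ncols"]); ny <- as.integer(vals["nrows"])
  body <- lines[-(1:6)]
  rows <- lapply(body, function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  g <- do.call(rbind, rev(rows))  # back to south-first row order
  stopifnot(nrow(g) == ny, ncol(g) == nx)
  structure(list(grid = g, cell_km = unname(vals["cellsize"]),
                 origin = c(x = unname(vals["xllcorner"]),
                            y = unname(vals["yllcorner"])),
                 legend = landcover_classes()),
            class = "landcover_raster")
}

#' Write / read a query log
#'
#' JSON-lines (one object per event: `user_id`, `tract_id`, `tokens` array)
#' or CSV with space-joined tokens in a `query` column.
#'
#' @param log a `query_log`.
#' @param path file path; `.jsonl` or `.csv` chosen by `format`.
#' @param format `"jsonl"` or `"csv"`.
#' @export
write_query_log <- function(log, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  df <- as.data.frame(log)
  if (format == "csv") {
    write.csv(df[, c("event_id", "user_id", "tract_id", "query")], path,
              row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    toks <- strsplit(df$query, " ", fixed = TRUE)
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(list(user_id = df$user_id[i],
                                       tract_id = df$tract_id[i],
                                       tokens = toks[[i]]),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' @rdname write_query_log
#' @export
read_query_log <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    toks <- strsplit(df$query, " ", fixed = TRUE)
    ev <- data.frame(event_id = seq_len(nrow(df)), user_id = df$user_id,
                     tract_id = df$tract_id, stringsAsFactors = FALSE)
  } else {
    objs <- lapply(readLines(path), jsonlite::fromJSON)
    toks <- lapply(objs, function(o) as.character(o$tokens))
    ev <- data.frame(event_id = seq_along(objs),
                     user_id = vapply(objs, function(o) o$user_id, ""),
                     tract_id = vapply(objs, function(o) o$tract_id, ""),
                     stringsAsFactors = FALSE)
  }
  tok <- data.frame(event_id = rep.int(ev$event_id, lengths(toks)),
                    token = unlist(toks), stringsAsFactors = FALSE)
  query_log(ev, tok)
}

#' Write / read per-tract tables (census, prevalence) as CSV
#' @param x a data.frame keyed by `tract_id`.
#' @param path file path.
#' @export
write_tract_table <- function(x, path) {
  write.csv(format_doubles_exact(as.data.frame(x)), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

# format double columns with 17 significant digits so parsing them back
# restores the exact IEEE value
format_doubles_exact <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' @rdname write_tract_table
#' @param class extra S3 class to prepend on read (e.g. `"census_table"`).
#' @export
read_tract_table <- function(path, class = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(class)) class(d) <- c(class, "data.frame")
  d
}

#' Write / read a neighbor index as CSV (`tract_id`, `rank`, `neighbor_id`)
#' @param x a `neighbor_index`.
#' @param path file path.
#' @export
write_neighbor_index <- function(x, path) {
  stopifnot(inherits(x, "neighbor_index"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_neighbor_index
#' @export
read_neighbor_index <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  structure(d, class = c("neighbor_index", "data.frame"),
            m = max(d$rank))
}
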