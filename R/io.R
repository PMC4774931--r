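#' Raster and vector I/O
#'
#' Rasters are exchanged as ESRI ASCII grids (.asc), a plain-text
#' single-band format carrying the full grid geometry in its header, so every
#' written layer is self-describing and round-trips exactly at the printed
#' precision. Polygon layers (tenures, priority zones, protected areas) are
#' exchanged as GeoJSON FeatureCollections. Occurrences travel as CSV with
#' columns taxon, lon, lat, year, source.
#'
#' @name habfoot-io
NULL

#' Write a raster matrix as an ESRI ASCII grid
#'
#' @param values numeric matrix (height x width), row 1 = southernmost row
#' @param grid the [grid_geometry()]
#' @param path output file path
#' @param nodata sentinel written for NA cells
#' @export
writeAsciiGrid <- function(values, grid, path, nodata = -9999) {
  stopifnot(all(dim(values) == c(grid$height, grid$width)))
  v <- values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$width),
    paste("nrows", grid$height),
    paste("xllcorner", format(grid$origin[1], scientific = FALSE)),
    paste("yllcorner", format(grid$origin[2], scientific = FALSE)),
    paste("cellsize", format(grid$cell_size, scientific = FALSE)),
    paste("NODATA_value", nodata)), con)
  # ASCII grids store rows north-to-south
  for (r in rev(seq_len(grid$height)))
    writeLines(paste(format(v[r, ], trim = TRUE, digits = 10), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [writeAsciiGrid()] or any conforming grid
#' @return list with `values` (matrix, row 1 = south) and `grid`
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  body <- lines[i:length(lines)]
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  grid <- grid_geometry(hdr$ncols, hdr$nrows, hdr$cellsize,
                        c(hdr$xllcorner, hdr$yllcorner))
  list(values = m, grid = grid)
}

polygon_feature <- function(geometry, properties) {
  ring <- geometry
  if (!isTRUE(all(ring[1, ] == ring[nrow(ring), ])))
    ring <- rbind(ring, ring[1, ])
  list(type = "Feature",
       properties = properties,
       geometry = list(type = "Polygon",
                       coordinates = list(unname(ring))))
}

#' Write a polygon layer as GeoJSON
#'
#' @param polygons list of polygons, each a list with a `geometry` (n x 2
#'   coordinate matrix, open or closed ring) and scalar property fields
#' @param path output path
#' @export
writeGeoJSON <- function(polygons, path) {
  feats <- lapply(polygons, function(p) {
    props <- p[setdiff(names(p), "geometry")]
    props <- lapply(props, function(v) if (inherits(v, "Date")) format(v) else v)
    polygon_feature(p$geometry, props)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a GeoJSON polygon layer
#'
#' Only Polygon geometries (outer ring) are consumed; holes are out of scope.
#' @param path GeoJSON file
#' @return list of polygons in the [writeGeoJSON()] structure
#' @export
readGeoJSON <- function(path) {
  fc <- jsonlite::read_json(path)
  lapply(fc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(pt) unlist(pt)))
    props <- f$properties
    for (k in intersect(c("grant_date", "expiry_date"), names(props)))
      if (!is.null(props[[k]])) props[[k]] <- as.Date(props[[k]])
    c(list(geometry = ring), props)
  })
}

#' Write an occurrence set to CSV
#'
#' @param occ an occurrence set (see [occurrenceSet()])
#' @param path output CSV
#' @export
writeOccurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence CSV (taxon, lon, lat, year, source)
#'
#' @param path CSV path
#' @param crs_tag coordinate-reference tag to attach
#' @export
readOccurrences <- function(path, crs_tag = "unknown") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  occurrenceSet(df, crs_tag = crs_tag)
}
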