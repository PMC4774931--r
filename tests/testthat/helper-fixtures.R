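# shared fixtures: everything is generated in code, nothing is read from disk

small_spec <- function(seed = 1, n_presences = 120, ...) {
  landscapeSpec(grid_width = 32, grid_height = 32, seed = seed,
                n_presences = n_presences, n_background_per_species = 60,
                n_species_background = 3, ...)
}

# a bare occurrence set from coordinate vectors (handles empty sets)
occ <- function(lon, lat, taxon = "p_cincta_cincta", year = 2005,
                source = "test", id = NULL) {
  n <- length(lon)
  df <- data.frame(taxon = rep_len(taxon, n), lon = lon, lat = lat,
                   year = rep_len(year, n), source = rep_len(source, n),
                   stringsAsFactors = FALSE)
  if (!is.null(id)) df$id <- id
  occurrenceSet(df, crs_tag = "test")
}

# a constant-or-matrix binary raster on a fresh grid
bin <- function(values, width = ncol(values), height = nrow(values),
                cell_size = 250) {
  binary_raster(values, grid_geometry(width, height, cell_size))
}

# tiny climate stack where each layer is handed in as a matrix
toy_stack <- function(layers, cell_size = 250) {
  g <- grid_geometry(ncol(layers[[1]]), nrow(layers[[1]]), cell_size)
  full <- vector("list", 8)
  nms <- c("annual_mean_temp", "temp_seasonality", "max_temp_warmest",
           "min_temp_coldest", "annual_precip", "precip_wettest",
           "precip_driest", "precip_seasonality")
  for (i in seq_len(8))
    full[[i]] <- if (i <= length(layers)) layers[[i]]
                 else matrix(0.5, g$height, g$width)
  names(full) <- nms
  structure(list(layers = full, grid = g, layer_names = nms),
            class = "climate_stack")
}

# centre coordinates of given (row, col) cells
centres <- function(grid, rows, cols) {
  data.frame(lon = grid$origin[1] + (cols - 0.5) * grid$cell_size,
             lat = grid$origin[2] + (rows - 0.5) * grid$cell_size)
}

extfile <- function(name) system.file("extdata", name, package = "habfoot")
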