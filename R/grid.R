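#' Grid geometry for aligned raster layers
#'
#' All raster layers in a pipeline share one planar, equal-area grid: `width`
#' by `height` square cells of side `cell_size` metres, anchored at `origin`
#' (the outer corner of cell \[1,1\]). Cell ownership is half-open: a point
#' with coordinate x belongs to the cell whose interval is
#' `[x0, x0 + cell_size)`, so every point belongs to exactly one cell and
#' area bookkeeping is exact cell arithmetic.
#'
#' Rasters are stored as plain numeric/integer matrices with `height` rows and
#' `width` columns; row r spans y in `[origin_y + (r-1)*cs, origin_y + r*cs)`.
#'
#' @param width,height grid dimensions in cells (each >= 1)
#' @param cell_size cell side length in metres (default 250 m)
#' @param origin numeric length-2, planar (x, y) of the grid corner in metres
#' @return an object of class `grid_geometry`
#' @export
grid_geometry <- function(width, height, cell_size = 250, origin = c(0, 0)) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 1L || height < 1L)
    stop("grid dimensions must be positive integers", call. = FALSE)
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("cell_size must be > 0", call. = FALSE)
  structure(list(width = width, height = height,
                 cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d cells, %.6g m cells, origin (%.6g, %.6g)\n",
              x$width, x$height, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(a$width == b$width) && isTRUE(a$height == b$height) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_if_grid_mismatch <- function(a, b, what = "layers") {
  if (!same_grid(a, b))
    stop("grid mismatch between ", what, call. = FALSE)
  invisible(TRUE)
}

#' Cell-centre coordinates of every grid cell
#'
#' @param grid a [grid_geometry()]
#' @return data.frame with columns `row`, `col`, `x`, `y` in raster storage
#'   order (column-major over the matrix)
#' @export
cellCentres <- function(grid) {
  rows <- rep(seq_len(grid$height), times = grid$width)
  cols <- rep(seq_len(grid$width), each = grid$height)
  data.frame(row = rows, col = cols,
             x = grid$origin[1] + (cols - 0.5) * grid$cell_size,
             y = grid$origin[2] + (rows - 0.5) * grid$cell_size)
}

#' Locate points on the grid (half-open cell ownership)
#'
#' @param grid a [grid_geometry()]
#' @param x,y planar coordinates in metres
#' @return data.frame with `row`, `col` (NA for points off the grid) and
#'   logical `on_grid`
#' @export
locateCells <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1
  row <- floor((y - grid$origin[2]) / grid$cell_size) + 1
  on <- !is.na(col) & !is.na(row) &
    col >= 1 & col <= grid$width & row >= 1 & row <= grid$height
  col[!on] <- NA_integer_; row[!on] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col), on_grid = on)
}

raster_values_at <- function(values, grid, x, y) {
  loc <- locateCells(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- loc$on_grid
  out[ok] <- values[cbind(loc$row[ok], loc$col[ok])]
  out
}

#' Binary raster on a grid
#'
#' A 0/1 integer matrix plus its [grid_geometry()]; NA marks no-data.
#' @param values matrix of 0/1/NA with dim (height, width)
#' @param grid the matching [grid_geometry()]
#' @param provenance free-text provenance tag
#' @export
binary_raster <- function(values, grid, provenance = "") {
  if (!all(dim(values) == c(grid$height, grid$width)))
    stop("raster dimensions do not match grid", call. = FALSE)
  v <- values
  storage.mode(v) <- "integer"
  if (!all(v[!is.na(v)] %in% c(0L, 1L)))
    stop("binary raster values must be 0/1/NA", call. = FALSE)
  structure(list(values = v, grid = grid, provenance = provenance),
            class = "binary_raster")
}

#' @export
print.binary_raster <- function(x, ...) {
  cat(sprintf("binary_raster: %d x %d, %d cells set, %.4g km^2\n",
              x$grid$height, x$grid$width, sum(x$values == 1L, na.rm = TRUE),
              maskAreaKm2(x)))
  invisible(x)
}

#' Area of a binary mask in square kilometres
#'
#' Exact cell arithmetic: `count(mask == 1) * cell_size^2 / 1e6`.
#' @param mask a [binary_raster()] or 0/1 matrix
#' @param cell_size cell side in metres (taken from the raster when omitted)
#' @return area in km^2
#' @export
maskAreaKm2 <- function(mask, cell_size = NULL) {
  if (inherits(mask, "binary_raster")) {
    cell_size <- mask$grid$cell_size
    mask <- mask$values
  }
  if (is.null(cell_size)) stop("cell_size required for bare matrices", call. = FALSE)
  sum(mask == 1L, na.rm = TRUE) * cell_size^2 / 1e6
}

#' Exact Euclidean dilation of a binary mask
#'
#' Sets every cell whose centre lies within Euclidean distance `distance`
#' (metres) of the centre of any set cell. Uses an exact distance transform,
#' so a radius of 2 cells yields the 13-cell discrete disc
#' (offsets with i^2 + j^2 <= 4). `distance = 0` is the identity.
#'
#' @param mask 0/1 matrix (NA treated as 0 for distance purposes, restored
#'   as NA in the output)
#' @param distance metres, >= 0
#' @param cell_size metres per cell
#' @return 0/1 matrix of the same dimension
#' @export
dilateMask <- function(mask, distance, cell_size) {
  if (distance < 0) stop("distance must be >= 0", call. = FALSE)
  na <- is.na(mask)
  m <- mask; m[na] <- 0L
  if (sum(m) == 0L || distance == 0) {
    out <- m
  } else {
    # distmap gives, for each cell, the exact distance (in cells) to the
    # nearest zero of its argument; invert so zeros are the set cells.
    d <- EBImage::distmap(1 - m, metric = "euclidean")
    out <- (as.matrix(d) * cell_size <= distance) * 1L
  }
  storage.mode(out) <- "integer"
  out[na] <- NA_integer_
  out
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the desktop-GIS
#' convention), unlike [base::round()]'s round-half-even. Applied to the
#' decimal representation: `roundHalfAway(0.125, 2) == 0.13`.
#'
#' @param x numeric
#' @param digits decimal places (>= 0)
#' @export
roundHalfAway <- function(x, digits = 0) {
  if (digits < 0) stop("digits must be >= 0", call. = FALSE)
  p <- 10^digits
  # nudge by a relative epsilon so values stored just below a .5 boundary
  # by binary floating point (e.g. 0.125) still round away from zero
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage at the printed precision
#'
#' `100 * num / den`, rounded half-away to one decimal — the precision used
#' throughout the report tables.
#' @param num,den numerator and denominator
#' @export
pct1 <- function(num, den) {
  if (length(den) == 1 && den == 0) return(NA_real_)
  roundHalfAway(100 * num / den, 1)
}
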