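#' Omission, commission and model comparison
#'
#' Two refined models (built from two- and three-decimal thinned records)
#' trade area against omission: the evaluation quantifies that trade-off.
#' Omission is checked against recent records (year >= 2000 by convention);
#' commission has no true absences, so the count of target-group background
#' points inside the model is its proxy. Percentages print at one decimal,
#' half away from zero, and the two-model percentage-point difference is
#' computed from counts before rounding.
#'
#' @name evaluate
NULL

#' Omission check of a mask against recent records
#'
#' @param mask a [binary_raster()] or `habitat_model`
#' @param recent an [occurrenceSet()] of recent records (non-empty)
#' @return list `inside`, `total`, `pct` (one decimal)
#' @export
omissionRate <- function(mask, recent) {
  if (inherits(mask, "habitat_model")) mask <- mask$mask
  if (nrow(recent) == 0) stop("recent record set is empty", call. = FALSE)
  v <- raster_values_at(mask$values, mask$grid, recent$lon, recent$lat)
  inside <- sum(v == 1L, na.rm = TRUE)
  list(inside = inside, total = nrow(recent),
       pct = pct1(inside, nrow(recent)))
}

#' Commission proxy: background points inside a mask
#'
#' @param mask a [binary_raster()] or `habitat_model`
#' @param background a `background_set` or [occurrenceSet()]
#' @return integer count
#' @export
commissionProxy <- function(mask, background) {
  if (inherits(mask, "habitat_model")) mask <- mask$mask
  bg <- if (inherits(background, "background_set")) background$points
        else background
  v <- raster_values_at(mask$values, mask$grid, bg$lon, bg$lat)
  sum(v == 1L, na.rm = TRUE)
}

#' Model area in square kilometres
#'
#' Exact cell arithmetic; see [maskAreaKm2()].
#' @param mask a [binary_raster()] or `habitat_model`
#' @param cell_size metres (taken from the raster when omitted)
#' @export
modelArea <- function(mask, cell_size = NULL) {
  if (inherits(mask, "habitat_model")) mask <- mask$mask
  maskAreaKm2(mask, cell_size)
}

#' Compare two habitat models
#'
#' Populates areas, omission counts/rates, commission proxies, the area
#' ratio and the omission percentage-point difference (from counts, rounded
#' last), plus a recommendation flag mirroring the adopted reasoning: prefer
#' the smaller model when the larger one needs at least `r` times the area
#' to gain less than `delta` percentage points of omission.
#'
#' @param a,b `habitat_model`s (or binary rasters) on one grid; `a` is the
#'   larger/coarser candidate
#' @param recent recent records for the omission check
#' @param background background points for the commission proxy
#' @param r,delta recommendation thresholds (defaults 3 and 2)
#' @return a `model_comparison`
#' @export
compareModels <- function(a, b, recent, background, r = 3, delta = 2) {
  ma <- if (inherits(a, "habitat_model")) a$mask else a
  mb <- if (inherits(b, "habitat_model")) b$mask else b
  stop_if_grid_mismatch(ma$grid, mb$grid, "the two models")
  oa <- omissionRate(ma, recent); ob <- omissionRate(mb, recent)
  area_a <- maskAreaKm2(ma); area_b <- maskAreaKm2(mb)
  ratio <- if (area_b > 0) area_a / area_b else Inf
  diff_pp <- roundHalfAway(100 * (oa$inside - ob$inside) / oa$total, 1)
  rec <- if (is.finite(ratio) && ratio >= r && abs(diff_pp) < delta) "b"
         else "inspect"
  structure(list(
    a = list(area_km2 = area_a, omission_inside = oa$inside,
             omission_total = oa$total, omission_pct = oa$pct,
             background_inside = commissionProxy(ma, background)),
    b = list(area_km2 = area_b, omission_inside = ob$inside,
             omission_total = ob$total, omission_pct = ob$pct,
             background_inside = commissionProxy(mb, background)),
    area_ratio = ratio, omission_pct_difference = diff_pp,
    zero_denominator = area_b == 0,
    recommendation = rec, r = r, delta = delta),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model_comparison\n")
  cat(sprintf("  A: %8.4g km^2, omission %5.1f%% (%d/%d), %d background inside\n",
              x$a$area_km2, x$a$omission_pct, x$a$omission_inside,
              x$a$omission_total, x$a$background_inside))
  cat(sprintf("  B: %8.4g km^2, omission %5.1f%% (%d/%d), %d background inside\n",
              x$b$area_km2, x$b$omission_pct, x$b$omission_inside,
              x$b$omission_total, x$b$background_inside))
  cat(sprintf("  area ratio %.3g, omission difference %.1f pp, recommend: %s\n",
              x$area_ratio, x$omission_pct_difference, x$recommendation))
  invisible(x)
}
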