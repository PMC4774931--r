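#' From climate envelope to habitat model
#'
#' The thresholded climate envelope over-predicts in flat savanna country
#' with diffuse bioclimatic boundaries, so it is refined with fine-scale
#' vegetation information: islands and built-up areas are removed, the
#' vegetation classes that actually carry presence records inside the
#' envelope are selected (classes with three or fewer records are ignored,
#' as are water and cleared classes), and the selected classes are buffered
#' by a metric distance — 1118 m by default, the mean of maximum distances
#' travelled by radio-tracked birds — to admit adjacent cleared country the
#' birds are known to use. The buffered extent is *not* re-clipped to the
#' envelope: the habitat model may exceed the favourable-class extent.
#'
#' @name refine
NULL

#' Remove excluded land statuses from the envelope
#'
#' @param env a [binary_raster()] (the thresholded envelope)
#' @param veg a `vegetation_layer` on the same grid
#' @param statuses_to_remove land statuses set to 0 (default islands and
#'   built-up urban areas)
#' @return a [binary_raster()]
#' @export
maskExclusions <- function(env, veg, statuses_to_remove = c("urban", "island")) {
  stop_if_grid_mismatch(env$grid, veg$grid, "envelope and vegetation")
  v <- env$values
  v[status_mask(veg, statuses_to_remove) == 1L] <- 0L
  binary_raster(v, env$grid,
                provenance = paste0(env$provenance, "; removed ",
                                    paste(statuses_to_remove, collapse = "+")))
}

#' Select favourable vegetation classes by within-envelope record counts
#'
#' Counts the full-precision (unrounded) presence records falling in each
#' vegetation class within the exclusion-masked envelope. Classes with at
#' least `min_records` records are selected, except water and cleared
#' (non-remnant) classes, which are never habitat. Records off-grid or
#' outside the envelope are skipped and counted.
#'
#' @param records_unrounded the vetted, full-precision [occurrenceSet()]
#' @param veg a `vegetation_layer`
#' @param env the exclusion-masked envelope ([binary_raster()])
#' @param min_records selection threshold (default 4, i.e. "three or fewer
#'   records are ignored")
#' @return a `class_selection`: per-class counts, the selected ids, and a
#'   report table (class_id, label, count, selected, reason)
#' @export
selectFavourableClasses <- function(records_unrounded, veg, env,
                                    min_records = 4) {
  stop_if_grid_mismatch(veg$grid, env$grid, "vegetation and envelope")
  loc <- locateCells(veg$grid, records_unrounded$lon, records_unrounded$lat)
  on <- loc$on_grid
  inside <- rep(FALSE, nrow(loc))
  inside[on] <- env$values[cbind(loc$row[on], loc$col[on])] == 1L
  cls <- rep(NA_integer_, nrow(loc))
  cls[inside] <- veg$class_raster[cbind(loc$row[inside], loc$col[inside])]

  meta <- veg$class_meta
  counts <- vapply(meta$class_id, function(id) sum(cls == id, na.rm = TRUE), 0L)
  never <- meta$status %in% c("water", "non_remnant")
  selected <- counts >= min_records & !never
  reason <- ifelse(selected, "selected",
                   ifelse(never, paste0("status:", meta$status),
                          sprintf("records<%d", min_records)))
  report <- data.frame(class_id = meta$class_id, label = meta$label,
                       count = counts, selected = selected, reason = reason,
                       stringsAsFactors = FALSE)
  structure(list(selected = meta$class_id[selected], counts = report,
                 min_records = min_records,
                 skipped_off_grid = sum(!on),
                 skipped_outside_envelope = sum(on & !inside)),
            class = "class_selection")
}

#' @export
print.class_selection <- function(x, ...) {
  cat(sprintf("class_selection: %d of %d classes selected (min %d records)\n",
              length(x$selected), nrow(x$counts), x$min_records))
  print(x$counts)
  invisible(x)
}

#' Buffer selected vegetation classes by a metric distance
#'
#' A cell is set iff its centre lies within Euclidean distance `distance` of
#' the centre of any selected-class cell (exact distance transform);
#' `distance = 0` returns the selected-class mask itself. Buffering is
#' extensive and monotone in distance.
#'
#' @param veg a `vegetation_layer`
#' @param selection a `class_selection` (or integer vector of class ids)
#' @param distance metres (default 1118, the radio-tracking movement scale)
#' @param base optional [binary_raster()] to buffer instead of the bare
#'   class mask (used to buffer `favourable AND envelope`)
#' @return a [binary_raster()]
#' @export
bufferClasses <- function(veg, selection, distance = 1118, base = NULL) {
  ids <- if (inherits(selection, "class_selection")) selection$selected
         else selection
  if (is.null(base)) {
    m <- matrix(0L, veg$grid$height, veg$grid$width)
    m[veg$class_raster %in% ids] <- 1L
  } else {
    stop_if_grid_mismatch(veg$grid, base$grid, "vegetation and base mask")
    m <- base$values
  }
  out <- dilateMask(m, distance, veg$grid$cell_size)
  binary_raster(out, veg$grid,
                provenance = sprintf("classes {%s} buffered %gm",
                                     paste(ids, collapse = ","), distance))
}

#' Build the habitat model
#'
#' `mask = buffer(favourable-classes AND envelope, distance)`. The buffer is
#' applied after the intersection and the result is not re-clipped to the
#' envelope, so buffered cells outside the climate envelope are retained.
#'
#' @param env_clipped exclusion-masked thresholded envelope
#' @param veg a `vegetation_layer`
#' @param selection a `class_selection`
#' @param distance buffer distance, metres (default 1118)
#' @param threshold,decimals provenance: the suitability threshold and
#'   thinning level behind the envelope
#' @return a `habitat_model`
#' @export
buildHabitatModel <- function(env_clipped, veg, selection, distance = 1118,
                              threshold = 0.5, decimals = NA) {
  ids <- selection$selected
  if (length(ids) == 0)
    warning("empty class selection: habitat model is empty", call. = FALSE)
  core <- matrix(0L, veg$grid$height, veg$grid$width)
  core[veg$class_raster %in% ids & env_clipped$values == 1L] <- 1L
  mask <- dilateMask(core, distance, veg$grid$cell_size)
  structure(list(mask = binary_raster(mask, veg$grid),
                 core = binary_raster(core, veg$grid),
                 favourable_classes = ids,
                 buffer_distance = distance,
                 threshold = threshold, decimals = decimals,
                 provenance = sprintf(
                   "threshold>=%g, decimals=%s, buffer=%gm, classes={%s}",
                   threshold, as.character(decimals), distance,
                   paste(ids, collapse = ","))),
            class = "habitat_model")
}

#' @export
print.habitat_model <- function(x, ...) {
  cat(sprintf("habitat_model: %.4g km^2 (%d favourable classes, %gm buffer)\n  %s\n",
              maskAreaKm2(x$mask), length(x$favourable_classes),
              x$buffer_distance, x$provenance))
  invisible(x)
}
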