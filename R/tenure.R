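#' Tenure overlay, conversion rates, priority zones and offset accounting
#'
#' The cumulative-impact question is answered by overlay arithmetic: how much
#' of the habitat model, and of each favourable vegetation class within it,
#' lies outside extant extractive or exploratory tenure; what fraction of
#' exploration-lease area converts to planned mine footprint; how much of
#' each offset-strategy priority zone is itself under tenure; and whether
#' enough cleared land of the right pre-clearing vegetation group exists —
#' within the species' movement distance of a mine — to rehabilitate as an
#' offset. All areas are exact cell arithmetic (cell-centre point-in-polygon,
#' union semantics over overlapping tenures), percentages print at one
#' decimal, half away from zero.
#'
#' @name tenure
NULL

#' Filter tenures extant at a date
#'
#' Keeps polygons with `grant_date <= as_of < expiry_date` (or no expiry),
#' plus explicitly whitelisted expired ids (expired exploration permits that
#' underpin later detailed mine plans). Rows with malformed dates are
#' rejected and logged.
#'
#' @param tenures a `tenure_layer`
#' @param as_of reference date (default 2015-09-07, the accounting date)
#' @param include_expired_ids ids retained regardless of expiry
#' @return a `tenure_layer`; rejected ids in `attr(, "rejected")`
#' @export
filterExtant <- function(tenures, as_of = as.Date("2015-09-07"),
                         include_expired_ids = character()) {
  as_of <- as.Date(as_of)
  if (is.na(as_of)) stop("invalid as_of date", call. = FALSE)
  rejected <- character()
  keep <- vapply(tenures$polygons, function(p) {
    g <- tryCatch(as.Date(p$grant_date), error = function(e) NA)
    e <- tryCatch(as.Date(p$expiry_date), error = function(e) NA)
    if (is.na(g)) { rejected <<- c(rejected, p$id); return(FALSE) }
    if (p$id %in% include_expired_ids) return(TRUE)
    g <= as_of && (is.na(e) || as_of < e)
  }, logical(1))
  out <- structure(list(polygons = tenures$polygons[keep], grid = tenures$grid),
                   class = "tenure_layer")
  attr(out, "rejected") <- rejected
  out
}

valid_ring <- function(ring) {
  is.matrix(ring) && ncol(ring) == 2 && all(is.finite(ring)) &&
    nrow(unique(ring)) >= 3
}

#' Rasterize a polygon layer with union semantics
#'
#' A cell is set iff its centre falls inside at least one polygon, so
#' overlapping tenures are never double counted. Invalid geometries are
#' skipped and logged.
#'
#' @param tenures a `tenure_layer`, `zone_layer`, or bare list of polygons
#' @param grid the target [grid_geometry()]
#' @param by_type also return one mask per `tenure_type`
#' @return a [binary_raster()] (the union); with `by_type`, a list with
#'   `union` and `by_type` masks. Skipped polygon ids in `attr(, "skipped")`.
#' @export
rasterizeUnion <- function(tenures, grid, by_type = FALSE) {
  polys <- if (is.list(tenures) && !is.null(tenures$polygons)) tenures$polygons
           else tenures
  cc <- cellCentres(grid)
  skipped <- character()
  inside <- lapply(polys, function(p) {
    if (!valid_ring(p$geometry)) {
      skipped <<- c(skipped, if (!is.null(p$id)) p$id else "<unnamed>")
      return(NULL)
    }
    points_in_ring(p$geometry, cc$x, cc$y)
  })
  as_mask <- function(flags) {
    m <- matrix(0L, grid$height, grid$width)
    if (length(flags)) m[cbind(cc$row[flags], cc$col[flags])] <- 1L
    m
  }
  union_flags <- Reduce(`|`, Filter(Negate(is.null), inside),
                        accumulate = FALSE) %||% logical(nrow(cc))
  u <- binary_raster(as_mask(union_flags), grid, provenance = "tenure union")
  attr(u, "skipped") <- skipped
  if (!by_type) return(u)
  types <- vapply(polys, function(p) p$tenure_type %||% "untyped", "")
  per_type <- lapply(split(seq_along(polys), types), function(ix) {
    flags <- Reduce(`|`, Filter(Negate(is.null), inside[ix]),
                    accumulate = FALSE) %||% logical(nrow(cc))
    binary_raster(as_mask(flags), grid)
  })
  list(union = u, by_type = per_type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tenure-free accounting of the habitat model
#'
#' The central overlay report: for each favourable vegetation class, the
#' area within the (unbuffered) envelope intersection, the part of it free
#' of any extant tenure, the percentage free and the recent-record count; a
#' totals row over classes; the same row for the buffered habitat model;
#' per-tenure-type areas within the habitat model (overlaps across types
#' permitted, so type areas may exceed the union); and protected-area
#' coverage of both the buffered model and the favourable classes alone.
#'
#' @param habitat a `habitat_model` (its `core` is the favourable-class AND
#'   envelope mask, its `mask` the buffered model)
#' @param veg the `vegetation_layer`
#' @param tenures a `tenure_layer` (already extant-filtered) or a
#'   [binary_raster()] union mask
#' @param protected optional protected-area polygons (list) or mask
#' @param recent recent records ([occurrenceSet()])
#' @return an `area_report`
#' @export
overlapReport <- function(habitat, veg, tenures, protected = NULL, recent) {
  grid <- veg$grid
  stop_if_grid_mismatch(habitat$mask$grid, grid, "habitat and vegetation")
  rz <- if (inherits(tenures, "binary_raster"))
    list(union = tenures, by_type = list())
  else rasterizeUnion(tenures, grid, by_type = TRUE)
  tu <- rz$union$values

  prot <- if (is.null(protected)) NULL
          else if (inherits(protected, "binary_raster")) protected
          else rasterizeUnion(protected, grid)

  loc <- locateCells(grid, recent$lon, recent$lat)
  ok <- loc$on_grid
  rec_cells <- cbind(loc$row[ok], loc$col[ok])

  cell_km2 <- grid$cell_size^2 / 1e6
  class_row <- function(id, label) {
    m <- (veg$class_raster == id & habitat$core$values == 1L)
    total <- sum(m) * cell_km2
    free <- sum(m & tu == 0L) * cell_km2
    n_rec <- sum(m[rec_cells])
    data.frame(class_id = id, label = label, total_km2 = total,
               free_km2 = free, pct_free = pct1(free, total),
               n_recent_records = n_rec, stringsAsFactors = FALSE)
  }
  ids <- habitat$favourable_classes
  labels <- veg$class_meta$label[match(ids, veg$class_meta$class_id)]
  per_class <- do.call(rbind, Map(class_row, ids, labels))

  tot_total <- sum(per_class$total_km2); tot_free <- sum(per_class$free_km2)
  hm <- habitat$mask$values
  hm_total <- sum(hm == 1L) * cell_km2
  hm_free <- sum(hm == 1L & tu == 0L) * cell_km2
  totals <- data.frame(
    row = c("TOTAL_CLASSES", "HABITAT_MODEL"),
    total_km2 = c(tot_total, hm_total),
    free_km2 = c(tot_free, hm_free),
    pct_free = c(pct1(tot_free, tot_total), pct1(hm_free, hm_total)),
    n_recent_records = c(sum(per_class$n_recent_records),
                         sum(hm[rec_cells] == 1L)),
    stringsAsFactors = FALSE)

  by_type <- if (length(rz$by_type))
    data.frame(tenure_type = names(rz$by_type),
               area_in_model_km2 = vapply(rz$by_type, function(m)
                 sum(m$values == 1L & hm == 1L) * cell_km2, 0),
               stringsAsFactors = FALSE)
  else data.frame(tenure_type = character(), area_in_model_km2 = numeric())
  rownames(by_type) <- NULL

  protected_row <- if (!is.null(prot)) {
    pv <- prot$values
    buf_km2 <- sum(pv == 1L & hm == 1L) * cell_km2
    core_km2 <- sum(pv == 1L & habitat$core$values == 1L) * cell_km2
    n_in <- sum(pv[rec_cells] == 1L & hm[rec_cells] == 1L)
    list(area_km2 = buf_km2, core_area_km2 = core_km2,
         pct_of_model = pct1(buf_km2, hm_total), n_records_inside = n_in)
  } else NULL

  structure(list(per_class = per_class, totals = totals,
                 per_tenure_type = by_type, protected = protected_row,
                 dropped_records = sum(!ok)),
            class = "area_report")
}

#' @export
print.area_report <- function(x, ...) {
  cat("area_report\n")
  print(x$per_class, row.names = FALSE)
  print(x$totals, row.names = FALSE)
  if (nrow(x$per_tenure_type)) print(x$per_tenure_type, row.names = FALSE)
  if (!is.null(x$protected))
    cat(sprintf("protected: %.4g km^2 (%.1f%% of model), %d records inside\n",
                x$protected$area_km2, x$protected$pct_of_model,
                x$protected$n_records_inside))
  invisible(x)
}

#' Percentage of an area free of tenure, at printed precision
#'
#' Worked-example arithmetic for accounting tables: `100 * free / total`,
#' one decimal, half away from zero.
#' @param total_km2,free_km2 areas
#' @export
areaPctFree <- function(total_km2, free_km2) pct1(free_km2, total_km2)

#' Lease-to-footprint conversion rates
#'
#' Rows sharing a `group` pool their lease areas against that group's single
#' affected-area figure (proponents sharing portions of one exploration
#' permit are assessed together): per group
#' `pct_affected = 100 * affected / sum(lease areas)`, plus overall totals.
#'
#' @param table data.frame with columns `group`, `tenement_id`,
#'   `lease_area_ha`, `affected_area_ha` (one non-NA value per group)
#' @return a `conversion_report`: per-group table and totals
#' @export
footprintConversion <- function(table) {
  if (any(table$lease_area_ha < 0, na.rm = TRUE))
    stop("lease areas must be >= 0", call. = FALSE)
  groups <- split(table, table$group)
  rows <- lapply(groups, function(g) {
    lease <- sum(g$lease_area_ha)
    if (lease == 0) stop("zero lease area in group ", g$group[1], call. = FALSE)
    affected <- stats::na.omit(g$affected_area_ha)
    if (length(affected) != 1)
      stop("group ", g$group[1], " needs exactly one affected-area figure",
           call. = FALSE)
    data.frame(group = g$group[1], n_leases = nrow(g),
               lease_area_ha = lease, affected_area_ha = as.numeric(affected),
               pct_affected = pct1(affected, lease),
               stringsAsFactors = FALSE)
  })
  per_group <- do.call(rbind, rows)
  rownames(per_group) <- NULL
  tot_lease <- sum(per_group$lease_area_ha)
  tot_aff <- sum(per_group$affected_area_ha)
  structure(list(per_group = per_group,
                 totals = data.frame(lease_area_ha = tot_lease,
                                     affected_area_ha = tot_aff,
                                     pct_affected = pct1(tot_aff, tot_lease))),
            class = "conversion_report")
}

#' @export
print.conversion_report <- function(x, ...) {
  cat("conversion_report\n")
  print(x$per_group, row.names = FALSE)
  cat(sprintf("TOTAL: %s ha leased, %s ha affected, %.1f%%\n",
              format(x$totals$lease_area_ha, big.mark = ","),
              format(x$totals$affected_area_ha, big.mark = ","),
              x$totals$pct_affected))
  invisible(x)
}

#' Priority-zone tenure accounting
#'
#' Per zone: total area, area outside the tenure union, percentage outside;
#' an overall row over all zones; and the strategy-deficit comparison — the
#' extent of Priority 1 (high conservation value) under tenure against the
#' extent of Priority 3 (offset candidates) free of tenure, flagged when the
#' former exceeds the latter (a 1:1 offset is then impossible).
#'
#' @param zones a `zone_layer`
#' @param tenure_union a [binary_raster()] (the extant tenure union)
#' @param grid the [grid_geometry()]
#' @return a `priority_report`
#' @export
priorityZoneReport <- function(zones, tenure_union, grid) {
  cell_km2 <- grid$cell_size^2 / 1e6
  tu <- tenure_union$values
  rows <- lapply(zones$polygons, function(z) {
    zm <- rasterizeUnion(list(z), grid)$values
    area <- sum(zm == 1L) * cell_km2
    outside <- sum(zm == 1L & tu == 0L) * cell_km2
    data.frame(priority = z$priority, area_km2 = area,
               outside_km2 = outside, pct_outside = pct1(outside, area),
               stringsAsFactors = FALSE)
  })
  per_zone <- if (length(rows)) do.call(rbind, rows)
              else data.frame(priority = integer(), area_km2 = numeric(),
                              outside_km2 = numeric(), pct_outside = numeric())
  tot <- sum(per_zone$area_km2); out <- sum(per_zone$outside_km2)
  p1_under <- if (1 %in% per_zone$priority)
    per_zone$area_km2[per_zone$priority == 1] -
      per_zone$outside_km2[per_zone$priority == 1] else NA_real_
  p3_free <- if (3 %in% per_zone$priority)
    per_zone$outside_km2[per_zone$priority == 3] else NA_real_
  structure(list(per_zone = per_zone,
                 overall = data.frame(area_km2 = tot, outside_km2 = out,
                                      pct_outside = pct1(out, tot)),
                 p1_under_tenure_km2 = p1_under,
                 p3_free_km2 = p3_free,
                 offset_deficit = isTRUE(p1_under > p3_free)),
            class = "priority_report")
}

#' @export
print.priority_report <- function(x, ...) {
  cat("priority_report\n")
  print(x$per_zone, row.names = FALSE)
  cat(sprintf("overall: %.4g of %.4g km^2 outside tenure (%.1f%%)\n",
              x$overall$outside_km2, x$overall$area_km2, x$overall$pct_outside))
  if (!is.na(x$p1_under_tenure_km2))
    cat(sprintf("P1 under tenure %.4g km^2 vs P3 free %.4g km^2%s\n",
                x$p1_under_tenure_km2, x$p3_free_km2,
                if (x$offset_deficit) " -- OFFSET DEFICIT" else ""))
  invisible(x)
}

#' Offset-sufficiency ledger
#'
#' How much cleared (non-remnant) land of the target pre-clearing broad
#' vegetation groups lies within the climate envelope — the land that could
#' be rehabilitated as habitat — and how much of it lies within the species'
#' recorded movement distance of a mine's boundary, against the offset area
#' the approval requires.
#'
#' @param veg the `vegetation_layer`
#' @param envelope the thresholded climate envelope ([binary_raster()])
#' @param impact_polygon the mine footprint (n x 2 ring) or a polygon list
#'   entry with `$geometry`
#' @param required_km2 offset area required by the approval
#' @param radius_km movement radius (default 16 km)
#' @param target_broad_groups pre-clearing broad groups restorable as
#'   habitat; must exist in the class metadata
#' @param exclude_tenure optional tenure-union [binary_raster()]; when given,
#'   cells under tenure are not counted as available
#' @return an `offset_ledger`
#' @export
offsetSufficiency <- function(veg, envelope, impact_polygon, required_km2,
                              radius_km = 16, target_broad_groups,
                              exclude_tenure = NULL) {
  if (radius_km < 0) stop("radius must be >= 0", call. = FALSE)
  if (required_km2 < 0) stop("required area must be >= 0", call. = FALSE)
  known <- unique(veg$class_meta$broad_group)
  if (!all(target_broad_groups %in% known))
    stop("unknown broad group(s): ",
         paste(setdiff(target_broad_groups, known), collapse = ", "),
         call. = FALSE)
  grid <- veg$grid
  cell_km2 <- grid$cell_size^2 / 1e6
  ids <- veg$class_meta$class_id[
    veg$class_meta$status == "non_remnant" &
      veg$class_meta$broad_group %in% target_broad_groups]
  cleared <- matrix(veg$class_raster %in% ids, grid$height, grid$width) &
    envelope$values == 1L
  if (!is.null(exclude_tenure)) avail_base <- cleared & exclude_tenure$values == 0L
  else avail_base <- cleared

  ring <- if (is.list(impact_polygon)) impact_polygon$geometry else impact_polygon
  imp <- rasterizeUnion(list(list(geometry = ring, id = "impact")), grid)$values
  near <- dilateMask(imp, radius_km * 1000, grid$cell_size)

  cleared_km2 <- sum(cleared) * cell_km2
  avail_km2 <- sum(avail_base & near == 1L) * cell_km2
  per_group <- vapply(target_broad_groups, function(bg) {
    gids <- veg$class_meta$class_id[veg$class_meta$status == "non_remnant" &
                                      veg$class_meta$broad_group == bg]
    sum(matrix(veg$class_raster %in% gids, grid$height, grid$width) &
          envelope$values == 1L) * cell_km2
  }, 0)
  structure(list(cleared_favourable_km2 = cleared_km2,
                 cleared_by_group_km2 = per_group,
                 required_offset_km2 = required_km2,
                 available_within_radius_km2 = avail_km2,
                 movement_radius_km = radius_km,
                 required_pct_of_cleared = pct1(required_km2,
                                                max(cleared_km2, .Machine$double.eps)),
                 sufficient_within_radius = avail_km2 >= required_km2,
                 sufficient_overall = cleared_km2 >= required_km2),
            class = "offset_ledger")
}

#' @export
print.offset_ledger <- function(x, ...) {
  cat("offset_ledger\n")
  cat(sprintf("  cleared favourable land in envelope: %.4g km^2\n",
              x$cleared_favourable_km2))
  cat(sprintf("  required offset: %.4g km^2 (%.1f%% of cleared extent)\n",
              x$required_offset_km2, x$required_pct_of_cleared))
  cat(sprintf("  available within %g km of the impact: %.4g km^2 -> %s\n",
              x$movement_radius_km, x$available_within_radius_km2,
              if (x$sufficient_within_radius) "sufficient"
              else "INSUFFICIENT"))
  invisible(x)
}
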