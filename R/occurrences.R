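#' Occurrence records: vetting and rounding-based spatial thinning
#'
#' Raw occurrence records for a presence-only model arrive from heterogeneous
#' sources (atlases, recovery-team databases, impact statements) and carry
#' misidentifications, out-of-range ambiguous records and positional errors.
#' Vetting removes these by rule, itemising every removal. Spatial thinning
#' then mitigates sampling bias: coordinates are rounded to a fixed number of
#' decimals, duplicate rounded locations are collapsed to one record, and —
#' crucially — the retained records keep their original full-precision
#' coordinates for model fitting.
#'
#' @name occurrences
NULL

#' Construct an occurrence set
#'
#' @param records data.frame with columns `taxon`, `lon`, `lat` and
#'   optionally `id`, `year`, `source`
#' @param crs_tag text tag naming the coordinate reference
#' @return an `occurrence_set` (a data.frame subclass)
#' @export
occurrenceSet <- function(records, crs_tag = "unknown") {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!all(c("taxon", "lon", "lat") %in% names(df)))
    stop("records need columns taxon, lon, lat", call. = FALSE)
  if (is.null(df$id)) df$id <- sprintf("rec-%05d", seq_len(nrow(df)))
  if (anyDuplicated(df$id)) stop("record ids must be unique", call. = FALSE)
  if (is.null(df$year)) df$year <- NA_integer_
  if (is.null(df$source)) df$source <- ""
  df <- df[, c("id", "taxon", "lon", "lat", "year", "source")]
  rownames(df) <- NULL
  structure(df, crs_tag = crs_tag,
            class = c("occurrence_set", "data.frame"))
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d records, %d taxa [%s]\n",
              nrow(x), length(unique(x$taxon)), attr(x, "crs_tag")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Vetting rules for raw occurrence records
#'
#' @param accepted_taxa taxa retained; anything else is removed under the
#'   `taxon` rule
#' @param ambiguous_taxa taxa subject to the latitude cutoff (e.g. records of
#'   unspecified subspecies)
#' @param latitude_cutoff latitude (same units as record `lat`) beyond which
#'   ambiguous-taxon records are removed; NA disables the rule
#' @param poleward `"north"` removes ambiguous records with
#'   `lat > cutoff`, `"south"` those with `lat < cutoff`
#' @param exclusion_regions list of polygons (each a list with `name` and
#'   `geometry`, an n x 2 ring) — e.g. the ocean; records inside are removed
#' @param explicit_exclusion_ids record ids removed unconditionally
#' @return a `vetting_rules` object
#' @export
vettingRules <- function(accepted_taxa = NULL, ambiguous_taxa = character(),
                         latitude_cutoff = NA_real_, poleward = "north",
                         exclusion_regions = list(),
                         explicit_exclusion_ids = character()) {
  poleward <- match.arg(poleward, c("north", "south"))
  structure(list(accepted_taxa = accepted_taxa,
                 ambiguous_taxa = ambiguous_taxa,
                 latitude_cutoff = latitude_cutoff,
                 poleward = poleward,
                 exclusion_regions = exclusion_regions,
                 explicit_exclusion_ids = explicit_exclusion_ids),
            class = "vetting_rules")
}

points_in_ring <- function(ring, x, y) {
  if (!isTRUE(all(ring[1, ] == ring[nrow(ring), ])))
    ring <- rbind(ring, ring[1, ])
  mgcv::in.out(ring, cbind(x, y))
}

#' Vet raw occurrence records
#'
#' Applies the rules in order — unparseable coordinates, explicit
#' exclusions, taxon acceptance, the ambiguous-taxon latitude cutoff,
#' exclusion regions — removing matching records and itemising every removal
#' by rule in the attached report. Idempotent: vetting already-vetted records
#' removes nothing.
#'
#' @param raw an [occurrenceSet()]
#' @param rules a [vettingRules()]
#' @return the vetted `occurrence_set`; the removal report
#'   (data.frame rule/count plus per-record detail) is in
#'   `attr(, "vetting_report")`
#' @export
vetRecords <- function(raw, rules) {
  if (is.null(raw)) stop("raw occurrence set is required", call. = FALSE)
  df <- as.data.frame(raw)
  removed <- data.frame(id = character(), rule = character(),
                        stringsAsFactors = FALSE)
  drop <- function(which, rule) {
    if (any(which)) {
      removed <<- rbind(removed, data.frame(id = df$id[which], rule = rule,
                                            stringsAsFactors = FALSE))
      df <<- df[!which, , drop = FALSE]
    }
  }
  drop(!is.finite(df$lon) | !is.finite(df$lat), "unparseable")
  drop(df$id %in% rules$explicit_exclusion_ids, "explicit")
  if (!is.null(rules$accepted_taxa))
    drop(!(df$taxon %in% rules$accepted_taxa), "taxon")
  if (!is.na(rules$latitude_cutoff) && length(rules$ambiguous_taxa)) {
    amb <- df$taxon %in% rules$ambiguous_taxa
    beyond <- if (rules$poleward == "north") df$lat > rules$latitude_cutoff
              else df$lat < rules$latitude_cutoff
    drop(amb & beyond, "latitude_cutoff")
  }
  for (region in rules$exclusion_regions)
    if (nrow(df))
      drop(points_in_ring(region$geometry, df$lon, df$lat), "exclusion_region")

  out <- occurrenceSet(df, crs_tag = attr(raw, "crs_tag"))
  tab <- table(removed$rule)
  counts <- data.frame(rule = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
  attr(out, "vetting_report") <- list(counts = counts, removed = removed,
                                      n_in = nrow(raw), n_out = nrow(out))
  out
}

round_away <- function(x, decimals) {
  sign(x) * floor(abs(x) * 10^decimals + 0.5 + sqrt(.Machine$double.eps)) /
    10^decimals
}

#' Thin occurrences by coordinate rounding
#'
#' Rounds each record's coordinates to `decimals` places (half away from
#' zero), keeps the first record per distinct rounded pair in input order,
#' and retains the original full-precision coordinates of the keepers.
#' Idempotent: re-thinning the retained set at the same decimals drops
#' nothing, and coarser rounding can only merge more keys, so
#' `|retained(2)| <= |retained(3)|` on any input.
#'
#' @param records an [occurrenceSet()]
#' @param decimals rounding precision (>= 0); 2 is ~700 m and 3 ~70 m at the
#'   study latitudes when coordinates are in degrees
#' @param degree_size coordinate units per "degree": coordinates are divided
#'   by this before rounding, so metre-based synthetic coordinates can be
#'   thinned at degree-like scales (the pipeline uses 1e5 m, making 2 and 3
#'   decimals merge 1000 m and 100 m blocks). Default 1: coordinates are
#'   already degrees.
#' @return a `thinned_occurrences`: `retained` set, `decimals`,
#'   `rounded_keys` and `dropped_count`
#' @export
thinByRounding <- function(records, decimals, degree_size = 1) {
  if (decimals < 0) stop("decimals must be >= 0", call. = FALSE)
  df <- as.data.frame(records)
  keys <- paste(sprintf("%.*f", decimals, round_away(df$lon / degree_size, decimals)),
                sprintf("%.*f", decimals, round_away(df$lat / degree_size, decimals)),
                sep = "|")
  keep <- !duplicated(keys)
  retained <- occurrenceSet(df[keep, , drop = FALSE],
                            crs_tag = attr(records, "crs_tag"))
  structure(list(retained = retained,
                 decimals = as.integer(decimals),
                 rounded_keys = keys[keep],
                 dropped_count = sum(!keep)),
            class = "thinned_occurrences")
}

#' @export
print.thinned_occurrences <- function(x, ...) {
  cat(sprintf("thinned_occurrences: %d retained at %d decimals (%d dropped)\n",
              nrow(x$retained), x$decimals, x$dropped_count))
  invisible(x)
}

#' Split records at a year cutoff
#'
#' `recent` holds records with `year >= year_cutoff`; records with missing
#' year go to `older` (they stay available for model fitting but cannot
#' anchor a recency-based omission check).
#'
#' @param records an [occurrenceSet()]
#' @param year_cutoff inclusive lower bound for "recent" (default 2000)
#' @return list with `recent` and `older` occurrence sets
#' @export
splitRecent <- function(records, year_cutoff = 2000) {
  df <- as.data.frame(records)
  is_recent <- !is.na(df$year) & df$year >= year_cutoff
  crs <- attr(records, "crs_tag")
  list(recent = occurrenceSet(df[is_recent, , drop = FALSE], crs_tag = crs),
       older = occurrenceSet(df[!is_recent, , drop = FALSE], crs_tag = crs))
}
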