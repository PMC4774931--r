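#' End-to-end pipeline on a synthetic landscape
#'
#' One call runs every stage in order — landscape generation, vetting,
#' thinning at one or both decimal levels, envelope fitting and prediction,
#' thresholding, exclusion masking, favourable-class selection, buffering,
#' the two-model comparison, the tenure overlay and priority-zone reports,
#' and the offset-sufficiency ledger — under a single root seed with named
#' per-stage substreams, so any stage can be re-run in isolation and results
#' are byte-reproducible.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Every defaulted constant is a study parameter: the 0.5 suitability
#' threshold, the 1118 m buffer, the minimum of 4 within-envelope records
#' for a favourable class ("three or fewer are ignored"), the year-2000
#' recency cutoff, the 2015-09-07 tenure as-of date, and the 16 km offset
#' search radius.
#'
#' @param decimals `"both"`, `2` or `3`: thinning level(s) to run
#' @param threshold suitability threshold in \[0, 1\]
#' @param features Maxent feature classes
#' @param beta Maxent regularization multiplier
#' @param buffer_m habitat buffer distance, metres
#' @param min_records favourable-class selection threshold
#' @param year_cutoff recency cutoff (inclusive)
#' @param as_of tenure accounting date
#' @param whitelist expired tenure ids retained by the extant filter
#' @param offsets_radius_km movement radius for the offset search
#' @param offsets_required_km2 offset area required by the approval scenario
#' @param target_broad_groups pre-clearing broad groups restorable as habitat
#' @param thin_degree_m metres per "degree" for thinning synthetic planar
#'   coordinates: at the default 1e5, two- and three-decimal rounding merge
#'   1000 m and 100 m blocks, the planar analogues of the ~700 m and ~70 m
#'   that those roundings represent in geographic degrees
#' @param seed root seed for the run
#' @return a `pipeline_config`
#' @export
pipelineConfig <- function(decimals = "both", threshold = 0.5,
                           features = c("linear", "quadratic"), beta = 1,
                           buffer_m = 1118, min_records = 4,
                           year_cutoff = 2000, as_of = "2015-09-07",
                           whitelist = character(),
                           offsets_radius_km = 16, offsets_required_km2 = 5,
                           target_broad_groups = "ironbark_sandplain",
                           thin_degree_m = 1e5, seed = 1L) {
  if (!identical(decimals, "both") && !decimals %in% c(2, 3))
    stop('decimals must be "both", 2 or 3', call. = FALSE)
  if (threshold < 0 || threshold > 1) stop("threshold in [0,1]", call. = FALSE)
  structure(list(decimals = decimals, threshold = threshold,
                 features = features, beta = beta, buffer_m = buffer_m,
                 min_records = min_records, year_cutoff = year_cutoff,
                 as_of = as.character(as_of), whitelist = whitelist,
                 offsets_radius_km = offsets_radius_km,
                 offsets_required_km2 = offsets_required_km2,
                 target_broad_groups = target_broad_groups,
                 thin_degree_m = thin_degree_m,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialise / reload a pipeline config (YAML)
#'
#' @param config a [pipelineConfig()]
#' @param path file path
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  x$whitelist <- as.character(unlist(x$whitelist))
  x$features <- as.character(unlist(x$features))
  do.call(pipelineConfig, x)
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Run the full pipeline on a synthetic landscape
#'
#' @param config a [pipelineConfig()]
#' @param spec a [landscapeSpec()]; its seed is overridden by the config's
#' @return a `report_bundle` (see Details) with every stage's outputs and a
#'   provenance record (config hash, seed)
#' @details The bundle contains: `landscape` (climate, vegetation, bias,
#'   true model, tenures, zones), `occurrences` (raw, vetted, recent/older
#'   split), per-decimals `models` (thinned set, envelope model, suitability,
#'   AUC, clipped envelope, class selection, habitat model), `comparison`
#'   (when both levels ran), `chosen` (the adopted model), and the
#'   `overlay`, `priority` and `offsets` reports.
#' @export
runPipeline <- function(config, spec = landscapeSpec(seed = config$seed)) {
  spec$seed <- config$seed
  climate <- generateClimateStack(spec)
  veg <- generateVegetationLayer(spec)
  bias <- biasSurface(veg, spec$bias_strength)
  truth <- trueModel(spec, climate, veg)
  occ_raw <- sampleOccurrences(truth, veg, bias, spec$n_presences,
                               seed = substream_seed(spec$seed, "occurrences"),
                               invalid_fraction = spec$invalid_fraction,
                               year_range = spec$year_range)
  background <- generateBackground(spec, veg, bias)
  tenures <- generateTenureLayer(spec, as_of = as.Date(config$as_of))
  zones <- generatePriorityZones(spec)

  vetted <- vetRecords(occ_raw, defaultVettingRules(spec))
  split <- splitRecent(vetted, config$year_cutoff)

  levels <- if (identical(config$decimals, "both")) c(2L, 3L)
            else as.integer(config$decimals)
  models <- lapply(levels, function(d) {
    thin <- thinByRounding(vetted, d, degree_size = config$thin_degree_m)
    training <- assembleTraining(thin, background, climate,
                                 feature_spec = config$features, decimals = d,
                                 degree_size = config$thin_degree_m)
    model <- fitMaxent(training, beta = config$beta,
                       seed = substream_seed(spec$seed, paste0("fit", d)))
    suit <- predictSuitability(model, climate)
    env <- thresholdEnvelope(suit, config$threshold)
    env_clip <- maskExclusions(env, veg)
    sel <- selectFavourableClasses(vetted, veg, env_clip,
                                   min_records = config$min_records)
    habitat <- buildHabitatModel(env_clip, veg, sel,
                                 distance = config$buffer_m,
                                 threshold = config$threshold, decimals = d)
    list(decimals = d, thinned = thin, model = model, suitability = suit,
         auc = evaluateAUC(suit, thin, background),
         envelope = env, envelope_clipped = env_clip,
         selection = sel, habitat = habitat)
  })
  names(models) <- paste0("d", levels)

  comparison <- if (length(models) == 2)
    compareModels(models[[1]]$habitat, models[[2]]$habitat,
                  split$recent, background)
  else NULL
  chosen <- models[[length(models)]]      # the finer-thinned (3 dp) model

  extant <- filterExtant(tenures, as.Date(config$as_of), config$whitelist)
  overlay <- overlapReport(chosen$habitat, veg, extant,
                           protected = NULL, recent = split$recent)
  tu <- rasterizeUnion(extant, spec$grid)
  priority <- priorityZoneReport(zones, tu, spec$grid)

  # impact scenario: the largest extant extraction-stage tenure (ML/MDL),
  # falling back to the largest extant tenure of any type
  impact <- pick_impact_polygon(extant)
  offsets <- if (!is.null(impact))
    offsetSufficiency(veg, chosen$envelope_clipped, impact,
                      required_km2 = config$offsets_required_km2,
                      radius_km = config$offsets_radius_km,
                      target_broad_groups = config$target_broad_groups)
  else NULL

  structure(list(spec = spec, config = config,
                 landscape = list(climate = climate, vegetation = veg,
                                  bias = bias, truth = truth,
                                  tenures = tenures, zones = zones),
                 occurrences = list(raw = occ_raw, vetted = vetted,
                                    recent = split$recent, older = split$older),
                 background = background,
                 models = models, comparison = comparison, chosen = chosen,
                 overlay = overlay, priority = priority, offsets = offsets,
                 provenance = list(config_hash = config_hash(config),
                                   seed = config$seed)),
            class = "report_bundle")
}

ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

pick_impact_polygon <- function(tenures) {
  if (length(tenures$polygons) == 0) return(NULL)
  types <- vapply(tenures$polygons, `[[`, "", "tenure_type")
  cand <- which(types %in% c("ML", "MDL"))
  if (length(cand) == 0) cand <- seq_along(tenures$polygons)
  areas <- vapply(tenures$polygons[cand], function(p) ring_area(p$geometry), 0)
  tenures$polygons[[cand[which.max(areas)]]]
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("report_bundle (seed %d, config %s)\n",
              x$provenance$seed, x$provenance$config_hash))
  for (m in x$models)
    cat(sprintf("  %d dp: %d records thinned, AUC %.3f, habitat %.4g km^2\n",
                m$decimals, nrow(m$thinned$retained), m$auc,
                maskAreaKm2(m$habitat$mask)))
  cat(sprintf("  overlay: %.1f%% of habitat model tenure-free\n",
              x$overlay$totals$pct_free[2]))
  if (!is.null(x$offsets))
    cat(sprintf("  offsets: %.4g km^2 cleared, %.4g km^2 within %g km\n",
                x$offsets$cleared_favourable_km2,
                x$offsets$available_within_radius_km2,
                x$offsets$movement_radius_km))
  invisible(x)
}

#' Write a report bundle's tables to CSV
#'
#' Persists the stage reports (vetting counts, per-decimals summary, class
#' selection, overlay per-class and totals, priority zones, offset ledger)
#' as CSVs under `dir`, byte-stable for a fixed config and seed.
#'
#' @param bundle a `report_bundle`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeReportBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(attr(bundle$occurrences$vetted, "vetting_report")$counts, "vetting.csv")
  model_rows <- do.call(rbind, lapply(bundle$models, function(m)
    data.frame(decimals = m$decimals,
               n_retained = nrow(m$thinned$retained),
               auc = m$auc,
               envelope_km2 = maskAreaKm2(m$envelope_clipped),
               habitat_km2 = maskAreaKm2(m$habitat$mask))))
  w(model_rows, "models.csv")
  w(bundle$chosen$selection$counts, "class_selection.csv")
  w(bundle$overlay$per_class, "overlay_per_class.csv")
  w(bundle$overlay$totals, "overlay_totals.csv")
  w(bundle$overlay$per_tenure_type, "overlay_by_type.csv")
  w(bundle$priority$per_zone, "priority_zones.csv")
  if (!is.null(bundle$comparison)) {
    cmp <- bundle$comparison
    w(data.frame(model = c("a", "b"),
                 area_km2 = c(cmp$a$area_km2, cmp$b$area_km2),
                 omission_pct = c(cmp$a$omission_pct, cmp$b$omission_pct),
                 background_inside = c(cmp$a$background_inside,
                                       cmp$b$background_inside),
                 area_ratio = cmp$area_ratio,
                 omission_pct_difference = cmp$omission_pct_difference,
                 recommendation = cmp$recommendation),
      "comparison.csv")
  }
  if (!is.null(bundle$offsets))
    w(data.frame(cleared_favourable_km2 = bundle$offsets$cleared_favourable_km2,
                 required_offset_km2 = bundle$offsets$required_offset_km2,
                 available_within_radius_km2 =
                   bundle$offsets$available_within_radius_km2,
                 movement_radius_km = bundle$offsets$movement_radius_km,
                 required_pct_of_cleared = bundle$offsets$required_pct_of_cleared,
                 sufficient_within_radius = bundle$offsets$sufficient_within_radius),
      "offset_ledger.csv")
  writeLines(c(sprintf("config_hash: %s", bundle$provenance$config_hash),
               sprintf("seed: %d", bundle$provenance$seed)),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}
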