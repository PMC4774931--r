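#' Synthetic landscapes with known ground truth
#'
#' Every downstream stage of the pipeline (envelope fitting, habitat
#' refinement, tenure overlay, offset accounting) is exercised on landscapes
#' built here: an 8-layer climate stack of smooth gradients, a patchy
#' vegetation mosaic with remnant/non-remnant/water/urban/island statuses, a
#' known logistic true-suitability surface, presence records sampled from it
#' under an urban-proximity observation bias, a multi-species target-group
#' background sharing that bias, and dated, typed tenure polygons. All
#' generators are fully deterministic given the spec seed; each stage draws
#' from its own named substream so adding records never perturbs tenures.
#'
#' @name synthlandscape
NULL

# -- deterministic substreams --------------------------------------------

substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# -- smooth random fields -------------------------------------------------

# white noise smoothed with a separable Gaussian kernel, reflection-padded;
# rescaled to zero mean, unit sd
smooth_field <- function(height, width, range_cells = 6) {
  z <- matrix(stats::rnorm(height * width), height, width)
  s <- max(range_cells, 1)
  half <- ceiling(3 * s)
  k <- stats::dnorm(seq(-half, half), sd = s)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    padded <- c(rev(v[seq_len(min(half, n))]), v,
                rev(v[seq.int(n, by = -1, length.out = min(half, n))]))
    while (length(padded) < n + 2 * half) padded <- c(padded[1], padded, padded[length(padded)])
    stats::convolve(padded, rev(k), type = "filter")[seq_len(n) + (length(padded) - 2 * half - n)]
  }
  z <- apply(z, 2, pad_conv)
  z <- t(apply(z, 1, pad_conv))
  (z - mean(z)) / stats::sd(z)
}

# -- landscape spec -------------------------------------------------------

#' Specification of a synthetic landscape
#'
#' Defaults describe the study conditions the pipeline is tested under:
#' 250 m cells (the analysis resolution), 500 presence records, a
#' seven-species target-group background of 300 points per species, an
#' urban-proximity sampling bias of unit strength, ten vegetation classes,
#' and a land-status mix dominated by remnant woodland with a cleared
#' (non-remnant) quarter, minor water, urban and island fractions.
#'
#' @param grid_width,grid_height grid dimensions in cells (>= 8 each)
#' @param cell_size metres (default 250)
#' @param origin planar (x, y) of the grid corner, metres
#' @param seed integer; fully determines every generated artefact
#' @param n_presences number of presence records to draw
#' @param n_background_per_species background points per target-group species
#' @param n_species_background number of target-group species
#' @param bias_strength dimensionless >= 0; 0 = unbiased sampling
#' @param n_veg_classes total vegetation classes (>= 5)
#' @param fractions named areal fractions over statuses
#'   remnant/non_remnant/water/urban/island, summing to 1
#' @param invalid_fraction fraction of presence records deliberately injected
#'   as invalid (wrong taxon, in-ocean, out-of-range) to exercise vetting
#' @param year_range inclusive record-year range
#' @param n_tenures number of tenure polygons to generate
#' @return a `landscape_spec`
#' @export
landscapeSpec <- function(grid_width = 64, grid_height = 64, cell_size = 250,
                          origin = c(0, 0), seed = 1,
                          n_presences = 500,
                          n_background_per_species = 300,
                          n_species_background = 7,
                          bias_strength = 1,
                          n_veg_classes = 10,
                          fractions = c(remnant = 0.55, non_remnant = 0.25,
                                        water = 0.07, urban = 0.08, island = 0.05),
                          invalid_fraction = 0.05,
                          year_range = c(1980, 2015),
                          n_tenures = 12) {
  if (grid_width < 8 || grid_height < 8)
    stop("grid dimensions must be at least 8 x 8", call. = FALSE)
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  need <- c("remnant", "non_remnant", "water", "urban", "island")
  if (!all(need %in% names(fractions)))
    stop("fractions must name all of: ", paste(need, collapse = ", "), call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("areal fractions must sum to 1", call. = FALSE)
  if (bias_strength < 0) stop("bias_strength must be >= 0", call. = FALSE)
  if (n_veg_classes < 5) stop("need at least 5 vegetation classes", call. = FALSE)
  structure(list(grid = grid_geometry(grid_width, grid_height, cell_size, origin),
                 seed = as.integer(seed),
                 n_presences = n_presences,
                 n_background_per_species = n_background_per_species,
                 n_species_background = n_species_background,
                 bias_strength = bias_strength,
                 n_veg_classes = as.integer(n_veg_classes),
                 fractions = fractions[need],
                 invalid_fraction = invalid_fraction,
                 year_range = year_range,
                 n_tenures = n_tenures),
            class = "landscape_spec")
}

#' @export
print.landscape_spec <- function(x, ...) {
  cat(sprintf("landscape_spec: %dx%d @ %gm, seed %d, %d presences, bias %g\n",
              x$grid$width, x$grid$height, x$grid$cell_size, x$seed,
              x$n_presences, x$bias_strength))
  invisible(x)
}

# -- climate --------------------------------------------------------------

climate_layer_names <- c("annual_mean_temp", "temp_seasonality",
                         "max_temp_warmest", "min_temp_coldest",
                         "annual_precip", "precip_wettest",
                         "precip_driest", "precip_seasonality")

#' Analytic defining gradient of a synthetic climate layer
#'
#' Layer `i` is built around a planar gradient at angle `(i-1) * pi / 8`
#' across the normalised grid; this returns that gradient alone, so the
#' generated layer can be checked against its noiseless definition.
#'
#' @param spec a [landscapeSpec()]
#' @param i layer index 1..8
#' @return matrix (height x width) in \[0, 1\]
#' @export
climateGradient <- function(spec, i) {
  g <- spec$grid
  xn <- matrix(rep((seq_len(g$width) - 0.5) / g$width, each = g$height),
               g$height, g$width)
  yn <- matrix(rep((seq_len(g$height) - 0.5) / g$height, times = g$width),
               g$height, g$width)
  th <- (i - 1) * pi / 8
  f <- cos(th) * xn + sin(th) * yn
  (f - min(f)) / (max(f) - min(f))
}

# plausible output units per layer (affine transform of the unit gradient)
climate_layer_scale <- data.frame(
  name = climate_layer_names,
  offset = c(18, 1.2, 28, 5, 400, 120, 5, 40),
  range  = c(10, 0.8, 10, 10, 800, 260, 30, 60))

#' Generate the 8-layer synthetic climate stack
#'
#' Each layer is a smooth planar gradient in its own direction plus
#' low-amplitude smoothed noise, rescaled to plausible units for the eight
#' bioclimatic covariates (annual mean temperature, temperature seasonality,
#' extreme-period temperatures, and four precipitation summaries).
#'
#' @param spec a [landscapeSpec()]
#' @return a `climate_stack`: named list of layers plus the grid
#' @export
generateClimateStack <- function(spec) {
  g <- spec$grid
  layers <- with_seed(substream_seed(spec$seed, "climate"), {
    lapply(seq_len(8), function(i) {
      base <- climateGradient(spec, i)
      noise <- smooth_field(g$height, g$width, range_cells = max(2, g$width / 16))
      u <- base + 0.08 * noise
      climate_layer_scale$offset[i] + climate_layer_scale$range[i] *
        (u - min(u)) / (max(u) - min(u))
    })
  })
  names(layers) <- climate_layer_names
  structure(list(layers = layers, grid = g, layer_names = climate_layer_names),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack: %d layers on %dx%d grid\n  %s\n",
              length(x$layers), x$grid$height, x$grid$width,
              paste(x$layer_names, collapse = ", ")))
  invisible(x)
}

# -- vegetation -----------------------------------------------------------

# apportion n cells over fractions exactly (largest remainder)
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate the patchy vegetation mosaic
#'
#' Land statuses (remnant, non-remnant, water, urban, island) are laid out by
#' thresholding one smooth random field at the spec's target areal fractions,
#' which yields contiguous patches whose realised fractions are exact to one
#' cell. Statuses are then subdivided into vegetation classes using a second
#' smooth field, and every class carries metadata: a label, its land status
#' and a pre-clearing broad vegetation group shared between remnant classes
#' and the cleared (non-remnant) classes derived from them — the hook the
#' offset accounting needs.
#'
#' @param spec a [landscapeSpec()]
#' @return a `vegetation_layer`: integer `class_raster`, `class_meta`
#'   data.frame (class_id, label, status, broad_group), and the grid
#' @export
generateVegetationLayer <- function(spec) {
  g <- spec$grid
  n_cells <- g$width * g$height
  with_seed(substream_seed(spec$seed, "vegetation"), {
    u <- smooth_field(g$height, g$width, range_cells = max(3, g$width / 10))
    v <- smooth_field(g$height, g$width, range_cells = max(2, g$width / 14))
    counts <- apportion(n_cells, spec$fractions)
    status_of_cell <- character(n_cells)
    ord <- order(u)                       # contiguous-ish bands of the field
    bounds <- cumsum(counts)
    starts <- c(1, utils::head(bounds, -1) + 1)
    for (s in seq_along(counts))
      if (counts[s] > 0)
        status_of_cell[ord[starts[s]:bounds[s]]] <- names(counts)[s]

    # class budget: 1 each for water/urban/island, rest split ~2:1
    # remnant : non-remnant
    n_free <- spec$n_veg_classes - 3L
    n_nonrem <- max(1L, round(n_free / 3))
    n_rem <- n_free - n_nonrem
    broad_groups <- c("ironbark_sandplain", "alluvial_woodland", "basalt_scrub")

    meta <- list(); class_raster <- matrix(NA_integer_, g$height, g$width)
    cid <- 0L
    assign_classes <- function(status, k, label_stem, groups) {
      idx <- which(status_of_cell == status)
      if (length(idx) == 0 || k == 0) return(invisible(NULL))
      # split the status area into k classes by quantiles of the second field
      q <- if (k > 1) findInterval(v[idx], stats::quantile(v[idx],
             probs = seq_len(k - 1) / k), rightmost.closed = FALSE) + 1 else rep(1, length(idx))
      for (j in seq_len(k)) {
        cid <<- cid + 1L
        meta[[cid]] <<- data.frame(class_id = cid,
                                   label = sprintf("%s-%02d", label_stem, j),
                                   status = status,
                                   broad_group = groups[(j - 1) %% length(groups) + 1],
                                   stringsAsFactors = FALSE)
        class_raster[idx[q == j]] <<- cid
      }
    }
    assign_classes("remnant", n_rem, "RE-rem", broad_groups)
    assign_classes("non_remnant", n_nonrem, "RE-clr", broad_groups)
    assign_classes("water", 1L, "water", "water")
    assign_classes("urban", 1L, "urban", "urban")
    assign_classes("island", 1L, "island", broad_groups[1])
    class_meta <- do.call(rbind, meta)
    # drop classes that received no cells (tiny status areas)
    present <- sort(unique(as.vector(class_raster)))
    class_meta <- class_meta[class_meta$class_id %in% present, , drop = FALSE]
    rownames(class_meta) <- NULL
    structure(list(class_raster = class_raster, class_meta = class_meta, grid = g),
              class = "vegetation_layer")
  })
}

#' @export
print.vegetation_layer <- function(x, ...) {
  cat(sprintf("vegetation_layer: %d classes on %dx%d grid\n",
              nrow(x$class_meta), x$grid$height, x$grid$width))
  tab <- table(x$class_meta$status)
  cat("  classes by status:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

status_mask <- function(veg, statuses) {
  ids <- veg$class_meta$class_id[veg$class_meta$status %in% statuses]
  m <- matrix(0L, veg$grid$height, veg$grid$width)
  m[veg$class_raster %in% ids] <- 1L
  m
}

#' Urban-proximity observation-bias surface
#'
#' Sampling effort for opportunistic bird records decays with distance from
#' towns: `exp(-bias_strength * d_urban / scale)` with `d_urban` the exact
#' Euclidean distance (metres) to the nearest urban cell and `scale` a
#' decay length defaulting to a quarter of the grid extent. With
#' `bias_strength = 0`, or no urban cells at all, the surface is uniform (1).
#'
#' @param veg a vegetation layer
#' @param bias_strength dimensionless >= 0
#' @param scale decay length in metres
#' @return matrix (height x width) in (0, 1\]
#' @export
biasSurface <- function(veg, bias_strength = 1,
                        scale = veg$grid$width * veg$grid$cell_size / 4) {
  g <- veg$grid
  urban <- status_mask(veg, "urban")
  if (bias_strength == 0 || sum(urban) == 0)
    return(matrix(1, g$height, g$width))
  d <- as.matrix(EBImage::distmap(1 - urban, metric = "euclidean")) * g$cell_size
  exp(-bias_strength * d / scale)
}

# -- true model -----------------------------------------------------------

#' Ground-truth suitability model for a synthetic landscape
#'
#' True suitability is a fixed logistic function of the standardised climate
#' layers, `plogis(b0 + sum(coef_i * z_i))`, with coefficients chosen to give
#' a wide logit range and a negative intercept so that clearly suitable
#' climate is a concentrated minority of the landscape — the regime a
#' range-restricted species lives in, and the one where a presence-background
#' model is informative. The favourable vegetation classes are a fixed
#' subset of the remnant classes. Fully deterministic given climate and
#' vegetation.
#'
#' @param spec a [landscapeSpec()]
#' @param climate the landscape's climate stack
#' @param veg the landscape's vegetation layer
#' @return a `true_model`: coefficients, favourable class ids, and the
#'   true-suitability raster in \[0, 1\]
#' @export
trueModel <- function(spec, climate, veg) {
  # dominated by two near-orthogonal gradients (mean temperature, annual
  # precipitation) with mild contributions elsewhere: avoids cancellation
  # between correlated gradient directions and gives a logit range wide
  # enough that the landscape holds clearly suitable and unsuitable climate
  coefs <- c(annual_mean_temp = 3.5, temp_seasonality = -1.0,
             max_temp_warmest = 0.5, min_temp_coldest = 0.0,
             annual_precip = 3.5, precip_wettest = 0.5,
             precip_driest = -1.0, precip_seasonality = 0.0)
  z <- lapply(climate$layer_names, function(nm) {
    l <- climate$layers[[nm]]
    (l - mean(l)) / stats::sd(l)
  })
  intercept <- -3
  logit <- intercept + Reduce(`+`, Map(function(m, b) m * b, z, coefs))
  suit <- stats::plogis(logit)
  rem <- veg$class_meta$class_id[veg$class_meta$status == "remnant"]
  fav <- rem[seq_len(ceiling(length(rem) / 2))]
  structure(list(coefficients = coefs, intercept = intercept,
                 favourable_classes = fav,
                 true_suitability = suit, grid = spec$grid),
            class = "true_model")
}

# -- occurrences ----------------------------------------------------------

new_record_frame <- function(id, taxon, lon, lat, year, source) {
  data.frame(id = id, taxon = taxon, lon = lon, lat = lat,
             year = year, source = source, stringsAsFactors = FALSE)
}

# sample n cells with probability proportional to w, jitter uniformly in-cell
sample_points_weighted <- function(grid, w, n) {
  idx <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
  row <- (idx - 1) %% grid$height + 1
  col <- (idx - 1) %/% grid$height + 1
  x <- grid$origin[1] + (col - 1 + stats::runif(n)) * grid$cell_size
  y <- grid$origin[2] + (row - 1 + stats::runif(n)) * grid$cell_size
  data.frame(row = row, col = col, x = x, y = y)
}

#' Sample presence records from the true model
#'
#' Presences are drawn cell-wise with probability proportional to
#' `true_suitability * bias` over favourable-class cells — with a small
#' residual weight (2%) on other land cells, since the birds occasionally
#' use cleared country adjacent to habitat — then jittered uniformly within
#' the cell so records carry full-precision planar coordinates. A configured
#' fraction of deliberately invalid records is appended — wrong taxon,
#' in-ocean coordinates, or ambiguous taxon beyond the range cutoff — each
#' labelled in its `source` tag and tallied in the attached injection log so
#' vetting reports can be asserted exactly.
#'
#' @param true_model a [trueModel()]
#' @param veg vegetation layer (water cells carry no presences)
#' @param bias bias surface matrix from [biasSurface()]
#' @param n number of valid presence records (>= 1)
#' @param seed integer
#' @param invalid_fraction fraction of `n` added as invalid records
#' @param year_range inclusive sampling range for record years
#' @return an `occurrence_set` with attributes `injection_log`
#'   (data.frame rule/count) and `placement` (row/col of each valid record)
#' @export
sampleOccurrences <- function(true_model, veg, bias, n, seed,
                              invalid_fraction = 0, year_range = c(1980, 2015)) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  g <- true_model$grid
  with_seed(seed, {
    fav <- matrix(veg$class_raster %in% true_model$favourable_classes,
                  g$height, g$width)
    w <- true_model$true_suitability * bias * ifelse(fav, 1, 0.02)
    w[status_mask(veg, "water") == 1L] <- 0
    pts <- sample_points_weighted(g, w, n)
    years <- sample(seq(year_range[1], year_range[2]), n, replace = TRUE)
    rec <- new_record_frame(sprintf("btf-%05d", seq_len(n)),
                            "p_cincta_cincta", pts$x, pts$y, years,
                            "synthetic:valid")

    n_bad <- round(n * invalid_fraction)
    log <- data.frame(rule = c("taxon", "exclusion_region", "latitude_cutoff"),
                      count = 0L, stringsAsFactors = FALSE)
    if (n_bad > 0) {
      kinds <- rep(c("wrong_taxon", "in_ocean", "out_of_range"),
                   length.out = n_bad)
      ext_x <- g$origin[1] + g$width * g$cell_size
      ext_y <- g$origin[2] + g$height * g$cell_size
      bad <- lapply(seq_len(n_bad), function(i) {
        kind <- kinds[i]
        yr <- sample(seq(year_range[1], year_range[2]), 1)
        if (kind == "wrong_taxon") {
          new_record_frame(sprintf("bad-%03d", i), "p_cincta_atropygialis",
                           stats::runif(1, g$origin[1], ext_x),
                           stats::runif(1, g$origin[2], ext_y),
                           yr, "synthetic:invalid:wrong_taxon")
        } else if (kind == "in_ocean") {
          # the ocean strip lies east of the grid (see defaultVettingRules)
          new_record_frame(sprintf("bad-%03d", i), "p_cincta_cincta",
                           stats::runif(1, ext_x + 0.1 * g$cell_size,
                                        ext_x + 4 * g$cell_size),
                           stats::runif(1, g$origin[2], ext_y),
                           yr, "synthetic:invalid:in_ocean")
        } else {
          # ambiguous subspecies north of the range cutoff (top 5% of grid)
          cutoff <- g$origin[2] + 0.95 * g$height * g$cell_size
          new_record_frame(sprintf("bad-%03d", i), "p_cincta_unspec",
                           stats::runif(1, g$origin[1], ext_x),
                           stats::runif(1, cutoff + 1e-6, ext_y),
                           yr, "synthetic:invalid:out_of_range")
        }
      })
      rec <- rbind(rec, do.call(rbind, bad))
      log$count[log$rule == "taxon"] <- sum(kinds == "wrong_taxon")
      log$count[log$rule == "exclusion_region"] <- sum(kinds == "in_ocean")
      log$count[log$rule == "latitude_cutoff"] <- sum(kinds == "out_of_range")
    }
    occ <- occurrenceSet(rec, crs_tag = "synthetic-planar-m")
    attr(occ, "injection_log") <- log
    attr(occ, "placement") <- pts[, c("row", "col")]
    occ
  })
}

#' Vetting rules matched to the synthetic generator
#'
#' Accepts the southern-subspecies taxon plus ambiguous-subspecies records,
#' removes ambiguous records poleward of the range cutoff (the top 5% of the
#' grid, standing in for the 18.9 degrees S limit), and excludes an "ocean"
#' strip immediately east of the grid where in-water invalids are planted.
#'
#' @param spec a [landscapeSpec()]
#' @return a [vettingRules()] object
#' @export
defaultVettingRules <- function(spec) {
  g <- spec$grid
  ext_x <- g$origin[1] + g$width * g$cell_size
  ext_y <- g$origin[2] + g$height * g$cell_size
  ocean <- rbind(c(ext_x, g$origin[2] - g$cell_size),
                 c(ext_x + 100 * g$cell_size, g$origin[2] - g$cell_size),
                 c(ext_x + 100 * g$cell_size, ext_y + g$cell_size),
                 c(ext_x, ext_y + g$cell_size))
  vettingRules(accepted_taxa = c("p_cincta_cincta", "p_cincta_unspec"),
               ambiguous_taxa = "p_cincta_unspec",
               latitude_cutoff = g$origin[2] + 0.95 * g$height * g$cell_size,
               poleward = "north",
               exclusion_regions = list(list(name = "ocean", geometry = ocean)))
}

#' Generate the multi-species target-group background
#'
#' Background points are records of other woodland species collected by the
#' same observers, so they share the urban-proximity sampling bias but not
#' the focal species' climate response: each species' points are drawn
#' proportional to the bias surface alone over land cells, then jittered
#' within-cell.
#'
#' @param spec a [landscapeSpec()]
#' @param veg vegetation layer
#' @param bias bias surface from [biasSurface()]
#' @return a `background_set`: `points` (occurrence_set) and `species_tags`
#' @export
generateBackground <- function(spec, veg, bias) {
  g <- spec$grid
  species <- sprintf("tg_species_%02d", seq_len(spec$n_species_background))
  with_seed(substream_seed(spec$seed, "background"), {
    w <- bias
    w[status_mask(veg, "water") == 1L] <- 0
    per <- spec$n_background_per_species
    recs <- lapply(seq_along(species), function(s) {
      pts <- sample_points_weighted(g, w, per)
      new_record_frame(sprintf("bg-%02d-%05d", s, seq_len(per)), species[s],
                       pts$x, pts$y,
                       sample(seq(spec$year_range[1], spec$year_range[2]),
                              per, replace = TRUE),
                       "synthetic:background")
    })
    pts <- occurrenceSet(do.call(rbind, recs), crs_tag = "synthetic-planar-m")
    structure(list(points = pts, species_tags = species),
              class = "background_set")
  })
}

#' @export
print.background_set <- function(x, ...) {
  cat(sprintf("background_set: %d points from %d species\n",
              nrow(x$points), length(x$species_tags)))
  invisible(x)
}

# -- tenures and zones ----------------------------------------------------

tenure_types <- c("EPC", "EPG", "EPM", "EPP", "MC", "MDL", "ML", "PL", "PSL")

rect_ring <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
}

#' Generate dated, typed tenure polygons
#'
#' Random axis-aligned rectangles within the landscape extent, each typed
#' from the Queensland tenure alphabet (EPC, EPG, EPM, EPP, MC, MDL, ML, PL,
#' PSL), granted between 1990 and 2014; roughly a fifth expire before the
#' default 2015-09-07 as-of date so the extant filter has work to do.
#' Overlaps are deliberate — downstream accounting must use union semantics.
#'
#' @param spec a [landscapeSpec()]
#' @param as_of reference date used to plant a mix of extant/expired tenures
#' @return a `tenure_layer` (list of polygons with geometry, id,
#'   tenure_type, status, grant_date, expiry_date)
#' @export
generateTenureLayer <- function(spec, as_of = as.Date("2015-09-07")) {
  g <- spec$grid
  n <- spec$n_tenures
  if (n == 0)
    return(structure(list(polygons = list(), grid = g), class = "tenure_layer"))
  ext <- c(g$width, g$height) * g$cell_size
  with_seed(substream_seed(spec$seed, "tenure"), {
    polys <- lapply(seq_len(n), function(i) {
      w <- stats::runif(1, 0.1, 0.45) * ext[1]
      h <- stats::runif(1, 0.1, 0.45) * ext[2]
      x0 <- g$origin[1] + stats::runif(1, 0, ext[1] - w)
      y0 <- g$origin[2] + stats::runif(1, 0, ext[2] - h)
      grant <- as.Date("1990-01-01") + round(stats::runif(1, 0, 9000))
      expired <- stats::runif(1) < 0.2
      expiry <- if (expired) grant + round(stats::runif(1, 365, as.numeric(as_of - grant) - 1))
                else as_of + round(stats::runif(1, 365, 3650))
      # cycle through types so at least two are always present when n >= 2
      list(geometry = rect_ring(x0, y0, x0 + w, y0 + h),
           id = sprintf("TEN-%03d", i),
           tenure_type = tenure_types[(i - 1) %% length(tenure_types) + 1],
           status = "granted",
           grant_date = grant, expiry_date = expiry)
    })
    structure(list(polygons = polys, grid = g), class = "tenure_layer")
  })
}

#' @export
print.tenure_layer <- function(x, ...) {
  cat(sprintf("tenure_layer: %d polygons", length(x$polygons)))
  if (length(x$polygons))
    cat(" (types ", paste(sort(unique(vapply(x$polygons, `[[`, "", "tenure_type"))),
                          collapse = ","), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Generate non-overlapping priority zones
#'
#' Three labelled offset-strategy zones (1: high conservation value,
#' 2: corridors, 3: rehabilitation candidates) as disjoint vertical bands
#' separated by one-cell gaps.
#'
#' @param spec a [landscapeSpec()]
#' @param n_zones 0..3 zones to emit
#' @return a `zone_layer` (list of polygons with `priority` labels)
#' @export
generatePriorityZones <- function(spec, n_zones = 3) {
  g <- spec$grid
  if (n_zones == 0)
    return(structure(list(polygons = list(), grid = g), class = "zone_layer"))
  cs <- g$cell_size
  band_w <- floor((g$width - (n_zones - 1)) / n_zones)
  polys <- lapply(seq_len(n_zones), function(k) {
    c0 <- (k - 1) * (band_w + 1)
    x0 <- g$origin[1] + c0 * cs
    x1 <- x0 + band_w * cs
    list(geometry = rect_ring(x0, g$origin[2], x1,
                              g$origin[2] + g$height * cs),
         priority = k)
  })
  structure(list(polygons = polys, grid = g), class = "zone_layer")
}

#' @export
print.zone_layer <- function(x, ...) {
  cat(sprintf("zone_layer: %d zones\n", length(x$polygons)))
  invisible(x)
}
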