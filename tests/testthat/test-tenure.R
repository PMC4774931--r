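rect <- function(x0, y0, x1, y1)
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))

tl <- function(polys, grid) structure(list(polygons = polys, grid = grid),
                                      class = "tenure_layer")

test_that("the extant filter honours dates and the expired whitelist", {
  g <- grid_geometry(8, 8, 250)
  mk <- function(id, grant, expiry) list(geometry = rect(0, 0, 500, 500),
    id = id, tenure_type = "EPC", status = "granted",
    grant_date = as.Date(grant), expiry_date = as.Date(expiry))
  layer <- tl(list(mk("a", "2000-01-01", "2010-01-01"),
                   mk("b", "2000-01-01", "2020-01-01"),
                   mk("c", "2016-01-01", "2020-01-01")), g)
  ext <- filterExtant(layer, as.Date("2015-09-07"))
  expect_equal(vapply(ext$polygons, `[[`, "", "id"), "b")
  # whitelisted expired tenure is retained
  ext2 <- filterExtant(layer, as.Date("2015-09-07"), include_expired_ids = "a")
  expect_setequal(vapply(ext2$polygons, `[[`, "", "id"), c("a", "b"))
  # boundary: expiry day itself is no longer extant, grant day is
  edge <- tl(list(mk("d", "2015-09-07", "2015-09-08"),
                  mk("e", "2015-09-06", "2015-09-07")), g)
  ext3 <- filterExtant(edge, as.Date("2015-09-07"))
  expect_equal(vapply(ext3$polygons, `[[`, "", "id"), "d")
  # malformed date is rejected and logged
  badrow <- mk("f", "2000-01-01", "2020-01-01"); badrow$grant_date <- "not a date"
  ext4 <- filterExtant(tl(list(badrow), g), as.Date("2015-09-07"))
  expect_length(ext4$polygons, 0)
  expect_equal(attr(ext4, "rejected"), "f")
})

test_that("extant counts match a direct date check on the synthetic layer", {
  spec <- small_spec(seed = 31, n_tenures = 20)
  ten <- generateTenureLayer(spec)
  as_of <- as.Date("2015-09-07")
  want <- sum(vapply(ten$polygons, function(p)
    p$grant_date <= as_of && as_of < p$expiry_date, logical(1)))
  expect_equal(length(filterExtant(ten, as_of)$polygons), want)
})

test_that("rasterization uses union semantics and cell centres", {
  g <- grid_geometry(8, 8, 250)
  r1 <- list(geometry = rect(0, 0, 1000, 500), id = "r1", tenure_type = "EPC")
  # identical rectangles: union equals one rectangle (4 x 2 = 8 cells)
  u <- rasterizeUnion(tl(list(r1, r1), g), g)
  expect_equal(sum(u$values), 8)
  # a rectangle covering k whole cells
  r2 <- list(geometry = rect(250, 250, 1250, 1000), id = "r2", tenure_type = "ML")
  expect_equal(sum(rasterizeUnion(tl(list(r2), g), g)$values), 4 * 3)
  # empty layer -> zero mask
  expect_equal(sum(rasterizeUnion(tl(list(), g), g)$values), 0)
  # invalid geometry skipped, logged
  badp <- list(geometry = matrix(c(0, 0), 1, 2), id = "bad", tenure_type = "MC")
  u2 <- rasterizeUnion(tl(list(r1, badp), g), g)
  expect_equal(attr(u2, "skipped"), "bad")
  expect_equal(sum(u2$values), 8)
  # per-type masks sum to at least the union (overlaps double-count by type)
  both <- rasterizeUnion(tl(list(r1, r2), g), g, by_type = TRUE)
  expect_gte(sum(vapply(both$by_type, function(m) sum(m$values), 0L)),
             sum(both$union$values))
})

test_that("overlap report equals a per-cell brute-force oracle", {
  spec <- landscapeSpec(grid_width = 48, grid_height = 48, seed = 41,
                        n_presences = 200, n_background_per_species = 50,
                        n_species_background = 2)
  veg <- generateVegetationLayer(spec)
  tm <- trueModel(spec, generateClimateStack(spec), veg)
  raw <- sampleOccurrences(tm, veg, biasSurface(veg, 0), 200, seed = 2)
  env <- maskExclusions(bin(matrix(1L, 48, 48)), veg)
  sel <- selectFavourableClasses(raw, veg, env)
  hm <- buildHabitatModel(env, veg, sel, distance = 1118)
  ten <- generateTenureLayer(spec)
  ext <- filterExtant(ten)
  recent <- splitRecent(raw, 2000)$recent
  rep <- overlapReport(hm, veg, ext, recent = recent)

  # oracle: triple loop over cells
  tu <- rasterizeUnion(ext, spec$grid)$values
  cell_km2 <- 0.0625
  loc <- locateCells(spec$grid, recent$lon, recent$lat)
  for (k in seq_along(hm$favourable_classes)) {
    id <- hm$favourable_classes[k]
    tot <- 0; free <- 0; nrec <- 0
    for (r in 1:48) for (cc in 1:48) {
      if (veg$class_raster[r, cc] == id && hm$core$values[r, cc] == 1L) {
        tot <- tot + cell_km2
        if (tu[r, cc] == 0L) free <- free + cell_km2
      }
    }
    nrec <- sum(veg$class_raster[cbind(loc$row, loc$col)] == id &
                  hm$core$values[cbind(loc$row, loc$col)] == 1L)
    row <- rep$per_class[rep$per_class$class_id == id, ]
    expect_equal(row$total_km2, tot)
    expect_equal(row$free_km2, free)
    expect_equal(row$n_recent_records, nrec)
    # exact complement in cell arithmetic
    expect_equal(row$free_km2 + (row$total_km2 - row$free_km2), row$total_km2)
  }
  expect_equal(rep$totals$total_km2[1], sum(rep$per_class$total_km2))

  # no tenures -> 100% free everywhere
  rep0 <- overlapReport(hm, veg, tl(list(), spec$grid), recent = recent)
  expect_true(all(rep0$per_class$pct_free[rep0$per_class$total_km2 > 0] == 100))
  expect_equal(rep0$totals$pct_free[2], 100)
})

test_that("a planted tenure fraction over the habitat is recovered exactly", {
  # habitat = everything; tenure = left 3/8 of an edge-aligned grid
  g <- grid_geometry(32, 32, 250)
  veg <- structure(list(
    class_raster = matrix(1L, 32, 32),
    class_meta = data.frame(class_id = 1L, label = "w", status = "remnant",
                            broad_group = "ironbark_sandplain"),
    grid = g), class = "vegetation_layer")
  env <- bin(matrix(1L, 32, 32))
  sel <- structure(list(selected = 1L), class = "class_selection")
  hm <- buildHabitatModel(env, veg, sel, distance = 0)
  f <- 12 / 32
  ten <- tl(list(list(geometry = rect(0, 0, 12 * 250, 32 * 250), id = "t",
                      tenure_type = "ML", status = "granted",
                      grant_date = as.Date("2000-01-01"),
                      expiry_date = as.Date("2030-01-01"))), g)
  rep <- overlapReport(hm, veg, ten, recent = occ(10, 10))
  expect_equal(rep$totals$pct_free[2], roundHalfAway(100 * (1 - f), 1))
})

test_that("protected-area coverage reports both buffered and class-only extents", {
  g <- grid_geometry(16, 16, 250)
  veg <- structure(list(
    class_raster = matrix(1L, 16, 16),
    class_meta = data.frame(class_id = 1L, label = "w", status = "remnant",
                            broad_group = "ironbark_sandplain"),
    grid = g), class = "vegetation_layer")
  env <- bin({m <- matrix(0L, 16, 16); m[1:8, 1:8] <- 1L; m})
  sel <- structure(list(selected = 1L), class = "class_selection")
  hm <- buildHabitatModel(env, veg, sel, distance = 500)
  prot <- list(list(geometry = rect(0, 0, 16 * 250, 16 * 250), id = "np"))
  rep <- overlapReport(hm, veg, tl(list(), g), protected = prot,
                       recent = occ(10, 10))
  expect_gt(rep$protected$area_km2, rep$protected$core_area_km2)
  expect_equal(rep$protected$area_km2, maskAreaKm2(hm$mask))
})

test_that("footprint conversion reproduces the published per-group and overall rates", {
  tab <- utils::read.csv(extfile("galilee_lease_footprints.csv"),
                         check.names = FALSE)
  conv <- footprintConversion(tab)
  expect_equal(conv$totals$lease_area_ha, 395836)
  expect_equal(conv$totals$affected_area_ha, 168252)
  expect_equal(conv$totals$pct_affected, 42.5)
  pg <- conv$per_group
  expect_equal(pg$pct_affected[pg$group == "Adani"], 71.8)
  expect_equal(pg$pct_affected[pg$group == "Alpha/Kevin's Corner"], 49.7)
  # zero affected area is a clean 0%
  z <- data.frame(group = "z", tenement_id = "t", lease_area_ha = 100,
                  affected_area_ha = 0)
  expect_equal(footprintConversion(z)$per_group$pct_affected, 0)
  # zero lease area is an error
  z0 <- data.frame(group = "z", tenement_id = "t", lease_area_ha = 0,
                   affected_area_ha = 10)
  expect_error(footprintConversion(z0), "zero lease area")
})

test_that("priority-zone accounting matches analytic rectangle overlaps", {
  g <- grid_geometry(40, 10, 250)
  zones <- structure(list(polygons = list(
    list(geometry = rect(0, 0, 10 * 250, 10 * 250), priority = 1),
    list(geometry = rect(12 * 250, 0, 24 * 250, 10 * 250), priority = 2),
    list(geometry = rect(26 * 250, 0, 40 * 250, 10 * 250), priority = 3)),
    grid = g), class = "zone_layer")
  # tenure covers x cells 0..19 entirely
  ten <- tl(list(list(geometry = rect(0, 0, 20 * 250, 10 * 250), id = "t",
                      tenure_type = "EPC")), g)
  tu <- rasterizeUnion(ten, g)
  repz <- priorityZoneReport(zones, tu, g)
  pz <- repz$per_zone
  # P1 fully covered, P2 covered for 8 of its 12 columns, P3 untouched
  expect_equal(pz$pct_outside, c(0, roundHalfAway(100 * 4 / 12, 1), 100))
  expect_equal(repz$p1_under_tenure_km2, 10 * 10 * 0.0625)
  expect_equal(repz$p3_free_km2, 14 * 10 * 0.0625)
  expect_false(repz$offset_deficit)    # P3 free exceeds P1 under tenure
  # flip: tenure over P1 only, P3 smaller free extent
  ten2 <- tl(list(list(geometry = rect(0, 0, 10 * 250, 10 * 250), id = "t",
                       tenure_type = "EPC"),
                  list(geometry = rect(26 * 250, 0, 39 * 250, 10 * 250),
                       id = "u", tenure_type = "ML")), g)
  repz2 <- priorityZoneReport(zones, rasterizeUnion(ten2, g), g)
  expect_true(repz2$offset_deficit)
  # zero tenure: 100% outside for every priority
  rep0 <- priorityZoneReport(zones, bin(matrix(0L, 10, 40)), g)
  expect_true(all(rep0$per_zone$pct_outside == 100))
})

test_that("offset sufficiency back-solves the published around-28% worked example", {
  # 1104 cleared km2 (1 km cells), required 309 km2 -> 28.0%
  g <- grid_geometry(40, 40, 1000)
  cr <- matrix(2L, 40, 40)
  cr[seq_len(1104)] <- 1L                          # 1104 cleared target cells
  veg <- structure(list(class_raster = cr,
    class_meta = data.frame(class_id = 1:2,
                            label = c("cleared-ironbark", "other"),
                            status = c("non_remnant", "remnant"),
                            broad_group = c("ironbark_sandplain", "basalt_scrub")),
    grid = g), class = "vegetation_layer")
  env <- binary_raster(matrix(1L, 40, 40), g)
  imp <- rect(0, 0, 5000, 5000)
  led <- offsetSufficiency(veg, env, imp, required_km2 = 309, radius_km = 100,
                           target_broad_groups = "ironbark_sandplain")
  expect_equal(led$cleared_favourable_km2, 1104)
  expect_equal(led$required_pct_of_cleared, roundHalfAway(100 * 309 / 1104, 1))
  expect_equal(led$required_pct_of_cleared, 28.0)
  expect_true(led$sufficient_overall)

  # required 0 is trivially sufficient
  led0 <- offsetSufficiency(veg, env, imp, required_km2 = 0, radius_km = 0,
                            target_broad_groups = "ironbark_sandplain")
  expect_true(led0$sufficient_within_radius)
  # radius 0: only cleared cells whose centre is inside the impact polygon
  ledr <- offsetSufficiency(veg, env, imp, required_km2 = 1, radius_km = 0,
                            target_broad_groups = "ironbark_sandplain")
  cc <- cellCentres(g)
  inside <- habfoot:::points_in_ring(imp, cc$x, cc$y)
  cleared_inside <- sum(inside & as.vector(cr == 1L))
  expect_equal(ledr$available_within_radius_km2, cleared_inside * 1)
  expect_error(offsetSufficiency(veg, env, imp, 1, 1, "no_such_group"),
               "unknown broad group")
})
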