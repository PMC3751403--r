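# Zone geometry used throughout: toy_region_map() has HRZ over
# lon 114.5-117.5 and TRZ_SCP over lon 117.5-121, both lat -35.5..-33.

test_that("record filtering applies blacklists and bounding boxes", {
  recs <- data.frame(
    species = rep(c("sp1", "sp2"), each = 5),
    lon = c(115, 115.2, 115.4, 149.1, 115.8,   118, 118.2, 118.4, 118.6, 144),
    lat = rep(-34, 10),
    source_id = c("h1", "h2", "h3", "garden_syd", "h4",
                  "h5", "h6", "h7", "h8", "h9"))
  ex <- list(
    blacklist = "garden_syd",  # a capital-city botanic garden record
    bbox = data.frame(species = "sp2", lon_min = 114, lon_max = 122,
                      lat_min = -36, lat_max = -33))
  out <- filter_records(recs, ex)
  expect_equal(nrow(out$records) + nrow(out$removed), nrow(recs))
  expect_equal(nrow(out$removed), 2)
  expect_setequal(out$removed$rule, c("blacklist", "bbox:sp2"))
  # empty rule set is the identity
  expect_identical(filter_records(recs)$records, recs)
  # rule for unknown species warns but does not error
  expect_warning(
    filter_records(recs, list(bbox = data.frame(
      species = "ghost", lon_min = 0, lon_max = 1,
      lat_min = 0, lat_max = 1))), "ghost")
})

test_that("zone counting assigns points by containment and conserves totals", {
  map <- toy_region_map()
  recs <- data.frame(species = "sp",
                     lon = c(116, 119, 140, 117.5),
                     lat = c(-34, -34, -34, -34))
  counts <- count_in_zones(recs, map)
  expect_equal(sum(counts), nrow(recs))
  expect_equal(unname(counts["outside"]), 1)
  # the shared boundary point (lon 117.5) counts as inside exactly one
  # zone, never both
  expect_equal(unname(counts["HRZ"] + counts["TRZ_SCP"]), 3)

  # genuinely overlapping zones are an error
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  overlap <- region_map(list(Z1 = sq, Z2 = sq))
  expect_error(count_in_zones(
    data.frame(species = "s", lon = 0.5, lat = 0.5), overlap),
    "overlapping zones")

  # points generated inside a polygon are all counted there
  set.seed(1)
  pts <- rangediv:::runif_in_polygon(100, map$zones$TRZ_SCP[[1]])
  counts <- count_in_zones(
    data.frame(species = "s", lon = pts[, 1], lat = pts[, 2]), map)
  expect_equal(unname(counts["TRZ_SCP"]), 100)
})

test_that("the >90% rule is strict and scale-invariant", {
  expect_equal(assign_zone(c(HRZ = 95, TRZ_SCP = 5)), "HRZ")
  expect_equal(assign_zone(c(HRZ = 90, TRZ_SCP = 10)), "both")
  expect_equal(assign_zone(c(HRZ = 0, TRZ_SCP = 7)), "TRZ_SCP")
  # scale invariance
  for (m in c(2, 10, 1000)) {
    expect_equal(assign_zone(c(HRZ = 95 * m, TRZ_SCP = 5 * m)), "HRZ")
    expect_equal(assign_zone(c(HRZ = 90 * m, TRZ_SCP = 10 * m)), "both")
  }
  # an 'outside' element is ignored, not counted in the denominator
  expect_equal(assign_zone(c(HRZ = 91, TRZ_SCP = 9, outside = 50)), "HRZ")
  expect_error(assign_zone(c(HRZ = 0, TRZ_SCP = 0)), "cannot be classified")
})

test_that("hotspot classification uses the buffered super-region", {
  map <- toy_region_map()
  inside <- data.frame(species = "a", lon = runif(10, 115, 120),
                       lat = runif(10, -35, -33.5))
  expect_equal(assign_swbp(inside, map), "SWBP")
  east <- data.frame(species = "b", lon = runif(10, 145, 150),
                     lat = runif(10, -35, -33))
  expect_equal(assign_swbp(east, map), "nonSWBP")
  # 8 of 10 records slightly east of the formal boundary (~20 km) but
  # within the 50 km buffer, 2 inside: still a hotspot species
  near <- data.frame(species = "c",
                     lon = c(rep(121.2, 8), 120, 119),
                     lat = rep(-34, 10))
  expect_equal(assign_swbp(near, map), "SWBP")
  expect_equal(assign_swbp(near, map, buffer_km = 0), "nonSWBP")
  expect_error(assign_swbp(near[0, ], map), "no records")
})

test_that("end-to-end assignment table and the purity dial behave", {
  map <- toy_region_map()
  set.seed(7)
  homes <- setNames(rep(c("HRZ", "TRZ_SCP"), 10), paste0("sp", 1:20))
  # purity 1: every species recovered in its home zone
  occ <- simulate_occurrences(homes, map, n_per_species = 40,
                              purity = 1, seed = 2)
  tab <- assign_regions(occ, map)
  expect_equal(nrow(tab), 20)
  expect_true(all(tab$swbp_state == "SWBP"))
  expect_equal(setNames(tab$zone_state, tab$species), homes[tab$species])
  expect_true(all(tab$n_hrz + tab$n_trz_scp + tab$n_outside == 40))

  # purity 0.5: records split evenly, so nearly everything is "both"
  occ5 <- simulate_occurrences(homes, map, n_per_species = 40,
                               purity = 0.5, seed = 3)
  tab5 <- assign_regions(occ5, map)
  expect_gt(mean(tab5$zone_state == "both"), 0.9)
})

test_that("region maps round-trip through GeoJSON", {
  map <- toy_region_map()
  path <- tempfile(fileext = ".geojson")
  write_region_geojson(map, path)
  back <- read_region_geojson(path)
  expect_setequal(names(back$zones), names(map$zones))
  expect_equal(rangediv:::close_ring(back$zones$HRZ[[1]]),
               rangediv:::close_ring(map$zones$HRZ[[1]]), ignore_attr = TRUE)
})

test_that("sampling fractions follow from present/absent counts", {
  counts <- banksia_region_counts()
  f <- sampling_fractions(setNames(counts$present, counts$state),
                          setNames(counts$absent, counts$state))
  expect_equal(unname(f["nonSWBP"]), 15 / 16)
  expect_equal(unname(f["SWBP"]), 143 / 155)
  expect_equal(unname(f["HRZ"]), 1)
  expect_true(all(f > 0 & f <= 1))
})
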