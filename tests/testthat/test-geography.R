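test_that("load_rivers reads LineStrings with age properties", {
  gj <- paste0(
    '{"type":"FeatureCollection","features":[',
    '{"type":"Feature","properties":{"name":"Amazon","min_age_ma":2.4},',
    '"geometry":{"type":"LineString","coordinates":[[-70,-4],[-52,-1]]}}]}')
  rivers <- load_rivers(gj)
  expect_length(rivers, 1)
  expect_s3_class(rivers[[1]], "river_barrier")
  expect_equal(rivers[[1]]$name, "Amazon")
  expect_equal(rivers[[1]]$min_age_ma, 2.4)
  expect_equal(rivers[[1]]$coords, rbind(c(-70, -4), c(-52, -1)))
})

test_that("load_rivers rejects bad geometries and missing properties", {
  poly <- paste0(
    '{"type":"FeatureCollection","features":[',
    '{"type":"Feature","properties":{"name":"X","min_age_ma":1},',
    '"geometry":{"type":"Polygon","coordinates":[[[0,0],[1,0],[0,1],[0,0]]]}}]}')
  expect_error(load_rivers(poly), "LineString")
  noage <- paste0(
    '{"type":"FeatureCollection","features":[',
    '{"type":"Feature","properties":{"name":"X"},',
    '"geometry":{"type":"LineString","coordinates":[[0,0],[0,1]]}}]}')
  expect_error(load_rivers(noage), "min_age_ma")
})

test_that("bank sign follows the cross product of the downstream direction", {
  rv <- straight_river()  # south-to-north at lon 0
  expect_equal(assign_bank(c(-0.5, 0.5), rv)$bank, "left")
  expect_equal(assign_bank(c(0.5, 0.5), rv)$bank, "right")
  # beyond the northern terminus: headwaters rule
  expect_equal(assign_bank(c(0, 2.0), rv)$bank, "indeterminate")
  # exactly on the line
  expect_equal(assign_bank(c(0, 0.5), rv)$bank, "indeterminate")
  expect_error(assign_bank(c(0, 95), rv), "latitude")
  expect_error(assign_bank(c(190, 0), rv), "longitude")
})

test_that("reflection across a straight river swaps banks exactly", {
  rv <- straight_river()
  set.seed(4)
  for (i in 1:25) {
    lon <- runif(1, -1, 1); lat <- runif(1, 0.05, 0.95)
    if (abs(lon) < 1e-6) next
    a <- assign_bank(c(lon, lat), rv)$bank
    b <- assign_bank(c(-lon, lat), rv)$bank
    expect_true(all(c(a, b) %in% c("left", "right")))
    expect_true(a != b)
  }
})

test_that("translation parallel to a straight river preserves the bank", {
  rv <- river_barrier("long", cbind(c(0, 0), c(-40, 40)), 1)
  set.seed(5)
  for (i in 1:20) {
    lon <- runif(1, -2, 2); lat <- runif(1, -30, 30)
    if (abs(lon) < 1e-6) next
    shift <- runif(1, -5, 5)
    expect_equal(assign_bank(c(lon, lat), rv)$bank,
                 assign_bank(c(lon, lat + shift), rv)$bank)
  }
})

test_that("reversing the polyline swaps all determinate banks", {
  rv <- synthetic_river(meander_amplitude_deg = 0.5, lat_range = c(-3, 3))
  rev_rv <- river_barrier(rv$name, rv$coords[nrow(rv$coords):1, ],
                          rv$min_age_ma)
  set.seed(6)
  for (i in 1:25) {
    p <- c(rv$coords[1, 1] + runif(1, -2, 2), runif(1, -2.5, 2.5))
    a <- assign_bank(p, rv)$bank
    b <- assign_bank(p, rev_rv)$bank
    if (a == "indeterminate" || b == "indeterminate") {
      expect_equal(a, b)
    } else {
      expect_true(a != b)
    }
  }
})

test_that("distances are nonnegative great-circle km", {
  rv <- straight_river()
  res <- assign_bank(c(-1, 0.5), rv)
  # one degree of longitude at the equator-ish: about 111 km
  expect_gt(res$distance_km, 100)
  expect_lt(res$distance_km, 120)
  expect_gte(assign_bank(c(0, 0.5), rv)$distance_km, 0)
})

test_that("assign_banks_table yields one row per sample x river", {
  rv1 <- straight_river("R1")
  rv2 <- river_barrier("R2", cbind(c(-1, 1), c(0.2, 0.2)), 1)
  samples <- data.frame(
    sample_id = c("s1", "s2", "s3"), taxon = "t",
    latitude = c(0.5, 0.4, 0.6), longitude = c(-0.5, 0.3, -0.2),
    stringsAsFactors = FALSE)
  bt <- assign_banks_table(samples, list(rv1, rv2))
  expect_equal(nrow(bt), 6)
  expect_setequal(unique(bt$river_name), c("R1", "R2"))

  blank <- samples
  blank$latitude[2] <- NA
  expect_message(bt2 <- assign_banks_table(blank, list(rv1)), "s2")
  expect_equal(nrow(bt2), 2)

  dup <- rbind(samples, samples[1, ])
  expect_error(assign_banks_table(dup, list(rv1)), "duplicate")
})

test_that("pre-assigned bank columns bypass the geometry", {
  rv <- straight_river("R1")
  samples <- data.frame(sample_id = "s1", taxon = "t",
                        latitude = 0.5, longitude = -0.5,
                        stringsAsFactors = FALSE)
  samples[["bank:R1"]] <- "right"  # contradicts geometry on purpose
  bt <- assign_banks_table(samples, list(rv))
  expect_equal(bt$bank, "right")
  expect_true(is.na(bt$distance_km))
})

test_that("planted geography is recovered exactly at violation_rate 0", {
  lin <- setNames(rep(c("L1", "L2", "L3"), each = 4),
                  paste0("t", 1:12))
  rv <- synthetic_river(min_age_ma = 2.4)
  plan <- c(L1 = "left", L2 = "right", L3 = "left")
  md <- simulate_river_geography(lin, rv, plan, spread_km = 15,
                                 violation_rate = 0, seed = 21)
  bt <- assign_banks_table(md, list(rv))
  expect_equal(setNames(bt$bank, bt$sample_id),
               setNames(md$planted_bank, md$sample_id))

  # full reflection: every determinate assignment opposite to plan
  md1 <- simulate_river_geography(lin, rv, plan, spread_km = 15,
                                  violation_rate = 1, seed = 21)
  bt1 <- assign_banks_table(md1, list(rv))
  plan_by_sample <- setNames(plan[md1$taxon], md1$sample_id)
  expect_true(all(bt1$bank != plan_by_sample[bt1$sample_id]))

  # spread 0: all samples of a lineage at identical coordinates
  md0 <- simulate_river_geography(lin, rv, plan, spread_km = 0,
                                  violation_rate = 0, seed = 3)
  sp <- split(md0[, c("latitude", "longitude")], md0$taxon)
  for (s in sp) expect_true(all(apply(s, 2, function(x) diff(range(x)) == 0)))
})
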