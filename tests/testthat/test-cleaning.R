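test_that("decimal precision uncertainty follows the printed decimal places", {
  expect_equal(decimal_precision_uncertainty("40.41", "-3.70"), 1113.2)
  expect_equal(decimal_precision_uncertainty("40.416775", "-3.703790"),
               111320 / 1e6)
  expect_equal(decimal_precision_uncertainty("40", "-3"), 111320)
  # min of the two coordinate precisions is used
  expect_equal(decimal_precision_uncertainty("40.4", "-3.703790"), 11132)
  # numeric input: shortest round-trip representation, with a message
  expect_message(u <- decimal_precision_uncertainty(40.41, -3.7),
                 "round-trip")
  expect_equal(u, 11132) # -3.7 has one decimal place
})

test_that("general tier keeps coordinate-less records and removes planted rows", {
  gaz <- test_gazetteers()
  ok <- make_records(n = 4, species = sprintf("S%d f", 1:4),
                     latitude = c(40, 41, NA, 39.5),
                     longitude = c(-3.7, -5, NA, -1.2))
  ocean <- make_records(latitude = 36, longitude = -20, record_id = "sea1")
  zero <- make_records(latitude = 0, longitude = 0, record_id = "z1")
  eq <- make_records(latitude = 41, longitude = 41, record_id = "e1")
  no_order <- make_records(order = NA_character_, record_id = "no1")
  dup <- make_records(n = 2, record_id = c("dup1", "dup2"))
  res <- clean_general(rbind(ok, ocean, zero, eq, no_order, dup), gaz)
  rep <- res$report
  expect_equal(rep$removed[["validity"]], 2)   # zero-zero + lat==lon
  expect_equal(rep$removed[["outside_study_area"]], 1)
  expect_equal(rep$removed[["order_missing"]], 1)
  expect_equal(rep$removed[["duplicate"]], 1)
  expect_true("r0003" %in% rownames(res$records) ||
                any(is.na(res$records$latitude))) # coordinate-less kept
  expect_equal(rep$output_size, rep$input_size - sum(rep$removed))
  expect_equal(nrow(res$records), rep$output_size)
})

test_that("spatial tier applies uncertainty and proximity rules", {
  gaz <- test_gazetteers()
  base <- make_records(n = 3, species = sprintf("B%d f", 1:3),
                       latitude = c(38.0, 39.1, 42.2),
                       longitude = c(-6.1, -2.3, -7.4))
  high_unc <- make_records(coordinate_uncertainty_m = 15000,
                           record_id = "unc1", latitude = 37.5,
                           longitude = -4.4)
  # no reported uncertainty, 1 decimal place -> 11,132 m > 10 km, removed
  coarse <- make_records(coordinate_uncertainty_m = NA, latitude = 37.5,
                         longitude = -4.5, record_id = "coarse1")
  # ~500 m north of the capital gazetteer point
  near_cap <- make_records(latitude = 40.4168 + 0.0045, longitude = -3.7038,
                           record_id = "cap1")
  near_cen <- make_records(latitude = 40.0, longitude = -3.5 + 0.008,
                           record_id = "cen1")
  near_inst <- make_records(latitude = 41.4 + 0.0005, longitude = 2.0,
                            record_id = "inst1")
  no_xy <- make_records(latitude = NA, longitude = NA, record_id = "nx1")
  inp <- rbind(base, high_unc, coarse, near_cap, near_cen, near_inst, no_xy)
  res <- suppressMessages(clean_spatial(inp, gaz))
  rep <- res$report
  expect_equal(rep$removed[["coords_missing"]], 1)
  expect_equal(rep$removed[["uncertainty"]], 2)
  expect_equal(rep$removed[["capitals"]], 1)
  expect_equal(rep$removed[["centroids"]], 1)
  expect_equal(rep$removed[["institutions"]], 1)
  expect_equal(nrow(res$records), 3)
  expect_error(clean_spatial(inp, gaz, max_uncertainty_m = -5),
               "non-negative")
})

test_that("spatial tier output is a subset of the general tier output", {
  set.seed(4)
  gaz <- test_gazetteers()
  rec <- make_records(n = 120,
                      species = sprintf("S%02d f", sample(30, 120, TRUE)),
                      latitude = runif(120, 30, 46),
                      longitude = runif(120, -22, 6),
                      coordinate_uncertainty_m = sample(c(10, 500, 20000, NA),
                                                        120, TRUE),
                      user_id = sample(letters, 120, TRUE),
                      event_date = as.character(
                        as.Date("2012-01-01") + sample(3000, 120, TRUE)))
  gen <- clean_general(rec, gaz)
  spa <- suppressMessages(clean_spatial(gen$records, gaz))
  expect_true(all(spa$records$record_id %in% gen$records$record_id))
  expect_true(all(gen$records$record_id %in% rec$record_id))
  # final retained set is order-invariant: it equals the records passing
  # every predicate, regardless of attribution order
  keep <- gen$records
  unc <- keep$coordinate_uncertainty_m
  miss <- is.na(unc)
  unc[miss] <- suppressMessages(
    decimal_precision_uncertainty(keep$latitude[miss],
                                  keep$longitude[miss]))
  pass <- !is.na(keep$latitude) & !is.na(keep$longitude) &
    unc <= 10000 &
    occbias:::dist_points_to_points_km(keep$longitude, keep$latitude,
                                       gaz$capitals) > 1 &
    occbias:::dist_points_to_points_km(keep$longitude, keep$latitude,
                                       gaz$centroids) > 1 &
    occbias:::dist_points_to_points_km(keep$longitude, keep$latitude,
                                       gaz$institutions) > 0.1
  pass[is.na(pass)] <- FALSE
  expect_setequal(spa$records$record_id, keep$record_id[pass])
})

test_that("proximity distances agree with a brute-force great-circle oracle", {
  set.seed(11)
  n <- 100
  lon1 <- runif(n, -10, 3); lat1 <- runif(n, 36, 44)
  lon2 <- runif(n, -10, 3); lat2 <- runif(n, 36, 44)
  # independent haversine oracle, written out from the definition
  oracle <- function(lo1, la1, lo2, la2) {
    r <- 6371.0088
    p1 <- la1 * pi / 180; p2 <- la2 * pi / 180
    dp <- p2 - p1; dl <- (lo2 - lo1) * pi / 180
    a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
    2 * r * asin(pmin(1, sqrt(a)))
  }
  expect_lt(max(abs(haversine_km(lon1, lat1, lon2, lat2) -
                      oracle(lon1, lat1, lon2, lat2))) * 1000, 1)
})
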