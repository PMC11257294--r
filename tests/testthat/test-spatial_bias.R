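test_that("grid membership is half-open and deterministic on boundaries", {
  g <- grid_spec(0.25)
  expect_error(grid_spec(0.25, origin = c(0.1, 0)), "multiples")
  idx <- cell_index(g, c(0.25, 0.2499999, -0.25), c(0.5, 0.49, 36))
  expect_equal(idx$ix, c(1L, 0L, -1L)) # boundary point joins the upper cell
  expect_equal(idx$iy[1], 2L)
  # every finite point maps to exactly one cell
  set.seed(3)
  lon <- runif(200, -10, 3); lat <- runif(200, 36, 44)
  expect_false(anyNA(cell_index(g, lon, lat)$cell))
})

test_that("grid counts bin records and enumerate zero cells", {
  area <- rect_polygon(0, 1, 40, 41) # 4 x 4 cells at 0.25 degrees
  rec <- make_records(n = 3, longitude = c(0.1, 0.12, 0.6),
                      latitude = c(40.1, 40.11, 40.6),
                      species = sprintf("g%d f", 1:3))
  gc <- grid_counts(rec, grid_spec(0.25), area)
  expect_equal(nrow(gc), 16)
  expect_equal(sum(gc$count), 3)
  expect_setequal(gc$count[gc$count > 0], c(2, 1))
  expect_equal(sum(gc$count == 0), 14)
})

test_that("grid counts conserve the record total without a study area", {
  set.seed(5)
  rec <- make_records(n = 150, longitude = runif(150, -10, 3),
                      latitude = runif(150, 36, 44))
  rec$latitude[1:7] <- NA; rec$longitude[1:7] <- NA
  gc <- grid_counts(rec, grid_spec(0.25))
  expect_equal(sum(gc$count), 143)
})

test_that("nearest-neighbour index is near 1 for CSR and low for clusters", {
  area <- rect_polygon(-4, 0, 38, 42)
  set.seed(21)
  csr <- sample_points_in_polygon(400, area)
  rec_csr <- make_records(n = 400, longitude = csr$lon, latitude = csr$lat)
  nn <- nn_index(rec_csr, area, n_iter = 99, seed = 7)
  expect_gt(nn$index, 0.9)
  expect_lt(nn$index, 1.1)
  expect_lte(nn$lower, nn$upper)
  expect_equal(nn$n_points, 400)

  # 200 points in two tight clusters inside a much larger square
  set.seed(22)
  cl <- data.frame(
    lon = c(rnorm(100, -3, 0.01), rnorm(100, -1, 0.01)),
    lat = c(rnorm(100, 39, 0.01), rnorm(100, 41, 0.01)))
  rec_cl <- make_records(n = 200, longitude = cl$lon, latitude = cl$lat)
  nn_cl <- nn_index(rec_cl, area, n_iter = 99, seed = 7)
  expect_lt(nn_cl$index, 0.3)
  # brute-force oracle for the observed mean NN distance
  d <- matrix(Inf, 200, 200)
  for (i in 1:200) {
    d[i, ] <- haversine_km(cl$lon[i], cl$lat[i], cl$lon, cl$lat)
  }
  diag(d) <- Inf
  expect_equal(occbias:::mean_nn_km(cl$lon, cl$lat),
               mean(apply(d, 1, min)), tolerance = 1e-5)
})

test_that("nn index is invariant under a longitude shift of the scene", {
  area <- rect_polygon(-4, 0, 38, 42)
  set.seed(31)
  pts <- sample_points_in_polygon(150, area)
  rec <- make_records(n = 150, longitude = pts$lon, latitude = pts$lat)
  a <- nn_index(rec, area, n_iter = 19, seed = 5)
  rec2 <- rec
  rec2$longitude <- rec2$longitude + 20
  area2 <- rect_polygon(16, 20, 38, 42)
  b <- nn_index(rec2, area2, n_iter = 19, seed = 5)
  expect_equal(a$index, b$index, tolerance = 1e-10)
})

test_that("periods with too few points are skipped", {
  area <- rect_polygon(-4, 0, 38, 42)
  set.seed(41)
  pts <- sample_points_in_polygon(130, area)
  rec <- make_records(n = 130, longitude = pts$lon, latitude = pts$lat,
                      event_date = c(rep("2015-06-01", 120),
                                     rep("1985-06-01", 10)))
  expect_message(
    nn <- nn_index(rec, area, periods = default_periods(), n_iter = 19,
                   min_points = 100, seed = 2),
    "skipped")
  expect_equal(nn$period, "2012-2022")
})

test_that("feature distances handle coincidence, containment and scale", {
  cells <- data.frame(lon = c(0, 0, 0.5), lat = c(0, 0, 0.5))
  road <- list(cbind(c(0, 0.4), c(0, 0.4)))
  city <- data.frame(lon = 1, lat = 0)
  pa <- list(cbind(0.5 + 0.2 * cos(seq(0, 2 * pi, length.out = 20)),
                   0.5 + 0.2 * sin(seq(0, 2 * pi, length.out = 20))))
  fd <- feature_distances(cells, list(roads = road, cities = city,
                                      protected_areas = pa))
  expect_equal(fd$dist_roads[1], 0) # centroid on a road vertex
  # one degree of longitude at the equator on the mean-radius sphere
  expect_equal(fd$dist_cities[1], 2 * pi * 6371.0088 / 360,
               tolerance = 1e-6)
  expect_equal(fd$dist_protected_areas[3], 0) # inside the polygon
  expect_gt(fd$dist_protected_areas[1], 0)
})

test_that("segment distances agree with a dense point-sampling oracle", {
  set.seed(17)
  line <- cbind(runif(6, -6, -2), runif(6, 38, 42))
  lon <- runif(40, -8, 0); lat <- runif(40, 37, 43)
  mine <- occbias:::dist_points_to_segments_km(lon, lat, line)
  # brute-force oracle: the polyline as drawn in coordinate space, sampled
  # every ~0.002 degrees, minimum haversine point distance
  dense <- do.call(rbind, lapply(seq_len(nrow(line) - 1), function(s) {
    k <- ceiling(max(abs(line[s + 1, ] - line[s, ])) / 0.002)
    t <- seq(0, 1, length.out = k + 1)
    cbind(line[s, 1] + t * (line[s + 1, 1] - line[s, 1]),
          line[s, 2] + t * (line[s + 1, 2] - line[s, 2]))
  }))
  oracle <- occbias:::dist_points_to_points_km(lon, lat, dense)
  expect_lt(max(abs(mine - oracle) / pmax(oracle, 1)), 0.01)
})

test_that("distance-decay likelihood peaks at the generating parameters", {
  set.seed(8)
  D <- cbind(runif(300, 0, 40), runif(300, 0, 40))
  q <- 30; w <- c(0.08, 0)
  y <- rpois(300, q * exp(-as.vector(D %*% w)))
  ll <- function(w2) occbias:::decay_loglik(y, D, q, w2)
  expect_gte(ll(w), ll(w + c(0.03, 0)))
  expect_gte(ll(w), ll(pmax(w - c(0.03, 0), 0)))
  expect_gte(ll(w), ll(w + c(0, 0.05)))
})

test_that("flat-rate counts yield near-zero decay weights", {
  set.seed(12)
  cells <- data.frame(cell = 1:300, count = rpois(300, 20))
  dists <- data.frame(cell = 1:300, dist_roads = runif(300, 0, 50),
                      dist_cities = runif(300, 0, 50))
  fit <- fit_distance_decay(cells, dists, method = "map")
  expect_lt(max(fit$estimates$mean), 0.01)
  expect_equal(fit$q$mean, mean(cells$count), tolerance = 0.1)
  curve <- decay_rate_curve(fit, "roads", c(0, 10))
  expect_equal(curve$rate[1], fit$q$mean)
  expect_error(decay_rate_curve(fit, "nope"), "unknown feature")
})

test_that("misaligned counts and distances are rejected", {
  cells <- data.frame(cell = 1:10, count = rpois(10, 5))
  dists <- data.frame(cell = 11:20, dist_roads = runif(10))
  expect_error(fit_distance_decay(cells, dists, method = "map"),
               "not aligned")
})
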