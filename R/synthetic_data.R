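INSECT_ORDERS <- c("Lepidoptera", "Coleoptera", "Diptera", "Hymenoptera",
                   "Hemiptera", "Orthoptera", "Odonata", "Neuroptera",
                   "Mantodea", "Phasmatodea", "Blattodea", "Dermaptera",
                   "Ephemeroptera", "Plecoptera", "Trichoptera", "Mecoptera",
                   "Megaloptera", "Raphidioptera", "Psocodea", "Zygentoma")

#' Synthetic occurrence scenario
#'
#' Full generative configuration for a citizen-science-like occurrence
#' dataset with known, controllable biases. One global `seed` expands into
#' independent substreams for the landscape, the users and the event stream,
#' so the same scenario always reproduces the same records. Defaults emulate
#' a regional platform: an Iberian-scale rectangle, 20 insect orders with
#' geometric within-order species abundances, a heavy-tailed (lognormal)
#' user activity law with Dirichlet order preferences concentrated on few
#' orders, a spatial mixture of uniform, clustered (Thomas) and
#' accessibility-thinned point processes, and a daily intensity combining a
#' log-linear trend, weekday multipliers depressed at weekends, holiday
#' suppression and an annual sinusoid.
#'
#' @param seed Integer master seed.
#' @param study_area Named numeric `c(xmin, xmax, ymin, ymax)` in degrees.
#' @param cell_size Analysis grid resolution (degrees).
#' @param n_orders Number of insect orders (max 20, named after real
#'   orders so order-based statistics read naturally).
#' @param species_per_order Species per order.
#' @param abundance_p Geometric-decay parameter of within-order species
#'   abundance (rank k gets weight `(1-p)^(k-1)`).
#' @param range_size_mean Mean range size in grid cells (contiguous).
#' @param n_users Number of users.
#' @param activity_meanlog,activity_sdlog Lognormal user-activity law
#'   (counts rounded, minimum 1).
#' @param preference_alpha Dirichlet concentration over orders (small =
#'   specialists).
#' @param mixture Named weights over `uniform`, `thomas`, `accessibility`
#'   location processes (must sum to 1).
#' @param n_parents,cluster_sd_km Thomas process: number of cluster parents
#'   and Gaussian offspring scatter (km).
#' @param access_w Named per-km decay weights `c(roads=, cities=,
#'   protected_areas=)` of the accessibility thinning.
#' @param n_roads,n_cities,n_protected Feature layer sizes.
#' @param span Length-2 date span of the event stream.
#' @param trend_slope Log-linear trend over the span (log ratio end/start).
#' @param weekday_mult Seven multipliers, Mon..Sun.
#' @param holiday_mult Multiplier applied on national holidays.
#' @param sinusoid_amplitude Annual sinusoid amplitude (0 = none).
#' @param undated_frac Fraction of records emitted with an absent date
#'   (truly absent, never defaulted to Jan 1, so the artifact rule is
#'   testable by injection).
#' @param uncertainty_na_frac Fraction of records with no reported
#'   coordinate uncertainty.
#' @param n_env_layers Number of smooth environmental layers (named Bio1-7,
#'   Bio10-17).
#' @param species_sampling `"preference"` (orders via user preferences),
#'   `"range_proportional"` (record intensity proportional to range size) or
#'   `"range_independent"` (intensity independent of range).
#' @param source_category Stratum label the scenario emulates.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(seed = 1,
                               study_area = c(xmin = -10, xmax = 3,
                                              ymin = 36, ymax = 44),
                               cell_size = 0.25,
                               n_orders = 20,
                               species_per_order = 25,
                               abundance_p = 0.3,
                               range_size_mean = 30,
                               n_users = 857,
                               activity_meanlog = 1.5,
                               activity_sdlog = 1.5,
                               preference_alpha = 0.3,
                               mixture = c(uniform = 0.2, thomas = 0.5,
                                           accessibility = 0.3),
                               n_parents = 30,
                               cluster_sd_km = 10,
                               access_w = c(roads = 0.05, cities = 0.05,
                                            protected_areas = 0.02),
                               n_roads = 8, n_cities = 15, n_protected = 5,
                               span = c("2012-01-01", "2022-12-31"),
                               trend_slope = 0.5,
                               weekday_mult = c(1.1, 1.1, 1.05, 1, 1,
                                                0.85, 0.9),
                               holiday_mult = 0.5,
                               sinusoid_amplitude = 0.5,
                               undated_frac = 0.02,
                               uncertainty_na_frac = 0.3,
                               n_env_layers = 15,
                               species_sampling = c("preference",
                                                    "range_proportional",
                                                    "range_independent"),
                               source_category = "citizen_science") {
  species_sampling <- match.arg(species_sampling)
  stopifnot(n_orders >= 1, n_orders <= length(INSECT_ORDERS),
            species_per_order >= 1, abundance_p > 0, abundance_p < 1,
            range_size_mean >= 1, n_users >= 1,
            activity_sdlog >= 0, preference_alpha > 0,
            all(mixture >= 0), abs(sum(mixture) - 1) < 1e-9,
            all(weekday_mult > 0), holiday_mult > 0,
            sinusoid_amplitude >= 0, sinusoid_amplitude < 1,
            undated_frac >= 0, undated_frac < 1,
            n_env_layers >= 1, n_env_layers <= 15)
  stopifnot(study_area["xmax"] > study_area["xmin"],
            study_area["ymax"] > study_area["ymin"])
  structure(as.list(environment()), class = "synthetic_scenario")
}

# smooth random surface: low-order polynomial + neighbor-smoothed noise
smooth_surface <- function(nx, ny, n_smooth = 4) {
  u <- matrix(seq(0, 1, length.out = nx), nx, ny)
  v <- matrix(seq(0, 1, length.out = ny), nx, ny, byrow = TRUE)
  co <- rnorm(6)
  poly <- co[1] + co[2] * u + co[3] * v + co[4] * u * v +
    co[5] * u^2 + co[6] * v^2
  z <- matrix(rnorm(nx * ny), nx, ny)
  for (k in seq_len(n_smooth)) {
    zp <- rbind(z[1, ], z, z[nx, ])
    zp <- cbind(zp[, 1], zp, zp[, ny])
    z <- (zp[2:(nx + 1), 2:(ny + 1)] + zp[1:nx, 2:(ny + 1)] +
            zp[3:(nx + 2), 2:(ny + 1)] + zp[2:(nx + 1), 1:ny] +
            zp[2:(nx + 1), 3:(ny + 2)]) / 5
  }
  s <- poly + 2 * z / max(sd(as.vector(z)), 1e-9)
  (s - mean(s)) / max(sd(as.vector(s)), 1e-9)
}

#' Simulate the synthetic landscape
#'
#' Generates, reproducibly from the scenario's landscape substream: the
#' rectangular study-area polygon, the analysis grid and its cells, random
#' feature layers (roads as random-walk polylines, cities as points,
#' protected areas as circular polygons), per-cell feature distances, and a
#' stack of smooth environmental layers aligned to the grid.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list: `study_area`, `grid`, `cells` (with centroids and
#'   feature distances), `features`, `env` (an [env_stack()]).
#' @export
simulate_landscape <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(derive_seed(scenario$seed, "landscape"))
  sa <- scenario$study_area
  poly <- rect_polygon(sa["xmin"], sa["xmax"], sa["ymin"], sa["ymax"])
  grid <- grid_spec(scenario$cell_size)
  cells <- study_area_cells(grid, poly)
  ctr <- cell_centroid(grid, cells$ix, cells$iy)
  cells$lon <- ctr$lon
  cells$lat <- ctr$lat

  rand_pt <- function(n, margin = 0) {
    data.frame(lon = runif(n, sa["xmin"] + margin, sa["xmax"] - margin),
               lat = runif(n, sa["ymin"] + margin, sa["ymax"] - margin))
  }
  roads <- lapply(seq_len(scenario$n_roads), function(i) {
    p0 <- rand_pt(1)
    ang <- runif(1, 0, 2 * pi)
    steps <- 15
    dlon <- cumsum(cos(ang + rnorm(steps, 0, 0.5)) * 0.4)
    dlat <- cumsum(sin(ang + rnorm(steps, 0, 0.5)) * 0.4)
    cbind(pmin(pmax(p0$lon + c(0, dlon), sa["xmin"]), sa["xmax"]),
          pmin(pmax(p0$lat + c(0, dlat), sa["ymin"]), sa["ymax"]))
  })
  cities <- as.matrix(rand_pt(scenario$n_cities))
  colnames(cities) <- c("lon", "lat")
  protected <- if (scenario$n_protected > 0) {
    lapply(seq_len(scenario$n_protected), function(i) {
      c0 <- rand_pt(1, margin = 0.6)
      r <- runif(1, 0.2, 0.5)
      th <- seq(0, 2 * pi, length.out = 25)
      cbind(c0$lon + r * cos(th), c0$lat + r * sin(th))
    })
  } else list()
  features <- list(roads = roads, cities = cities,
                   protected_areas = protected)
  cells <- feature_distances(cells, features)

  nx <- as.integer(round((sa["xmax"] - sa["xmin"]) / scenario$cell_size))
  ny <- as.integer(round((sa["ymax"] - sa["ymin"]) / scenario$cell_size))
  layer_names <- paste0("Bio", c(1:7, 10:17))[seq_len(scenario$n_env_layers)]
  layers <- lapply(layer_names, function(nm) smooth_surface(nx, ny))
  names(layers) <- layer_names
  env <- env_stack(unname(c(sa["xmin"], sa["ymin"])), scenario$cell_size,
                   layers)
  list(study_area = poly, grid = grid, cells = cells, features = features,
       env = env)
}

rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / rowSums(g)
}

#' Simulate user profiles
#'
#' Per-user activity counts from a lognormal law (rounded, minimum 1; a zero
#' `activity_sdlog` gives identical counts -- a degenerate tail with no
#' leading contributors) and per-user order preference vectors from a
#' symmetric Dirichlet. Small `preference_alpha` concentrates most users on
#' a single order, emulating taxonomic specialists.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list: `user_id`, `activity` (integer), `preference`
#'   (users x orders matrix, rows sum to 1), `orders`.
#' @export
simulate_users <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(derive_seed(scenario$seed, "users"))
  n <- scenario$n_users
  activity <- pmax(1L, as.integer(round(rlnorm(n, scenario$activity_meanlog,
                                               scenario$activity_sdlog))))
  orders <- INSECT_ORDERS[seq_len(scenario$n_orders)]
  pref <- rdirichlet_rows(n, rep(scenario$preference_alpha,
                                 scenario$n_orders))
  colnames(pref) <- orders
  list(user_id = sprintf("user%04d", seq_len(n)), activity = activity,
       preference = pref, orders = orders)
}

# contiguous random range: grow a connected cell set from a random start
grow_range <- function(cells_keys, neighbors, size) {
  start <- sample(length(cells_keys), 1)
  members <- start
  frontier <- neighbors[[start]]
  while (length(members) < size && length(frontier) > 0) {
    nxt <- frontier[sample.int(length(frontier), 1)]
    members <- c(members, nxt)
    frontier <- setdiff(union(frontier, neighbors[[nxt]]), members)
  }
  members
}

#' Simulate the occurrence table
#'
#' Draws the full event stream from the scenario's event substream: each
#' user contributes their activity count of records; orders follow user
#' preferences (or the range-coupled modes, see
#' [synthetic_scenario()]); locations come from the configured mixture of
#' uniform, Thomas-cluster and accessibility-thinned processes; species are
#' chosen among those of the drawn order whose (contiguous, per-species)
#' range covers the drawn grid cell, with geometric within-order abundance;
#' event dates are drawn from the normalized daily intensity (trend x
#' weekday x holiday x annual sinusoid). Locations incompatible with any
#' species range are redrawn up to `max_retries` times, then the event is
#' skipped and logged.
#'
#' @param scenario A [synthetic_scenario()].
#' @param landscape From [simulate_landscape()] (same scenario).
#' @param users From [simulate_users()] (same scenario).
#' @param max_retries Location retries per event.
#' @return Canonical occurrence data.frame (basis HUMAN_OBSERVATION,
#'   dataset_id `"synthetic_platform"`), with attributes `"species_ranges"`
#'   (true per-species range cells), `"skipped"` and `"scenario_seed"`.
#' @export
simulate_occurrences <- function(scenario, landscape, users,
                                 max_retries = 10) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(derive_seed(scenario$seed, "events"))
  grid <- landscape$grid
  cells <- landscape$cells
  n_cells <- nrow(cells)
  orders <- users$orders

  # neighbor index for contiguous range growth
  key <- function(ix, iy) paste(ix, iy, sep = ":")
  cell_pos <- setNames(seq_len(n_cells), cells$cell)
  neighbors <- lapply(seq_len(n_cells), function(i) {
    nb <- c(key(cells$ix[i] + 1, cells$iy[i]), key(cells$ix[i] - 1, cells$iy[i]),
            key(cells$ix[i], cells$iy[i] + 1), key(cells$ix[i], cells$iy[i] - 1))
    unname(cell_pos[nb[nb %in% names(cell_pos)]])
  })

  n_species <- scenario$n_orders * scenario$species_per_order
  sp_order <- rep(orders, each = scenario$species_per_order)
  sp_name <- sprintf("Genus%03d species%03d", seq_len(n_species),
                     seq_len(n_species))
  sp_rank <- rep(seq_len(scenario$species_per_order), scenario$n_orders)
  sp_abund <- (1 - scenario$abundance_p)^(sp_rank - 1)
  sizes <- pmin(1L + rnbinom(n_species, mu = scenario$range_size_mean - 1,
                             size = 2), n_cells)
  ranges <- lapply(sizes, function(s) grow_range(cells$cell, neighbors, s))
  range_size <- vapply(ranges, length, integer(1))

  # per (order, cell) species lookup
  occ_key <- unlist(mapply(function(o, cl) paste(o, cells$cell[cl],
                                                 sep = "|"),
                           sp_order, ranges, SIMPLIFY = FALSE))
  occ_sp <- rep(seq_len(n_species), range_size)
  sp_by_ordercell <- split(occ_sp, occ_key)

  # accessibility weights per cell; empty feature layers contribute nothing
  dcols <- paste0("dist_", names(scenario$access_w))
  have <- dcols %in% names(cells) &
    vapply(dcols, function(cl) !is.null(cells[[cl]]) &&
             all(is.finite(cells[[cl]])), logical(1))
  Dm <- as.matrix(cells[, dcols[have], drop = FALSE])
  access_p <- exp(-as.vector(Dm %*% scenario$access_w[have]))
  if (length(access_p) == 0 || all(access_p == 0)) {
    access_p <- rep(1, n_cells)
  }
  access_p <- access_p / sum(access_p)

  # Thomas parents
  parents <- sample_points_in_polygon(scenario$n_parents,
                                      landscape$study_area)
  sd_deg <- scenario$cluster_sd_km / 111.32

  N <- sum(users$activity)
  ev_user <- rep(seq_along(users$activity), users$activity)

  mode <- scenario$species_sampling
  if (mode == "preference") {
    ev_order <- integer(N)
    off <- 0L
    for (u in seq_along(users$activity)) {
      a <- users$activity[u]
      ev_order[off + seq_len(a)] <- sample.int(scenario$n_orders, a,
                                               replace = TRUE,
                                               prob = users$preference[u, ])
      off <- off + a
    }
  } else {
    wts <- if (mode == "range_proportional") range_size else
      rlnorm(n_species, 0, 1)
    ev_species <- sample.int(n_species, N, replace = TRUE,
                             prob = wts / sum(wts))
  }

  # vectorized location draws per mixture component
  draw_locations <- function(comp_vec) {
    m <- length(comp_vec)
    lo <- numeric(m); la <- numeric(m)
    iu <- which(comp_vec == 1L)
    if (length(iu)) {
      p <- sample_points_in_polygon(length(iu), landscape$study_area)
      lo[iu] <- p$lon; la[iu] <- p$lat
    }
    it <- which(comp_vec == 2L)
    while (length(it)) { # resample offspring that left the study area
      k <- sample.int(nrow(parents), length(it), replace = TRUE)
      plon <- parents$lon[k] +
        rnorm(length(it), 0, sd_deg / cos(parents$lat[k] * pi / 180))
      plat <- parents$lat[k] + rnorm(length(it), 0, sd_deg)
      ok <- point_in_polygons(plon, plat, landscape$study_area)
      lo[it[ok]] <- plon[ok]; la[it[ok]] <- plat[ok]
      it <- it[!ok]
    }
    ia <- which(comp_vec == 3L)
    if (length(ia)) {
      ci <- sample.int(n_cells, length(ia), replace = TRUE, prob = access_p)
      half <- grid$cell_size / 2
      lo[ia] <- runif(length(ia), cells$lon[ci] - half, cells$lon[ci] + half)
      la[ia] <- runif(length(ia), cells$lat[ci] - half, cells$lat[ci] + half)
    }
    list(lon = lo, lat = la)
  }

  ev_comp <- sample.int(3, N, replace = TRUE, prob = scenario$mixture)
  lon <- numeric(N); lat <- numeric(N); species_idx <- integer(N)
  skipped <- logical(N)
  if (mode == "preference") {
    sp_env <- list2env(sp_by_ordercell, hash = TRUE)
    pending <- seq_len(N)
    for (round in seq_len(max_retries)) {
      if (!length(pending)) break
      loc <- draw_locations(ev_comp[pending])
      cl <- key(floor((loc$lon - grid$origin[1]) / grid$cell_size),
                floor((loc$lat - grid$origin[2]) / grid$cell_size))
      keys <- paste(orders[ev_order[pending]], cl, sep = "|")
      failed <- logical(length(pending))
      for (j in seq_along(pending)) {
        cand <- get0(keys[j], envir = sp_env, inherits = FALSE)
        if (is.null(cand)) {
          failed[j] <- TRUE
          next
        }
        e <- pending[j]
        species_idx[e] <- if (length(cand) == 1) cand else
          cand[sample.int(length(cand), 1, prob = sp_abund[cand])]
        lon[e] <- loc$lon[j]
        lat[e] <- loc$lat[j]
      }
      pending <- pending[failed]
    }
    skipped[pending] <- TRUE
  } else {
    # species chosen first; location uniform within a random range cell
    half <- grid$cell_size / 2
    pick <- ceiling(runif(N) * range_size[ev_species])
    ci <- vapply(seq_len(N), function(e) ranges[[ev_species[e]]][pick[e]],
                 integer(1))
    lon <- runif(N, cells$lon[ci] - half, cells$lon[ci] + half)
    lat <- runif(N, cells$lat[ci] - half, cells$lat[ci] + half)
    species_idx <- ev_species
  }

  keep <- !skipped
  n_kept <- sum(keep)

  # event dates from the daily intensity profile
  span <- as.Date(scenario$span)
  days <- seq(span[1], span[2], by = "day")
  tfrac <- as.numeric(days - span[1]) / max(as.numeric(span[2] - span[1]), 1)
  intensity <- exp(scenario$trend_slope * (tfrac - 0.5)) *
    scenario$weekday_mult[iso_weekday(days)]
  doy <- as.integer(format(days, "%j"))
  intensity <- intensity *
    (1 + scenario$sinusoid_amplitude * cos(2 * pi * (doy - 172) / 365.25))
  yrs <- unique(as.integer(format(days, "%Y")))
  hol <- holiday_calendar(yrs)
  intensity[days %in% hol$date] <-
    intensity[days %in% hol$date] * scenario$holiday_mult
  intensity <- pmax(intensity, 1e-9)
  ev_date <- days[sample.int(length(days), n_kept, replace = TRUE,
                             prob = intensity / sum(intensity))]
  if (scenario$undated_frac > 0) {
    ev_date[runif(n_kept) < scenario$undated_frac] <- NA
  }

  unc <- sample(c(10, 30, 100, 300, 1000, 5000, 10000, 25000), n_kept,
                replace = TRUE)
  unc[runif(n_kept) < scenario$uncertainty_na_frac] <- NA

  sp_of <- species_idx[keep]
  out <- data.frame(
    record_id = sprintf("syn%07d", seq_len(n_kept)),
    species = sp_name[sp_of],
    order = sp_order[sp_of],
    event_date = ev_date,
    latitude = round(lat[keep], 6),
    longitude = round(lon[keep], 6),
    coordinate_uncertainty_m = unc,
    basis_of_record = "HUMAN_OBSERVATION",
    dataset_id = "synthetic_platform",
    publisher = "Synthetic Platform",
    platform = "synthetic",
    user_id = users$user_id[ev_user[keep]],
    country_code = "ES",
    source_category = NA_character_,
    stringsAsFactors = FALSE
  )
  attr(out, "species_ranges") <- setNames(lapply(ranges, function(ix) {
    cells$cell[ix]
  }), sp_name)
  attr(out, "skipped") <- sum(skipped)
  attr(out, "scenario_seed") <- scenario$seed
  out
}
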