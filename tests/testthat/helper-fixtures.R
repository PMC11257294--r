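# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Canonical record constructor with sensible defaults; vectorized over the
# longest argument.
make_records <- function(n = 1, species = "Genus001 species001",
                         order = "Lepidoptera", event_date = "2015-06-15",
                         latitude = 40, longitude = -3,
                         coordinate_uncertainty_m = 10,
                         basis_of_record = "HUMAN_OBSERVATION",
                         dataset_id = "ds1", publisher = "pub",
                         platform = NA_character_, user_id = "u1",
                         country_code = "ES",
                         source_category = "citizen_science",
                         record_id = NULL) {
  n <- max(n, lengths(list(species, order, event_date, latitude, longitude,
                           user_id, dataset_id, basis_of_record)))
  rep_n <- function(x) rep_len(x, n)
  data.frame(
    record_id = record_id %||% sprintf("r%04d", seq_len(n)),
    species = rep_n(species), order = rep_n(order),
    event_date = as.Date(rep_n(event_date)),
    latitude = rep_n(latitude), longitude = rep_n(longitude),
    coordinate_uncertainty_m = rep_n(coordinate_uncertainty_m),
    basis_of_record = rep_n(basis_of_record),
    dataset_id = rep_n(dataset_id), publisher = rep_n(publisher),
    platform = rep_n(platform), user_id = rep_n(user_id),
    country_code = rep_n(country_code),
    source_category = rep_n(source_category),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Iberia-like rectangular study area used throughout the tests.
test_area <- function() rect_polygon(-10, 3, 36, 44)

test_gazetteers <- function() {
  gazetteer_set(test_area(),
                capitals = data.frame(lon = -3.7038, lat = 40.4168),
                centroids = data.frame(lon = -3.5, lat = 40.0),
                institutions = data.frame(lon = 2.0, lat = 41.4))
}

# Records whose per-species record counts and range sizes are exact:
# species k occupies `ranges[k]` distinct 0.25-degree cells (one column of
# cells each) and holds `counts[k]` records spread over those cells.
make_range_records <- function(ranges, counts, grid = grid_spec()) {
  stopifnot(length(ranges) == length(counts), all(counts >= ranges))
  rows <- list()
  for (k in seq_along(ranges)) {
    cell_iy <- seq_len(ranges[k]) - 1
    # counts[k] records round-robin over the species' cells
    iy <- cell_iy[(seq_len(counts[k]) - 1) %% ranges[k] + 1]
    rows[[k]] <- make_records(
      n = counts[k],
      species = sprintf("Species%03d fixture", k),
      longitude = grid$cell_size * (k + 0.5),
      latitude = grid$cell_size * (iy + 0.5) + 36,
      record_id = sprintf("rr%03d_%03d", k, seq_len(counts[k])))
  }
  do.call(rbind, rows)
}

# Closed-form OLS r-squared oracle on (x, y) pairs.
ols_r2_oracle <- function(x, y) {
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy^2 / (sxx * syy)
}

# Daily count series fixture (class as produced by daily_counts).
make_series <- function(counts, start = "2014-01-06") {
  dates <- seq(as.Date(start), by = "day", length.out = length(counts))
  out <- data.frame(date = dates, count = counts)
  class(out) <- c("daily_count_series", "data.frame")
  out
}
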