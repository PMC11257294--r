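#' Gazetteer set for record cleaning
#'
#' Bundles the vector layers the cleaning tiers test against: the study-area
#' polygon(s) and point gazetteers of country capitals, country centroids and
#' biodiversity institutions. Point layers are data.frames with `lon`/`lat`
#' (a `name` column is allowed and ignored). All geometries must be WGS84.
#'
#' @param study_area Polygon layer (see [geometry]); required.
#' @param capitals,centroids,institutions Point layers, optional.
#' @return A `gazetteer_set` object.
#' @export
gazetteer_set <- function(study_area, capitals = NULL, centroids = NULL,
                          institutions = NULL) {
  polys <- as_polygon_list(study_area, "study_area")
  if (length(polys) == 0) stop("empty study_area: configuration error")
  pt <- function(x, what) if (is.null(x)) NULL else as_coord_matrix(x, what)
  structure(list(study_area = polys,
                 capitals = pt(capitals, "capitals"),
                 centroids = pt(centroids, "centroids"),
                 institutions = pt(institutions, "institutions")),
            class = "gazetteer_set")
}

new_cleaning_report <- function(tier, input_size, filters) {
  removed <- vapply(filters, length, integer(1))
  structure(list(tier = tier,
                 input_size = input_size,
                 output_size = input_size - sum(removed),
                 removed = removed),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("Cleaning report (%s tier): %d -> %d records\n",
              x$tier, x$input_size, x$output_size))
  for (f in names(x$removed)) {
    cat(sprintf("  %-22s removed %d\n", f, x$removed[[f]]))
  }
  invisible(x)
}

# First-match filter machinery: each filter flags row indices among the
# still-retained set; a record is attributed to the first filter that
# catches it, so report counts sum exactly to input - output.
apply_filters <- function(records, tier, filters) {
  keep <- rep(TRUE, nrow(records))
  removed <- list()
  for (f in names(filters)) {
    idx <- which(keep)
    flag <- idx[filters[[f]](records[idx, , drop = FALSE])]
    removed[[f]] <- flag
    keep[flag] <- FALSE
  }
  list(records = records[keep, , drop = FALSE],
       report = new_cleaning_report(tier, nrow(records), removed))
}

#' General cleaning tier
#'
#' The tier used by non-spatial analyses: coordinate-less records are kept.
#' Filters, applied first-match in this order:
#' \enumerate{
#'   \item `validity` -- coordinates present but degenerate (0,0 point, or
#'     latitude equal to longitude);
#'   \item `outside_study_area` -- coordinates falling outside the study-area
#'     polygons (at sea / in the wrong country);
#'   \item `order_missing` -- no taxonomic order;
#'   \item `duplicate` -- repeated (species, event_date, latitude,
#'     longitude, dataset_id, user_id) tuple; the first occurrence is kept.
#' }
#'
#' @param records Canonical occurrence data.frame with `source_category`
#'   assigned (excluded records should already be dropped).
#' @param gazetteers A [gazetteer_set()].
#' @param duplicate_cols Columns defining the duplicate tuple.
#' @return A list with elements `records` and `report`
#'   (a `cleaning_report`).
#' @export
clean_general <- function(records, gazetteers,
                          duplicate_cols = c("species", "event_date",
                                             "latitude", "longitude",
                                             "dataset_id", "user_id")) {
  stopifnot(inherits(gazetteers, "gazetteer_set"))
  has_xy <- function(r) !is.na(r$latitude) & !is.na(r$longitude)
  filters <- list(
    validity = function(r) {
      has_xy(r) & ((r$latitude == 0 & r$longitude == 0) |
                     r$latitude == r$longitude)
    },
    outside_study_area = function(r) {
      out <- rep(FALSE, nrow(r))
      xy <- has_xy(r)
      if (any(xy)) {
        out[xy] <- !point_in_polygons(r$longitude[xy], r$latitude[xy],
                                      gazetteers$study_area)
      }
      out
    },
    order_missing = function(r) is.na(r$order) | r$order == "",
    duplicate = function(r) {
      key <- do.call(paste, c(lapply(duplicate_cols,
                                     function(cl) as.character(r[[cl]])),
                              sep = "\r"))
      duplicated(key)
    }
  )
  apply_filters(records, "general", filters)
}

#' Spatial cleaning tier
#'
#' The stricter tier for analyses that need coordinates; input should already
#' have passed [clean_general()]. Filters, first-match in order:
#' coordinate-less records; uncertainty above `max_uncertainty_m` (records
#' with no reported uncertainty are assigned the
#' [decimal_precision_uncertainty()] of their printed coordinates); points
#' within `capital_radius_km` of a country capital; within
#' `centroid_radius_km` of a country centroid; within
#' `institution_radius_m` of a biodiversity institution. All proximity tests
#' use great-circle (haversine) distance.
#'
#' @inheritParams clean_general
#' @param max_uncertainty_m Maximum tolerated coordinate uncertainty (m).
#' @param capital_radius_km,centroid_radius_km Exclusion radii (km).
#' @param institution_radius_m Exclusion radius (m).
#' @return A list with elements `records` and `report`.
#' @export
clean_spatial <- function(records, gazetteers, max_uncertainty_m = 10000,
                          capital_radius_km = 1, centroid_radius_km = 1,
                          institution_radius_m = 100) {
  stopifnot(inherits(gazetteers, "gazetteer_set"))
  if (max_uncertainty_m < 0) stop("max_uncertainty_m must be non-negative")
  near <- function(r, pts, radius_km) {
    if (is.null(pts)) return(rep(FALSE, nrow(r)))
    dist_points_to_points_km(r$longitude, r$latitude, pts) <= radius_km
  }
  filters <- list(
    coords_missing = function(r) is.na(r$latitude) | is.na(r$longitude),
    uncertainty = function(r) {
      unc <- r$coordinate_uncertainty_m
      miss <- is.na(unc)
      if (any(miss)) {
        unc[miss] <- decimal_precision_uncertainty(r$latitude[miss],
                                                   r$longitude[miss])
      }
      unc > max_uncertainty_m
    },
    capitals = function(r) near(r, gazetteers$capitals, capital_radius_km),
    centroids = function(r) near(r, gazetteers$centroids, centroid_radius_km),
    institutions = function(r) near(r, gazetteers$institutions,
                                    institution_radius_m / 1000)
  )
  apply_filters(records, "spatial", filters)
}

#' Coordinate uncertainty implied by decimal precision
#'
#' A coordinate written with `d` decimal places is treated as precise to
#' 111,320 / 10^d meters -- one degree of longitude at the equator divided by
#' the printed resolution, an upper bound at Iberian latitudes. `d` is the
#' smaller of the two coordinates' decimal-place counts (the conservative
#' choice). Character input preserves the printed representation (so
#' `"-3.70"` has two decimal places); numeric input falls back on the
#' shortest decimal representation that round-trips the stored value, and
#' says so via a message once per call.
#'
#' @param latitude,longitude Coordinate vectors, character or numeric.
#' @return Implied uncertainty in meters.
#' @export
#' @examples
#' decimal_precision_uncertainty("40.41", "-3.70")    # 1113.2
#' decimal_precision_uncertainty(40, -3)              # 111320
decimal_precision_uncertainty <- function(latitude, longitude) {
  d_lat <- decimal_places(latitude)
  d_lon <- decimal_places(longitude)
  METERS_PER_DEGREE / 10^pmin(d_lat, d_lon)
}

decimal_places <- function(x) {
  if (is.character(x)) {
    vapply(x, function(s) {
      if (is.na(s) || !grepl("\\.", s)) return(0L)
      nchar(sub("^-?[0-9]*\\.", "", s))
    }, integer(1), USE.NAMES = FALSE)
  } else {
    if (length(x) && any(is.finite(x))) {
      # numeric input lost the printed text; use the shortest round-trip
      message("decimal_places: numeric input, using shortest round-trip ",
              "decimal representation")
    }
    vapply(x, function(v) {
      if (is.na(v)) return(0L)
      for (d in 0:12) {
        if (abs(round(v, d) - v) < 1e-9) return(d)
      }
      12L
    }, integer(1))
  }
}
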