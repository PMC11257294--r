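#' Canonical occurrence schema
#'
#' Every reader and generator in the package produces a data.frame with these
#' columns (one row per occurrence record):
#' \describe{
#'   \item{record_id}{opaque identifier (character)}
#'   \item{species}{scientific name at species rank, or NA}
#'   \item{order}{insect order name, or NA}
#'   \item{event_date}{`Date`, or NA}
#'   \item{latitude, longitude}{WGS84 decimal degrees, or NA (always both)}
#'   \item{coordinate_uncertainty_m}{reported uncertainty in meters, or NA}
#'   \item{basis_of_record}{one of the nine Darwin Core basisOfRecord levels
#'     (unrecognized strings become `"UNKNOWN"`)}
#'   \item{dataset_id, publisher, platform}{provenance fields}
#'   \item{user_id}{recorder identity (from recordedBy or a platform user
#'     field), or NA}
#'   \item{country_code}{ISO-3166 alpha-2}
#'   \item{source_category}{`"academic"`, `"citizen_science"` or
#'     `"excluded"`; NA until assigned by [classify_source()]}
#' }
#' @name occurrence_schema
NULL

BASIS_LEVELS <- c("HUMAN_OBSERVATION", "OBSERVATION", "PRESERVED_SPECIMEN",
                  "MACHINE_OBSERVATION", "MATERIAL_SAMPLE", "LITERATURE",
                  "FOSSIL_SPECIMEN", "LIVING_SPECIMEN", "UNKNOWN")

SOURCE_LEVELS <- c("academic", "citizen_science", "excluded")

CANONICAL_COLS <- c("record_id", "species", "order", "event_date", "latitude",
                    "longitude", "coordinate_uncertainty_m", "basis_of_record",
                    "dataset_id", "publisher", "platform", "user_id",
                    "country_code", "source_category")

#' Column dialects for occurrence tables
#'
#' A dialect maps canonical column names to the column names found in a
#' file. `dwc_dialect()` covers raw Darwin Core headers as exported by GBIF;
#' `canonical_dialect()` is the identity mapping for tables the package wrote
#' itself. Dialects are declared, never auto-sniffed, so ingestion is
#' reproducible.
#'
#' @return Named character vector, canonical name -> source column.
#' @export
dwc_dialect <- function() {
  c(record_id = "gbifID", species = "species", order = "order",
    event_date = "eventDate", latitude = "decimalLatitude",
    longitude = "decimalLongitude",
    coordinate_uncertainty_m = "coordinateUncertaintyInMeters",
    basis_of_record = "basisOfRecord", dataset_id = "datasetKey",
    publisher = "publisher", platform = "platform",
    user_id = "recordedBy", country_code = "countryCode")
}

#' @rdname dwc_dialect
#' @export
canonical_dialect <- function() {
  setNames(CANONICAL_COLS, CANONICAL_COLS)
}

#' Read a Darwin-Core-style occurrence table
#'
#' Reads a delimited text file (CSV, or TSV for `.tsv`/`.txt` extensions)
#' into the [canonical occurrence schema][occurrence_schema]. Unparseable
#' coordinates, dates and uncertainty values become NA fields; coordinates
#' outside WGS84 bounds are blanked pairwise. A single warning summarizes the
#' number of repaired fields, and the per-issue counts are attached as the
#' `"ingest_log"` attribute. Row order is preserved; an empty file yields an
#' empty collection.
#'
#' @param path Path to the delimited file.
#' @param dialect Named character vector mapping canonical column names to
#'   file column names, e.g. [dwc_dialect()].
#' @param sep Field separator; default inferred from the file extension.
#' @return A data.frame in the canonical schema.
#' @export
read_occurrences <- function(path, dialect = dwc_dialect(), sep = NULL) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  check.names = FALSE, na.strings = c("", "NA"))
  mandatory <- c("basis_of_record", "dataset_id")
  for (m in mandatory) {
    if (is.na(dialect[m]) || !(dialect[m] %in% names(raw))) {
      stop("mandatory column not resolvable via dialect: ", m,
           " (expected file column '", dialect[m], "')")
    }
  }
  n <- nrow(raw)
  get_col <- function(canon) {
    src <- dialect[canon]
    if (!is.na(src) && src %in% names(raw)) raw[[src]] else rep(NA_character_, n)
  }
  log <- list()
  lat <- suppressWarnings(as.numeric(get_col("latitude")))
  lon <- suppressWarnings(as.numeric(get_col("longitude")))
  bad_parse <- (!is.na(get_col("latitude")) & is.na(lat)) |
    (!is.na(get_col("longitude")) & is.na(lon))
  out_of_range <- !is.na(lat) & !is.na(lon) &
    (lat < -90 | lat > 90 | lon < -180 | lon > 180)
  unpaired <- xor(is.na(lat), is.na(lon))
  drop_coord <- bad_parse | out_of_range | unpaired
  lat[drop_coord] <- NA_real_
  lon[drop_coord] <- NA_real_
  log$coordinates_blanked <- sum(drop_coord)

  raw_date <- get_col("event_date")
  date <- as.Date(suppressWarnings(as.Date(substr(raw_date, 1, 10),
                                           format = "%Y-%m-%d")))
  log$dates_unparsed <- sum(!is.na(raw_date) & is.na(date))

  unc <- suppressWarnings(as.numeric(get_col("coordinate_uncertainty_m")))
  unc[!is.na(unc) & unc < 0] <- NA_real_

  basis_raw <- get_col("basis_of_record")
  basis <- toupper(gsub("[ -]", "_", trimws(ifelse(is.na(basis_raw), "UNKNOWN",
                                                   basis_raw))))
  unknown <- !(basis %in% BASIS_LEVELS)
  log$basis_unrecognized <- sum(unknown)
  basis[unknown] <- "UNKNOWN"

  rid <- get_col("record_id")
  if (all(is.na(rid))) rid <- as.character(seq_len(n))

  out <- data.frame(
    record_id = rid,
    species = get_col("species"),
    order = get_col("order"),
    event_date = date,
    latitude = lat,
    longitude = lon,
    coordinate_uncertainty_m = unc,
    basis_of_record = basis,
    dataset_id = get_col("dataset_id"),
    publisher = get_col("publisher"),
    platform = get_col("platform"),
    user_id = get_col("user_id"),
    country_code = get_col("country_code"),
    source_category = get_col("source_category"),
    stringsAsFactors = FALSE
  )
  n_issues <- sum(unlist(log))
  if (n_issues > 0) {
    warning(sprintf(
      "read_occurrences: repaired %d field(s) (%d coordinates blanked, %d dates unparsed, %d basisOfRecord normalized to UNKNOWN)",
      n_issues, log$coordinates_blanked, log$dates_unparsed,
      log$basis_unrecognized))
  }
  attr(out, "ingest_log") <- log
  out
}

#' Dataset-category lookup table
#'
#' Hand-curated mapping from dataset identifiers to source strata, used to
#' classify human-observation records. `default_policy` controls what happens
#' to a dataset absent from the table: `"error"` (the default -- every
#' dataset must be curated), or a fallback category.
#'
#' @param mapping A data.frame with columns `dataset_id` and `category`
#'   (values `"academic"` or `"citizen_science"`), or a named character
#'   vector dataset_id -> category.
#' @param default_policy `"error"`, `"academic"` or `"citizen_science"`.
#' @return A `dataset_category_table` object.
#' @export
dataset_category_table <- function(mapping,
                                   default_policy = c("error", "academic",
                                                      "citizen_science")) {
  default_policy <- match.arg(default_policy)
  if (is.data.frame(mapping)) {
    stopifnot(all(c("dataset_id", "category") %in% names(mapping)))
    map <- setNames(as.character(mapping$category),
                    as.character(mapping$dataset_id))
  } else {
    map <- mapping
  }
  if (anyDuplicated(names(map))) {
    stop("duplicate dataset_id keys in category table")
  }
  bad <- setdiff(unique(map), c("academic", "citizen_science"))
  if (length(bad)) stop("invalid categories: ", paste(bad, collapse = ", "))
  structure(list(map = map, default_policy = default_policy),
            class = "dataset_category_table")
}

#' Classify occurrence records into source strata
#'
#' Assigns each record's `source_category` from its basisOfRecord and, where
#' that is not decisive, dataset or publisher metadata:
#' preserved specimens, material samples and literature records are
#' inherently academic; machine observations are classified by publisher;
#' human observations and plain observations by their dataset's curated
#' category; fossil and living specimens and unknown provenance are excluded.
#' Basis-level rules take precedence over dataset metadata; records where the
#' two conflict (e.g. a preserved specimen inside a citizen-science dataset)
#' are counted in the `"classification_log"` attribute.
#'
#' @param records Canonical occurrence data.frame.
#' @param table A [dataset_category_table()].
#' @param machine_publishers Named character vector publisher -> category for
#'   MACHINE_OBSERVATION records; unmapped publishers follow the table's
#'   `default_policy`.
#' @return `records` with `source_category` filled; idempotent.
#' @export
classify_source <- function(records, table, machine_publishers = NULL) {
  stopifnot(inherits(table, "dataset_category_table"))
  basis <- records$basis_of_record
  if (any(is.na(basis))) stop("records must have basis_of_record assigned")
  out <- rep(NA_character_, nrow(records))

  out[basis %in% c("PRESERVED_SPECIMEN", "MATERIAL_SAMPLE", "LITERATURE")] <-
    "academic"
  out[basis %in% c("FOSSIL_SPECIMEN", "LIVING_SPECIMEN", "UNKNOWN")] <-
    "excluded"

  mach <- which(basis == "MACHINE_OBSERVATION")
  if (length(mach)) {
    cat_m <- unname(machine_publishers[records$publisher[mach]])
    out[mach] <- cat_m
  }
  human <- which(basis %in% c("HUMAN_OBSERVATION", "OBSERVATION"))
  if (length(human)) {
    out[human] <- unname(table$map[records$dataset_id[human]])
  }

  missing <- which(is.na(out))
  if (length(missing)) {
    if (table$default_policy == "error") {
      ids <- unique(records$dataset_id[missing])
      stop("unclassifiable dataset(s), absent from the category table: ",
           paste(ids, collapse = ", "))
    }
    out[missing] <- table$default_policy
  }
  conflict <- basis %in% c("PRESERVED_SPECIMEN", "MATERIAL_SAMPLE",
                           "LITERATURE") &
    unname(table$map[records$dataset_id]) %in% "citizen_science"
  records$source_category <- out
  attr(records, "classification_log") <-
    list(basis_dataset_conflicts = sum(conflict, na.rm = TRUE),
         defaulted = length(missing))
  records
}

#' Merge occurrence collections from different platforms
#'
#' Concatenates a primary collection with an extra (e.g. a platform dump not
#' yet federated), forcing every extra record's `source_category` to
#' `extra_category`, and harmonizes order-name spelling through an alias map.
#' Record ids duplicated across the two collections are suffix-disambiguated
#' with a warning.
#'
#' @param primary,extra Canonical occurrence data.frames.
#' @param extra_category `"academic"` or `"citizen_science"`.
#' @param order_aliases Named character vector, variant spelling -> canonical
#'   order name, applied to the merged collection.
#' @return Merged canonical data.frame.
#' @export
merge_datasets <- function(primary, extra, extra_category,
                           order_aliases = NULL) {
  stopifnot(extra_category %in% c("academic", "citizen_science"))
  extra$source_category <- extra_category
  dup <- intersect(primary$record_id, extra$record_id)
  if (length(dup)) {
    warning(length(dup), " duplicate record_id(s) across collections; ",
            "extra records suffixed")
    hit <- extra$record_id %in% dup
    extra$record_id[hit] <- paste0(extra$record_id[hit], "_merged")
  }
  out <- rbind(primary[, CANONICAL_COLS], extra[, CANONICAL_COLS])
  if (!is.null(order_aliases)) {
    hit <- out$order %in% names(order_aliases)
    out$order[hit] <- unname(order_aliases[out$order[hit]])
  }
  rownames(out) <- NULL
  out
}
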