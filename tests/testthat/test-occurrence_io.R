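test_that("read_occurrences ingests Darwin Core tables, repairing bad fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "gbifID,species,order,eventDate,decimalLatitude,decimalLongitude,coordinateUncertaintyInMeters,basisOfRecord,datasetKey,publisher,recordedBy,countryCode",
    "g1,Pieris rapae,Lepidoptera,2015-06-01,40.1,-3.2,30,HUMAN_OBSERVATION,d1,pub,alice,ES",
    "g2,Pieris rapae,Lepidoptera,2015-06-02,,,,HUMAN_OBSERVATION,d1,pub,bob,ES",
    "g3,Lucanus cervus,Coleoptera,not-a-date,41.0,-2.0,xx,Obs,d2,pub,carol,ES"
  ), path)
  expect_warning(rec <- read_occurrences(path), "repaired")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$record_id, c("g1", "g2", "g3")) # row order preserved
  expect_true(is.na(rec$latitude[2]) && is.na(rec$longitude[2]))
  # unrecognized basis string falls back to UNKNOWN
  expect_equal(rec$basis_of_record[3], "UNKNOWN")
  expect_true(is.na(rec$event_date[3]))
  log <- attr(rec, "ingest_log")
  expect_equal(log$basis_unrecognized, 1)
  expect_equal(log$dates_unparsed, 1)
})

test_that("read_occurrences enforces mandatory columns and allows empty files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("species,decimalLatitude,decimalLongitude", path)
  expect_error(read_occurrences(path), "basis_of_record")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("basisOfRecord,datasetKey", path2)
  rec <- read_occurrences(path2)
  expect_equal(nrow(rec), 0)
})

test_that("read_occurrences blanks out-of-range and unpaired coordinates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "basisOfRecord,datasetKey,decimalLatitude,decimalLongitude",
    "HUMAN_OBSERVATION,d1,95.0,10.0",
    "HUMAN_OBSERVATION,d1,40.0,",
    "HUMAN_OBSERVATION,d1,40.0,-3.0"
  ), path)
  expect_warning(rec <- read_occurrences(path), "coordinates blanked")
  expect_true(all(is.na(rec$latitude[1:2])))
  expect_equal(rec$latitude[3], 40)
})

test_that("classify_source applies the basisOfRecord precedence rules", {
  tab <- dataset_category_table(c(d_cs = "citizen_science",
                                  d_ac = "academic"))
  mach <- c("Sound Platform" = "citizen_science",
            "Forest Lab" = "academic")
  rec <- make_records(
    basis_of_record = c("PRESERVED_SPECIMEN", "MATERIAL_SAMPLE",
                        "LITERATURE", "LIVING_SPECIMEN", "FOSSIL_SPECIMEN",
                        "UNKNOWN", "MACHINE_OBSERVATION",
                        "MACHINE_OBSERVATION", "HUMAN_OBSERVATION",
                        "OBSERVATION"),
    dataset_id = c(rep("d_cs", 8), "d_cs", "d_ac"),
    publisher = c(rep("x", 6), "Sound Platform", "Forest Lab", "x", "x"),
    source_category = NA_character_)
  out <- classify_source(rec, tab, machine_publishers = mach)
  expect_equal(out$source_category,
               c("academic", "academic", "academic", "excluded", "excluded",
                 "excluded", "citizen_science", "academic",
                 "citizen_science", "academic"))
  # specimen basis wins over the dataset's citizen-science label; flagged
  expect_equal(attr(out, "classification_log")$basis_dataset_conflicts, 3)
})

test_that("classify_source is total, partitioning, and idempotent", {
  set.seed(1)
  basis <- sample(c("HUMAN_OBSERVATION", "OBSERVATION",
                    "PRESERVED_SPECIMEN", "MACHINE_OBSERVATION",
                    "MATERIAL_SAMPLE", "LITERATURE", "FOSSIL_SPECIMEN",
                    "LIVING_SPECIMEN", "UNKNOWN"), 200, replace = TRUE)
  rec <- make_records(basis_of_record = basis,
                      dataset_id = sample(c("a", "b"), 200, replace = TRUE),
                      publisher = "P", source_category = NA_character_)
  tab <- dataset_category_table(c(a = "academic", b = "citizen_science"))
  out <- classify_source(rec, tab,
                         machine_publishers = c(P = "citizen_science"))
  expect_false(anyNA(out$source_category))
  counts <- table(factor(out$source_category,
                         levels = c("academic", "citizen_science",
                                    "excluded")))
  expect_equal(sum(counts), nrow(rec))
  out2 <- classify_source(out, tab,
                          machine_publishers = c(P = "citizen_science"))
  expect_equal(out2$source_category, out$source_category)
})

test_that("unclassifiable datasets follow the default policy", {
  rec <- make_records(basis_of_record = "HUMAN_OBSERVATION",
                      dataset_id = "unlisted", source_category = NA)
  tab_err <- dataset_category_table(c(known = "academic"))
  expect_error(classify_source(rec, tab_err), "unlisted")
  tab_cs <- dataset_category_table(c(known = "academic"),
                                   default_policy = "citizen_science")
  expect_equal(classify_source(rec, tab_cs)$source_category,
               "citizen_science")
})

test_that("merge_datasets concatenates, forces the stratum and fixes aliases", {
  a <- make_records(n = 3, order = "Lepidoptera",
                    source_category = "academic")
  b <- make_records(n = 2, order = "Hemíptera",
                    source_category = NA_character_,
                    record_id = c("x1", "x2"))
  out <- merge_datasets(a, b, "citizen_science",
                        order_aliases = c("Hemíptera" = "Hemiptera"))
  expect_equal(nrow(out), 5)
  expect_equal(out$source_category[4:5], rep("citizen_science", 2))
  expect_false(any(out$order == "Hemíptera"))
  expect_equal(sum(out$order == "Hemiptera"), 2)
})

test_that("merge_datasets disambiguates duplicate record ids with a warning", {
  a <- make_records(n = 2, record_id = c("r1", "r2"))
  b <- make_records(n = 2, record_id = c("r2", "r9"))
  expect_warning(out <- merge_datasets(a, b, "citizen_science"),
                 "duplicate")
  expect_equal(anyDuplicated(out$record_id), 0)
})
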