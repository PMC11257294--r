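PIPELINE_STAGES <- c("simulate", "ingest", "clean", "taxbias", "spatialbias",
                     "temporalbias", "envbias")

#' Validate a pipeline configuration
#'
#' A run configuration is a plain named list: `seed` (integer; every
#' stochastic stage derives its substream from it), `stages` (subset of
#' `simulate`, `ingest`, `clean`, `taxbias`, `spatialbias`, `temporalbias`,
#' `envbias`; later stages require the earlier ones' outputs), and either
#' `scenario` (arguments for [synthetic_scenario()], the self-contained
#' synthetic path) or `input` (paths: `occurrences`, `category_table`, plus
#' gazetteer/feature/raster inputs for the stages that need them).
#' Optional tuning fields: `nn_iter`, `nn_min_points`, `decay_method`,
#' `n_background`, `env_bins`, `periods` (list `start`, `end`, `width`).
#' Violations raise an error naming the offending field.
#'
#' @param config Named list as above.
#' @return The normalized config (defaults filled in).
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config field missing: seed")
  config$stages <- config$stages %||% PIPELINE_STAGES
  bad <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad)) stop("config field stages: unknown stage(s) ",
                        paste(bad, collapse = ", "))
  synthetic <- !is.null(config$scenario)
  if (!synthetic) {
    if (is.null(config$input)) {
      stop("config field missing: scenario or input")
    }
    for (f in c("occurrences", "category_table")) {
      if (is.null(config$input[[f]])) {
        stop("config field missing: input$", f)
      }
    }
    if ("envbias" %in% config$stages && is.null(config$input$rasters)) {
      stop("config field missing: input$rasters (envbias stage enabled)")
    }
    if ("spatialbias" %in% config$stages &&
          is.null(config$input$features)) {
      stop("config field missing: input$features (spatialbias stage enabled)")
    }
    if (is.null(config$input$study_area)) {
      stop("config field missing: input$study_area")
    }
  }
  config$nn_iter <- config$nn_iter %||% 99
  config$nn_min_points <- config$nn_min_points %||% 100
  config$decay_method <- config$decay_method %||% "map"
  config$n_background <- config$n_background %||% 10000
  config$env_bins <- config$env_bins %||% 50
  config$periods <- config$periods %||% list(start = 1982, end = 2022,
                                             width = 10)
  config
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(config), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

write_stage_file <- function(obj, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    write.csv(obj, path, row.names = FALSE)
  }
  unname(tools::md5sum(path))
}

#' Run the bias-assessment pipeline
#'
#' Executes the enabled stages in dependency order (simulate -> ingest ->
#' clean -> the four bias analyses), writing each stage's tables under
#' `out_dir/<stage>/` and a `manifest.json` recording the config hash and an
#' MD5 content hash per output file. On the synthetic path the run is fully
#' deterministic: rerunning with an unchanged config reproduces identical
#' hashes, and stages whose outputs already match are marked up-to-date. A
#' failing stage is recorded in the manifest and its dependent stages are
#' skipped.
#'
#' @param config Run configuration, see [validate_config()].
#' @param out_dir Output directory.
#' @return The manifest (invisibly written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(config), stages = list())
  state <- new.env(parent = emptyenv())
  periods <- default_periods(config$periods$start, config$periods$end,
                             config$periods$width)
  failed <- FALSE

  run_stage <- function(name, fn) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped_dependency")
      return(invisible(NULL))
    }
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- TRUE
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
    } else {
      manifest$stages[[name]] <<- c(list(status = "ok"), res)
    }
    invisible(NULL)
  }

  run_stage("simulate", function() {
    sc_args <- config$scenario
    sc_args$seed <- sc_args$seed %||% config$seed
    scenario <- do.call(synthetic_scenario, sc_args)
    state$scenario <- scenario
    state$landscape <- simulate_landscape(scenario)
    users <- simulate_users(scenario)
    occ <- simulate_occurrences(scenario, state$landscape, users)
    state$raw <- occ
    f1 <- write_stage_file(occ, file.path(out_dir, "simulate",
                                          "occurrences.csv"))
    f2 <- write_stage_file(state$landscape$cells,
                           file.path(out_dir, "simulate", "cells.csv"))
    list(files = list(occurrences.csv = f1, cells.csv = f2),
         n_records = nrow(occ), skipped = attr(occ, "skipped"),
         seed = scenario$seed)
  })

  run_stage("ingest", function() {
    if (!is.null(config$scenario)) {
      occ <- state$raw
      table <- dataset_category_table(
        c(synthetic_platform = state$scenario$source_category))
    } else {
      occ <- read_occurrences(config$input$occurrences,
                              dialect = config$input$dialect %||%
                                dwc_dialect())
      table <- dataset_category_table(
        read.csv(config$input$category_table, stringsAsFactors = FALSE),
        default_policy = config$input$default_policy %||% "error")
      if (!is.null(config$input$study_area) &&
            is.character(config$input$study_area)) {
        state$study_area_csv <- read.csv(config$input$study_area)
      }
    }
    occ <- classify_source(occ, table,
                           machine_publishers = config$input$machine_publishers)
    occ <- occ[occ$source_category != "excluded", , drop = FALSE]
    state$classified <- occ
    f <- write_stage_file(occ, file.path(out_dir, "ingest",
                                         "classified.csv"))
    list(files = list(classified.csv = f), n_records = nrow(occ))
  })

  run_stage("clean", function() {
    if (!is.null(config$scenario)) {
      gaz <- gazetteer_set(state$landscape$study_area)
      state$study_area <- state$landscape$study_area
    } else {
      sa <- state$study_area_csv
      gaz_in <- config$input
      gaz <- gazetteer_set(sa,
                           capitals = maybe_csv(gaz_in$capitals),
                           centroids = maybe_csv(gaz_in$centroids),
                           institutions = maybe_csv(gaz_in$institutions))
      state$study_area <- gaz$study_area
    }
    gen <- clean_general(state$classified, gaz)
    spa <- suppressMessages(clean_spatial(gen$records, gaz))
    state$general <- gen$records
    state$spatial <- spa$records
    f1 <- write_stage_file(gen$records, file.path(out_dir, "clean",
                                                  "general.csv"))
    f2 <- write_stage_file(spa$records, file.path(out_dir, "clean",
                                                  "spatial.csv"))
    f3 <- write_stage_file(list(general = unclass(gen$report),
                                spatial = unclass(spa$report)),
                           file.path(out_dir, "clean", "report.json"))
    list(files = list(general.csv = f1, spatial.csv = f2,
                      report.json = f3),
         n_general = nrow(gen$records), n_spatial = nrow(spa$records))
  })

  run_stage("taxbias", function() {
    comp <- order_composition(state$general)
    seg <- segment_users(state$general)
    umat <- user_order_matrix(state$general)
    prop <- proportionality_index(state$spatial, periods = periods)
    f1 <- write_stage_file(comp, file.path(out_dir, "taxbias",
                                           "composition.csv"))
    f2 <- write_stage_file(data.frame(segment = names(seg$shares),
                                      share_pct = as.numeric(seg$shares),
                                      n_users = c(length(seg$leading),
                                                  length(seg$sporadic),
                                                  length(seg$other))),
                           file.path(out_dir, "taxbias",
                                     "segmentation.csv"))
    umat_df <- if (ncol(umat) > 0) {
      data.frame(user = colnames(umat), t(umat), check.names = FALSE)
    } else data.frame(user = character(0))
    f3 <- write_stage_file(umat_df,
                           file.path(out_dir, "taxbias", "user_matrix.csv"))
    pr <- as.data.frame(prop)
    f4 <- write_stage_file(pr, file.path(out_dir, "taxbias",
                                         "proportionality.csv"))
    list(files = list(composition.csv = f1, segmentation.csv = f2,
                      user_matrix.csv = f3, proportionality.csv = f4),
         pooled_index = attr(prop, "pooled"))
  })

  run_stage("spatialbias", function() {
    grid <- state$landscape$grid %||% grid_spec()
    gc <- grid_counts(state$spatial, grid, state$study_area)
    nn <- nn_index(state$spatial, state$study_area, periods = NULL,
                   n_iter = config$nn_iter,
                   min_points = config$nn_min_points,
                   seed = derive_seed(config$seed, "nn"))
    f1 <- write_stage_file(gc, file.path(out_dir, "spatialbias",
                                         "grid_counts.csv"))
    f2 <- write_stage_file(nn, file.path(out_dir, "spatialbias",
                                         "nn_index.csv"))
    files <- list(grid_counts.csv = f1, nn_index.csv = f2)
    if (!is.null(state$landscape)) {
      dist <- state$landscape$cells
      fit <- fit_distance_decay(gc, dist, method = config$decay_method,
                                seed = derive_seed(config$seed, "decay"))
      f3 <- write_stage_file(list(q = fit$q, estimates = fit$estimates,
                                  method = fit$method,
                                  converged = fit$converged),
                             file.path(out_dir, "spatialbias",
                                       "decay_fit.json"))
      files$decay_fit.json <- f3
    }
    list(files = files, n_cells = nrow(gc))
  })

  run_stage("temporalbias", function() {
    series <- daily_counts(state$general)
    dec <- decompose_weekly(series)
    yrs <- unique(as.integer(format(series$date, "%Y")))
    hol <- holiday_effects(dec, holiday_calendar(yrs))
    f1 <- write_stage_file(dec$table, file.path(out_dir, "temporalbias",
                                                "decomposition.csv"))
    f2 <- write_stage_file(data.frame(weekday = names(dec$weekly),
                                      weekly = as.numeric(dec$weekly)),
                           file.path(out_dir, "temporalbias", "weekly.csv"))
    f3 <- write_stage_file(hol, file.path(out_dir, "temporalbias",
                                          "holiday_effects.csv"))
    list(files = list(decomposition.csv = f1, weekly.csv = f2,
                      holiday_effects.csv = f3),
         overall_holiday_effect = attr(hol, "overall"))
  })

  run_stage("envbias", function() {
    stack <- if (!is.null(config$scenario)) state$landscape$env else
      read_env_stack(config$input$rasters)
    n_bg <- min(config$n_background,
                sum(stats::complete.cases(
                  vapply(stack$layers, as.vector,
                         numeric(stack$nx * stack$ny)))))
    space <- build_env_space(stack, n_background = n_bg,
                             seed = derive_seed(config$seed, "env"))
    ev <- extract_env(state$spatial, stack,
                      min_year = config$periods$start)
    lab <- assign_period(attr(ev, "period_year"), periods)
    by_period <- lapply(setNames(periods$period, periods$period),
                        function(p) ev[lab %in% p, , drop = FALSE])
    cov <- period_env_coverage(by_period, space, bins = config$env_bins)
    f1 <- write_stage_file(data.frame(variable = space$variables,
                                      space$rotation, check.names = FALSE),
                           file.path(out_dir, "envbias", "loadings.csv"))
    f2 <- write_stage_file(cov$coverage, file.path(out_dir, "envbias",
                                                   "coverage.csv"))
    files <- list(loadings.csv = f1, coverage.csv = f2)
    if (!is.null(cov$jaccard)) {
      files$jaccard.csv <- write_stage_file(cov$jaccard,
                                            file.path(out_dir, "envbias",
                                                      "jaccard.csv"))
    }
    list(files = files, n_background = n_bg)
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}

maybe_csv <- function(path) {
  if (is.null(path)) NULL else read.csv(path)
}

#' Write / read an environmental stack as plain text
#'
#' Long-format CSV serialization of an [env_stack()]: one row per cell with
#' `ix`, `iy` and one column per layer. The header row of grid metadata is
#' stored in the first data columns (`origin_x`, `origin_y`, `cell_size`,
#' `nx`, `ny`), so the file is self-describing and text-only.
#'
#' @param stack An [env_stack()].
#' @param path CSV path.
#' @return `read_env_stack` returns the reconstructed `env_stack`.
#' @export
write_env_stack <- function(stack, path) {
  stopifnot(inherits(stack, "env_stack"))
  g <- expand.grid(ix = seq_len(stack$nx), iy = seq_len(stack$ny))
  vals <- as.data.frame(lapply(stack$layers, function(L) {
    L[cbind(g$ix, g$iy)]
  }))
  meta <- data.frame(origin_x = stack$origin[1], origin_y = stack$origin[2],
                     cell_size = stack$cell_size, nx = stack$nx,
                     ny = stack$ny)
  out <- cbind(g, vals)
  attr_line <- paste0("# ", jsonlite::toJSON(meta, digits = NA))
  con <- file(path, "w")
  writeLines(attr_line, con)
  write.csv(out, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_env_stack
#' @export
read_env_stack <- function(path) {
  first <- readLines(path, n = 1)
  stopifnot(startsWith(first, "# "))
  meta <- jsonlite::fromJSON(sub("^# ", "", first))
  tab <- read.csv(path, skip = 1)
  layer_names <- setdiff(names(tab), c("ix", "iy"))
  layers <- lapply(layer_names, function(nm) {
    L <- matrix(NA_real_, meta$nx, meta$ny)
    L[cbind(tab$ix, tab$iy)] <- tab[[nm]]
    L
  })
  names(layers) <- layer_names
  env_stack(c(meta$origin_x, meta$origin_y), meta$cell_size, layers,
            validate_names = FALSE)
}
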