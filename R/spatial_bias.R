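#' Nearest-neighbour clustering index with a uniform random null
#'
#' For each period (or for all records pooled when `periods = NULL`), the
#' observed mean nearest-neighbour great-circle distance is divided by the
#' mean nearest-neighbour distance of an equally sized uniform random sample
#' drawn in the study area; the ratio is computed independently for each of
#' `n_iter` null draws, then summarized by its mean and its 5th/95th
#' percentiles. An index below 1 means the records are more clustered than a
#' random sample of the same size. Periods with fewer than `min_points`
#' records are skipped with a message.
#'
#' @param records Canonical occurrence data.frame (spatial tier).
#' @param study_area Polygon layer (see [geometry]).
#' @param periods Optional period table from [default_periods()]; `NULL`
#'   pools all records.
#' @param n_iter Number of null iterations (default 99).
#' @param min_points Minimum records per period (default 100).
#' @param seed Integer seed controlling the full null-iteration stream.
#' @return A data.frame with one row per computed period: `period`, `index`
#'   (mean ratio), `lower`/`upper` (5th/95th percentile of the ratio),
#'   `n_points`, `n_iter`.
#' @export
nn_index <- function(records, study_area, periods = NULL, n_iter = 99,
                     min_points = 100, seed = 1) {
  polys <- as_polygon_list(study_area, "study_area")
  bb <- polygon_bbox(polys)
  if (bb["xmax"] <= bb["xmin"] || bb["ymax"] <= bb["ymin"]) {
    stop("degenerate study area: zero extent")
  }
  ok <- !is.na(records$latitude) & !is.na(records$longitude)
  records <- records[ok, , drop = FALSE]
  if (is.null(periods)) {
    groups <- list(pooled = records)
  } else {
    lab <- assign_period(event_year(records$event_date), periods)
    groups <- split(records, factor(lab, levels = periods$period))
  }
  set.seed(seed)
  rows <- list()
  for (g in names(groups)) {
    pts <- groups[[g]]
    n <- nrow(pts)
    if (n < min_points) {
      message("nn_index: period ", g, " skipped (", n, " < ", min_points,
              " points)")
      next
    }
    obs <- mean_nn_km(pts$longitude, pts$latitude)
    ratio <- vapply(seq_len(n_iter), function(i) {
      null <- sample_points_in_polygon(n, polys)
      obs / mean_nn_km(null$lon, null$lat)
    }, numeric(1))
    qs <- unname(quantile(ratio, c(0.05, 0.95)))
    rows[[g]] <- data.frame(period = g, index = mean(ratio),
                            lower = qs[1], upper = qs[2],
                            n_points = n, n_iter = n_iter,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distances from grid cells to accessibility features
#'
#' Computes, for each grid cell centroid, the great-circle distance (km) to
#' the nearest geometry of each feature layer: roads (polylines), cities
#' (points) and protected areas (polygons; distance 0 when the centroid lies
#' inside one). Line and polygon-boundary distances use a local
#' equirectangular approximation to the great-circle segment distance,
#' accurate to about 1% at regional scales.
#'
#' @param cells A data.frame with centroid `lon`/`lat` columns (e.g. from
#'   [grid_counts()]).
#' @param features Named list with any of `roads` (list of polyline
#'   matrices), `cities` (point matrix/data.frame), `protected_areas` (list
#'   of polygon matrices).
#' @return `cells` with one `dist_<feature>` column (km) per supplied layer.
#' @export
feature_distances <- function(cells, features) {
  stopifnot(all(c("lon", "lat") %in% names(cells)))
  if (!is.null(features$roads)) {
    cells$dist_roads <- dist_points_to_lines_km(cells$lon, cells$lat,
                                                features$roads)
  }
  if (!is.null(features$cities)) {
    cells$dist_cities <- dist_points_to_points_km(cells$lon, cells$lat,
                                                  features$cities)
  }
  if (!is.null(features$protected_areas)) {
    cells$dist_protected_areas <-
      dist_points_to_polygons_km(cells$lon, cells$lat,
                                 features$protected_areas)
  }
  cells
}

decay_loglik <- function(y, D, q, w) {
  # log-space evaluation keeps the objective finite when the rate underflows
  loglam <- log(q) - as.vector(D %*% w)
  sum(y * loglam - exp(loglam) - lgamma(y + 1))
}

decay_logpost <- function(y, D, q, w, priors) {
  if (q <= 0 || any(w < 0)) return(-Inf)
  decay_loglik(y, D, q, w) +
    sum(-priors$w_rate * w) +
    dgamma(q, shape = priors$q_shape, rate = priors$q_rate, log = TRUE)
}

decay_map <- function(y, D, priors) {
  nf <- ncol(D)
  # optimize on (log q, w); box-constrain w >= 0
  obj <- function(par) {
    q <- exp(par[1]); w <- par[2:(nf + 1)]
    -decay_logpost(y, D, q, w, priors)
  }
  start <- c(log(max(mean(y), 0.1)), rep(0.01, nf))
  fit <- optim(start, obj, method = "L-BFGS-B",
               lower = c(-20, rep(0, nf)), upper = c(20, rep(5, nf)))
  list(q = exp(fit$par[1]), w = fit$par[2:(nf + 1)],
       converged = fit$convergence == 0)
}

#' Bayesian Poisson distance-decay model of sampling effort
#'
#' Models per-cell record counts as `count_j ~ Poisson(lambda_j)` with
#' `lambda_j = q * exp(-sum_f w_f * d_fj)`, where `d_fj` is the distance (km)
#' from cell `j` to the nearest feature of type `f`. The baseline rate `q`
#' is the expected count in a cell at distance zero from every feature, and
#' each non-negative weight `w_f` is a per-km decay rate: the larger `w_f`,
#' the more strongly sampling concentrates near that feature. Priors are
#' weakly informative: `w_f ~ Exponential(w_rate)`, `q ~ Gamma(q_shape,
#' q_rate)`.
#'
#' Posterior means and 95% credible intervals are sampled with JAGS
#' (`method = "mcmc"`, the default: 2 chains, seeded); `method = "map"`
#' returns the posterior mode from constrained optimization instead and is
#' also used as a fallback if the sampler fails. Chains are checked with the
#' Gelman-Rubin diagnostic; `converged = FALSE` flags fits with any
#' potential scale-reduction factor above 1.1.
#'
#' @param cell_counts Data.frame with a `count` column (from
#'   [grid_counts()]).
#' @param cell_distances Data.frame with `dist_*` columns aligned on the
#'   same cells (from [feature_distances()]); a shared `cell` column, if
#'   present, is used to align the two.
#' @param priors List with `w_rate`, `q_shape`, `q_rate`.
#' @param method `"mcmc"` or `"map"`.
#' @param n_chains,n_iter,n_warmup Sampler configuration.
#' @param seed Integer seed (per-chain RNGs are derived from it).
#' @return A `distance_decay_fit` list: `estimates` (per-feature posterior
#'   mean/sd/2.5%/97.5% of `w`), `q` (same summaries), `method`,
#'   `converged`, `features`, and the data used.
#' @export
fit_distance_decay <- function(cell_counts, cell_distances,
                               priors = list(w_rate = 1, q_shape = 1,
                                             q_rate = 0.01),
                               method = c("mcmc", "map"), n_chains = 2,
                               n_iter = 2000, n_warmup = 1000, seed = 1) {
  method <- match.arg(method)
  if ("cell" %in% names(cell_counts) && "cell" %in% names(cell_distances)) {
    m <- match(cell_counts$cell, cell_distances$cell)
    if (anyNA(m)) stop("cell_counts and cell_distances are not aligned")
    cell_distances <- cell_distances[m, , drop = FALSE]
  } else if (nrow(cell_counts) != nrow(cell_distances)) {
    stop("cell_counts and cell_distances must align on the same cells")
  }
  dcols <- grep("^dist_", names(cell_distances), value = TRUE)
  if (length(dcols) == 0) stop("no dist_* columns in cell_distances")
  features <- sub("^dist_", "", dcols)
  D <- as.matrix(cell_distances[, dcols, drop = FALSE])
  y <- cell_counts$count
  stopifnot(all(is.finite(D)), all(y >= 0))

  map <- decay_map(y, D, priors)
  fit <- NULL
  if (method == "mcmc") {
    fit <- tryCatch(
      decay_mcmc(y, D, priors, n_chains, n_iter, n_warmup, seed, map),
      error = function(e) {
        warning("MCMC failed (", conditionMessage(e), "); using MAP fallback")
        NULL
      })
  }
  if (is.null(fit)) {
    est <- data.frame(feature = features, mean = map$w, sd = NA_real_,
                      q2.5 = NA_real_, q97.5 = NA_real_)
    fit <- list(estimates = est,
                q = data.frame(mean = map$q, sd = NA_real_, q2.5 = NA_real_,
                               q97.5 = NA_real_),
                method = "map", converged = map$converged)
  } else {
    fit$method <- "mcmc"
    fit$estimates$feature <- features
  }
  fit$features <- features
  fit$priors <- priors
  fit$data <- list(y = y, D = D)
  fit$map <- map
  class(fit) <- "distance_decay_fit"
  if (!fit$converged) warning("distance-decay fit flagged: convergence ",
                              "diagnostics exceeded threshold")
  fit
}

decay_mcmc <- function(y, D, priors, n_chains, n_iter, n_warmup, seed, map) {
  model <- "model {
    for (j in 1:J) {
      y[j] ~ dpois(lam[j])
      log(lam[j]) <- log(q) - inprod(w[], d[j, ])
    }
    for (f in 1:F) { w[f] ~ dexp(w_rate) }
    q ~ dgamma(q_shape, q_rate)
  }"
  inits <- lapply(seq_len(n_chains), function(k) {
    list(q = map$q, w = pmax(map$w, 1e-4),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, paste0("chain", k)))
  })
  jm <- rjags::jags.model(textConnection(model),
                          data = list(y = y, d = D, J = length(y),
                                      F = ncol(D), w_rate = priors$w_rate,
                                      q_shape = priors$q_shape,
                                      q_rate = priors$q_rate),
                          inits = inits, n.chains = n_chains, quiet = TRUE)
  update(jm, n_warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("q", "w"), n_iter,
                              progress.bar = "none")
  X <- do.call(rbind, lapply(samp, as.matrix))
  summ <- function(v) c(mean = mean(v), sd = sd(v),
                        q2.5 = unname(quantile(v, 0.025)),
                        q97.5 = unname(quantile(v, 0.975)))
  wcols <- grep("^w", colnames(X), value = TRUE)
  est <- t(vapply(wcols, function(cn) summ(X[, cn]), numeric(4)))
  converged <- TRUE
  if (n_chains >= 2) {
    psrf <- tryCatch(
      max(coda::gelman.diag(samp, autoburnin = FALSE,
                            multivariate = FALSE)$psrf[, 1]),
      error = function(e) NA_real_)
    converged <- is.finite(psrf) && psrf < 1.1
  }
  list(estimates = data.frame(feature = NA_character_, est,
                              row.names = NULL),
       q = data.frame(t(summ(X[, "q"]))),
       converged = converged)
}

#' @export
print.distance_decay_fit <- function(x, ...) {
  cat("Poisson distance-decay fit (", x$method, "), ",
      length(x$data$y), " cells\n", sep = "")
  cat(sprintf("  baseline rate q: %.3f\n", x$q$mean))
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  w_%-16s %.4f per km\n", x$features[i], est$mean[i]))
  }
  if (!x$converged) cat("  [flagged: convergence diagnostics]\n")
  invisible(x)
}

#' Predicted sampling rate versus distance
#'
#' Rate curve for one feature with the others held at distance zero:
#' `q * exp(-w_f * d)`.
#'
#' @param fit A [fit_distance_decay()] result.
#' @param feature Feature name.
#' @param distances Distances (km) at which to evaluate.
#' @return Data.frame with `distance_km` and `rate`.
#' @export
decay_rate_curve <- function(fit, feature, distances = seq(0, 100, by = 1)) {
  stopifnot(inherits(fit, "distance_decay_fit"))
  i <- match(feature, fit$features)
  if (is.na(i)) stop("unknown feature: ", feature)
  data.frame(distance_km = distances,
             rate = fit$q$mean * exp(-fit$estimates$mean[i] * distances))
}
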