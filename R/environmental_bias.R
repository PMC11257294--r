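#' In-memory environmental raster stack
#'
#' A lightweight aligned multi-layer raster: `nx` x `ny` cells of size
#' `cell_size` degrees anchored at `origin` (lower-left corner), with one
#' numeric `nx` x `ny` matrix per named layer (row = lon index, column = lat
#' index; NA = no-data). The fifteen supported bioclimatic layer names are
#' Bio1-Bio7 and Bio10-Bio17; Bio8, Bio9, Bio18 and Bio19 are rejected at
#' validation because their quarter-based definitions produce spatial
#' artifacts that can distort environmental-space analyses.
#'
#' @param origin `(lon, lat)` of the lower-left corner.
#' @param cell_size Cell edge in degrees.
#' @param layers Named list of equally sized numeric matrices.
#' @param validate_names Enforce the bioclim exclusion rule (default TRUE
#'   only when all names look like `Bio<k>`).
#' @return An `env_stack` object.
#' @export
env_stack <- function(origin, cell_size, layers, validate_names = TRUE) {
  stopifnot(length(origin) == 2, cell_size > 0, is.list(layers),
            length(layers) >= 1, !is.null(names(layers)))
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1) stop("all layers must share the same dimensions")
  banned <- c("Bio8", "Bio9", "Bio18", "Bio19")
  if (validate_names && any(names(layers) %in% banned)) {
    stop("layers ", paste(intersect(names(layers), banned), collapse = ", "),
         " are excluded: quarter-based bioclim variables produce spatial ",
         "artifacts; use Bio1-Bio7 and Bio10-Bio17")
  }
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 nx = dims[[1]][1], ny = dims[[1]][2], layers = layers),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layer(s), %d x %d cells of %g deg at (%g, %g)\n",
              length(x$layers), x$nx, x$ny, x$cell_size, x$origin[1],
              x$origin[2]))
  invisible(x)
}

# (ix, iy) 1-based cell of each coordinate; NA outside the extent.
stack_cell <- function(stack, lon, lat) {
  ix <- floor((lon - stack$origin[1]) / stack$cell_size) + 1L
  iy <- floor((lat - stack$origin[2]) / stack$cell_size) + 1L
  bad <- ix < 1L | ix > stack$nx | iy < 1L | iy > stack$ny
  ix[bad] <- NA_integer_
  iy[bad] <- NA_integer_
  cbind(ix = ix, iy = iy)
}

stack_values <- function(stack, ix, iy) {
  idx <- cbind(ix, iy)
  out <- vapply(stack$layers, function(L) L[idx], numeric(length(ix)))
  if (length(ix) == 1) out <- matrix(out, nrow = 1,
                                     dimnames = list(NULL,
                                                     names(stack$layers)))
  out
}

#' Extract environmental vectors for occurrence records
#'
#' Nearest-cell (containing-cell) extraction of every stack layer at each
#' record's coordinates. Records that are undated or dated before
#' `min_year` are excluded first (environmental layers describe the modern
#' climate normal); records outside the raster extent or on no-data cells
#' are dropped and counted.
#'
#' @param records Canonical occurrence data.frame (spatial tier).
#' @param stack An [env_stack()].
#' @param min_year Earliest usable year (default 1982).
#' @return Numeric matrix (records x layers) with `record_id` rownames and
#'   attributes `"record_id"`, `"period_year"` (event years) and
#'   `"extract_log"` (drop counts).
#' @export
extract_env <- function(records, stack, min_year = 1982) {
  stopifnot(inherits(stack, "env_stack"))
  yr <- event_year(records$event_date)
  keep_date <- !is.na(yr) & yr >= min_year
  has_xy <- !is.na(records$latitude) & !is.na(records$longitude)
  r <- records[keep_date & has_xy, , drop = FALSE]
  yr <- yr[keep_date & has_xy]
  cells <- stack_cell(stack, r$longitude, r$latitude)
  inside <- !is.na(cells[, "ix"])
  vals <- matrix(NA_real_, nrow(r), length(stack$layers),
                 dimnames = list(NULL, names(stack$layers)))
  if (any(inside)) {
    vals[inside, ] <- stack_values(stack, cells[inside, "ix"],
                                   cells[inside, "iy"])
  }
  complete <- inside & stats::complete.cases(vals)
  out <- vals[complete, , drop = FALSE]
  rownames(out) <- r$record_id[complete]
  attr(out, "record_id") <- r$record_id[complete]
  attr(out, "period_year") <- yr[complete]
  attr(out, "extract_log") <- list(
    dropped_predate = sum(!(keep_date & has_xy)),
    dropped_outside = sum(!inside),
    dropped_nodata = sum(inside & !stats::complete.cases(vals)))
  out
}

#' Build the PCA environmental space from background points
#'
#' Samples `n_background` valid raster cells uniformly without replacement,
#' z-scores every variable on that background sample (correlation PCA --
#' bioclim units are incommensurable), and eigendecomposes the result.
#' Loadings are sign-fixed so the largest-magnitude loading of each
#' component is positive, making scores reproducible across platforms.
#' Variables with zero variance on the background are dropped with a
#' warning.
#'
#' @param stack An [env_stack()].
#' @param n_background Background sample size (default 10,000).
#' @param seed Integer seed for the cell sample.
#' @return An `env_space` list: `variables`, `center`, `scale`, `rotation`,
#'   `scores` (background), `explained` (variance ratios), `background_cells`.
#' @export
build_env_space <- function(stack, n_background = 10000, seed = 1) {
  stopifnot(inherits(stack, "env_stack"))
  all_vals <- vapply(stack$layers, as.vector,
                     numeric(stack$nx * stack$ny))
  valid <- which(stats::complete.cases(all_vals))
  if (length(valid) < n_background) {
    stop("only ", length(valid), " valid cells; need n_background = ",
         n_background)
  }
  set.seed(seed)
  cells <- sort(sample(valid, n_background))
  X <- all_vals[cells, , drop = FALSE]
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(X)
  Z <- scale(X, center = ctr, scale = sds)
  pca <- prcomp(Z, center = FALSE, scale. = FALSE)
  # sign convention: largest |loading| positive per component
  for (k in seq_len(ncol(pca$rotation))) {
    j <- which.max(abs(pca$rotation[, k]))
    if (pca$rotation[j, k] < 0) {
      pca$rotation[, k] <- -pca$rotation[, k]
      pca$x[, k] <- -pca$x[, k]
    }
  }
  structure(list(variables = colnames(X), center = ctr, scale = sds,
                 rotation = pca$rotation, scores = pca$x,
                 explained = pca$sdev^2 / sum(pca$sdev^2),
                 background_cells = cells),
            class = "env_space")
}

#' Project environmental vectors into an env space
#'
#' Applies the background standardization and loadings of an existing
#' [build_env_space()] fit; affine-exact, so reprojecting the background
#' sample reproduces its stored scores.
#'
#' @param space An `env_space`.
#' @param X Numeric matrix with the space's variables as columns.
#' @return Score matrix (rows x components).
#' @export
project_env <- function(space, X) {
  stopifnot(inherits(space, "env_space"))
  miss <- setdiff(space$variables, colnames(X))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  Z <- scale(X[, space$variables, drop = FALSE], center = space$center,
             scale = space$scale)
  Z %*% space$rotation
}

#' Decadal coverage of the environmental space
#'
#' Bins the background PC1 x PC2 scores on a `bins` x `bins` grid spanning
#' the background extent, then measures for each period the fraction of
#' background-occupied bins that the period's occurrences also occupy, plus
#' the Jaccard overlap of occupied-bin sets between consecutive periods.
#' Occurrence scores outside the background extent are clipped to the edge
#' bins and counted.
#'
#' @param env_by_period Named list (period -> environmental matrix with the
#'   space's variables), e.g. splits of an [extract_env()] result.
#' @param space An `env_space` from [build_env_space()].
#' @param bins Bins per axis (default 50).
#' @return A list: `coverage` (data.frame period, n, coverage, n_clipped),
#'   `jaccard` (data.frame from, to, jaccard), `n_background_bins`.
#' @export
period_env_coverage <- function(env_by_period, space, bins = 50) {
  stopifnot(inherits(space, "env_space"), bins >= 2)
  bg <- space$scores[, 1:2, drop = FALSE]
  rng1 <- range(bg[, 1]); rng2 <- range(bg[, 2])
  bin_of <- function(scores) {
    clip1 <- scores[, 1] < rng1[1] | scores[, 1] > rng1[2]
    clip2 <- scores[, 2] < rng2[1] | scores[, 2] > rng2[2]
    b1 <- findInterval(pmin(pmax(scores[, 1], rng1[1]), rng1[2]),
                       seq(rng1[1], rng1[2], length.out = bins + 1),
                       rightmost.closed = TRUE, all.inside = TRUE)
    b2 <- findInterval(pmin(pmax(scores[, 2], rng2[1]), rng2[2]),
                       seq(rng2[1], rng2[2], length.out = bins + 1),
                       rightmost.closed = TRUE, all.inside = TRUE)
    list(bins = unique(paste(b1, b2, sep = ":")),
         n_clipped = sum(clip1 | clip2))
  }
  bg_bins <- bin_of(bg)$bins
  cov_rows <- list()
  occ_sets <- list()
  for (p in names(env_by_period)) {
    X <- env_by_period[[p]]
    if (is.null(X) || nrow(X) == 0) {
      cov_rows[[p]] <- data.frame(period = p, n = 0L, coverage = 0,
                                  n_clipped = 0L)
      occ_sets[[p]] <- character(0)
      next
    }
    sc <- project_env(space, X)[, 1:2, drop = FALSE]
    b <- bin_of(sc)
    occ_sets[[p]] <- b$bins
    cov_rows[[p]] <- data.frame(
      period = p, n = nrow(X),
      coverage = length(intersect(b$bins, bg_bins)) / length(bg_bins),
      n_clipped = b$n_clipped)
  }
  coverage <- do.call(rbind, cov_rows)
  rownames(coverage) <- NULL
  jac <- NULL
  pp <- names(env_by_period)
  if (length(pp) >= 2) {
    jac <- do.call(rbind, lapply(seq_len(length(pp) - 1), function(i) {
      a <- occ_sets[[pp[i]]]; b <- occ_sets[[pp[i + 1]]]
      u <- length(union(a, b))
      data.frame(from = pp[i], to = pp[i + 1],
                 jaccard = if (u == 0) NA_real_ else
                   length(intersect(a, b)) / u)
    }))
    rownames(jac) <- NULL
  }
  list(coverage = coverage, jaccard = jac,
       n_background_bins = length(bg_bins))
}
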