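#' Per-order composition of a source stratum
#'
#' Percentage of observations and of unique species (names identified to
#' species rank) per insect order within one stratum. Observation shares sum
#' to 100 over all orders; a `display` flag marks orders holding at least
#' `display_min_pct` of the observations (smaller orders are conventionally
#' dropped from barplots, never from the table).
#'
#' @param records Canonical occurrence data.frame (general cleaning tier).
#' @param stratum `"academic"` or `"citizen_science"`; `NULL` uses all rows.
#' @param display_min_pct Display threshold in percent (default 0.5).
#' @return Data.frame with `order`, `n_obs`, `observation_share`,
#'   `n_species`, `species_share`, `display`, sorted by observation share.
#' @export
order_composition <- function(records, stratum = NULL,
                              display_min_pct = 0.5) {
  if (!is.null(stratum)) {
    stopifnot(stratum %in% c("academic", "citizen_science"))
    records <- records[records$source_category %in% stratum, , drop = FALSE]
  }
  records <- records[!is.na(records$order), , drop = FALSE]
  if (nrow(records) == 0) {
    warning("empty stratum: no records with order data")
    return(data.frame(order = character(), n_obs = integer(),
                      observation_share = numeric(), n_species = integer(),
                      species_share = numeric(), display = logical()))
  }
  n_obs <- table(records$order)
  sp <- records[!is.na(records$species), c("order", "species")]
  sp <- unique(sp)
  n_sp <- table(factor(sp$order, levels = names(n_obs)))
  total_sp <- sum(n_sp)
  out <- data.frame(
    order = names(n_obs),
    n_obs = as.integer(n_obs),
    observation_share = 100 * as.integer(n_obs) / nrow(records),
    n_species = as.integer(n_sp),
    species_share = if (total_sp > 0) 100 * as.integer(n_sp) / total_sp
      else NA_real_,
    stringsAsFactors = FALSE
  )
  out$display <- out$observation_share >= display_min_pct
  out <- out[order(-out$observation_share), ]
  rownames(out) <- NULL
  out
}

#' Cross-platform correlation of per-order record counts
#'
#' Spearman rank correlations of log-transformed per-order observation
#' counts between every pair of record partitions (platforms or strata).
#' Orders absent from a platform count as zero; counts are transformed as
#' `log(x + 1)` (rank correlations are invariant to the offset). Platforms
#' with fewer than 3 distinct orders get NA coefficients with a warning.
#'
#' @param partitions Named list of canonical occurrence data.frames.
#' @param method Correlation method (default `"spearman"`).
#' @return List with `estimate` and `p_value` (symmetric matrices), `n`
#'   (number of orders), and `counts` (the order-by-platform count matrix).
#' @export
platform_order_correlation <- function(partitions, method = "spearman") {
  stopifnot(is.list(partitions), length(partitions) >= 2)
  orders <- sort(unique(unlist(lapply(partitions, function(p) {
    p$order[!is.na(p$order)]
  }))))
  counts <- vapply(partitions, function(p) {
    as.integer(table(factor(p$order, levels = orders)))
  }, integer(length(orders)))
  rownames(counts) <- orders
  k <- ncol(counts)
  est <- p <- matrix(NA_real_, k, k,
                     dimnames = list(colnames(counts), colnames(counts)))
  diag(est) <- 1
  diag(p) <- 0
  degenerate <- colSums(counts > 0) < 3
  if (any(degenerate)) {
    warning("platform(s) with < 3 distinct orders: ",
            paste(colnames(counts)[degenerate], collapse = ", "))
  }
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (degenerate[i] || degenerate[j]) next
      ct <- suppressWarnings(
        cor.test(log(counts[, i] + 1), log(counts[, j] + 1),
                 method = method, exact = FALSE))
      est[i, j] <- est[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(estimate = est, p_value = p, n = length(orders), counts = counts)
}

#' User-by-order preference matrix
#'
#' For every user with more than `min_obs` observations, the proportion of
#' that user's records in each insect order. Columns (users) are sorted by
#' their share in the most popular order -- Lepidoptera by default, falling
#' back to the overall most-recorded order if absent -- so specialist
#' profiles group visually.
#'
#' @param records Canonical occurrence data.frame with `user_id`.
#' @param min_obs Inclusion threshold: users need strictly more than this
#'   many observations (default 10).
#' @param sort_order Order name used as the sort key.
#' @return Matrix orders x users with columns summing to 1 (empty with a
#'   warning if no user qualifies); the sort key is kept as attribute
#'   `"sort_order"`.
#' @export
user_order_matrix <- function(records, min_obs = 10,
                              sort_order = "Lepidoptera") {
  r <- records[!is.na(records$user_id) & !is.na(records$order), , drop = FALSE]
  cnt <- table(r$user_id)
  keep <- names(cnt)[cnt > min_obs]
  if (length(keep) == 0) {
    warning("no user exceeds min_obs = ", min_obs)
    m <- matrix(numeric(0), nrow = 0, ncol = 0)
    attr(m, "sort_order") <- sort_order
    return(m)
  }
  r <- r[r$user_id %in% keep, , drop = FALSE]
  tab <- table(factor(r$order), factor(r$user_id))
  m <- sweep(unclass(tab), 2, colSums(tab), "/")
  if (!(sort_order %in% rownames(m))) {
    sort_order <- rownames(m)[which.max(rowSums(tab))]
  }
  m <- m[, order(-m[sort_order, ]), drop = FALSE]
  attr(m, "sort_order") <- sort_order
  m
}

#' Segment users by contribution performance
#'
#' Splits recorders into leading contributors (per-user observation counts
#' above the Tukey upper fence, Q3 + `fence_k` * IQR, of all per-user
#' counts), sporadic users (at most `sporadic_max` observations) and the
#' remainder, and reports each segment's share of all observations. With
#' fewer than 4 users the quartiles are undefined and the leading set is
#' empty, with a warning.
#'
#' @param records Canonical occurrence data.frame with `user_id`.
#' @param sporadic_max Sporadic threshold (default 10, inclusive).
#' @param fence_k Tukey fence multiplier (default 1.5).
#' @return A `user_segmentation` list: `leading`, `sporadic`, `other`
#'   (character vectors of user ids), `counts` (named per-user counts),
#'   `shares` (percent of all observations per segment), `fence`.
#' @export
segment_users <- function(records, sporadic_max = 10, fence_k = 1.5) {
  r <- records[!is.na(records$user_id), , drop = FALSE]
  cnt <- table(r$user_id)
  counts <- setNames(as.integer(cnt), names(cnt))
  if (length(counts) < 4) {
    warning("fewer than 4 users: quartiles undefined, leading set empty")
    fence <- Inf
  } else {
    q <- quantile(counts, c(0.25, 0.75), names = FALSE)
    fence <- q[2] + fence_k * (q[2] - q[1])
  }
  leading <- names(counts)[counts > fence]
  sporadic <- setdiff(names(counts)[counts <= sporadic_max], leading)
  other <- setdiff(names(counts), c(leading, sporadic))
  total <- sum(counts)
  share <- function(u) if (total == 0) NA_real_ else
    100 * sum(counts[u]) / total
  structure(list(leading = leading, sporadic = sporadic, other = other,
                 counts = counts, fence = fence,
                 shares = c(leading = share(leading),
                            sporadic = share(sporadic),
                            other = share(other))),
            class = "user_segmentation")
}

#' @export
print.user_segmentation <- function(x, ...) {
  cat(sprintf(
    "User segmentation: %d leading (%.2f%% of obs), %d sporadic (%.2f%%), %d other (%.2f%%); fence = %.2f\n",
    length(x$leading), x$shares["leading"], length(x$sporadic),
    x$shares["sporadic"], length(x$other), x$shares["other"], x$fence))
  invisible(x)
}

#' Shannon diversity per insect order
#'
#' `H = -sum(p_s * log(p_s))` over the relative abundances of species within
#' each order (natural log by default, the ecological convention). Only
#' records identified to species rank contribute.
#'
#' @param records Canonical occurrence data.frame.
#' @param group Optional subset: a character vector of user ids (rows are
#'   restricted to those users) or a source category.
#' @param base Logarithm base (default `exp(1)`).
#' @return Named numeric vector, one H per order.
#' @export
shannon_per_order <- function(records, group = NULL, base = exp(1)) {
  r <- records
  if (!is.null(group)) {
    if (length(group) == 1 && group %in% SOURCE_LEVELS) {
      r <- r[r$source_category %in% group, , drop = FALSE]
    } else {
      r <- r[r$user_id %in% group, , drop = FALSE]
    }
  }
  r <- r[!is.na(r$order) & !is.na(r$species), , drop = FALSE]
  if (nrow(r) == 0) return(setNames(numeric(0), character(0)))
  vapply(split(r$species, r$order), function(sp) {
    p <- table(sp) / length(sp)
    -sum(p * log(p, base = base))
  }, numeric(1))
}

#' Correlation between two per-order statistics
#'
#' Aligns two named vectors on their shared index, drops undefined pairs
#' pairwise, optionally applies `log(x + 1)`, and runs a two-sided
#' correlation test.
#'
#' @param x,y Named numeric vectors indexed by order.
#' @param method `"pearson"` or `"spearman"`.
#' @param log_transform Apply `log(x + 1)` to both sides first.
#' @return List with `estimate`, `p_value`, `n`.
#' @export
group_correlations <- function(x, y, method = c("pearson", "spearman"),
                               log_transform = FALSE) {
  method <- match.arg(method)
  common <- intersect(names(x), names(y))
  if (length(common) == 0) stop("x and y share no index")
  xv <- x[common]
  yv <- y[common]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (log_transform) {
    if (method == "pearson" && any(c(xv, yv) == 0)) {
      warning("log(x + 1) offset affects Pearson correlations of zero counts")
    }
    xv <- log(xv + 1); yv <- log(yv + 1)
  }
  ct <- suppressWarnings(cor.test(xv, yv, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Range-size/record-count proportionality index per decade
#'
#' For each period, each species' range size is the number of occupied grid
#' cells (computed independently per period) and its effort the number of
#' records; the index is the r-squared of the ordinary least-squares
#' regression of record count on range size. An index near 1 means species
#' are recorded proportionately to their range (low taxonomic bias); low
#' values mean some species are over- or under-sampled relative to range.
#'
#' @param records Canonical occurrence data.frame (spatial cleaning tier,
#'   species rank required).
#' @param grid A [grid_spec()] (default 0.25 degrees).
#' @param periods Period table from [default_periods()], or `NULL` for a
#'   single pooled regression over all records.
#' @param min_species Minimum species per period for a defined index.
#' @return Data.frame (class `bias_series`) with `period`, `value` (r², NA
#'   when undefined), `n_species`; when `periods` is given, the pooled
#'   all-years value is attached as attribute `"pooled"`.
#' @export
proportionality_index <- function(records, grid = grid_spec(),
                                  periods = default_periods(),
                                  min_species = 3) {
  r <- records[!is.na(records$species) & !is.na(records$latitude) &
                 !is.na(records$longitude), , drop = FALSE]
  one_index <- function(rr) {
    if (nrow(rr) == 0) return(c(NA_real_, 0))
    cells <- cell_index(grid, rr$longitude, rr$latitude)$cell
    range_size <- tapply(cells, rr$species, function(cl) length(unique(cl)))
    n_rec <- tapply(cells, rr$species, length)
    if (length(range_size) < min_species) return(c(NA_real_,
                                                   length(range_size)))
    # a perfect fit is a legitimate outcome here, not a modelling problem
    r2 <- suppressWarnings(
      summary(lm(as.vector(n_rec) ~ as.vector(range_size)))$r.squared)
    c(r2, length(range_size))
  }
  if (is.null(periods)) {
    v <- one_index(r)
    out <- data.frame(period = "pooled", value = v[1],
                      n_species = as.integer(v[2]))
  } else {
    lab <- assign_period(event_year(r$event_date), periods)
    out <- do.call(rbind, lapply(periods$period, function(p) {
      v <- one_index(r[lab %in% p, , drop = FALSE])
      data.frame(period = p, value = v[1], n_species = as.integer(v[2]))
    }))
    if (anyNA(out$value)) {
      warning("period(s) with fewer than ", min_species,
              " species: index undefined")
    }
    attr(out, "pooled") <- one_index(r)[1]
  }
  class(out) <- c("bias_series", "data.frame")
  out
}
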