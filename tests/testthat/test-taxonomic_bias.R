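test_that("order composition computes observation and species shares", {
  rec <- rbind(
    make_records(n = 80, order = "Lepidoptera",
                 species = sprintf("Lep%02d f", rep(1:4, 20))),
    make_records(n = 20, order = "Coleoptera",
                 species = sprintf("Col%02d f", rep(1:6, length.out = 20)))
  )
  comp <- order_composition(rec, "citizen_science")
  expect_equal(comp$observation_share[comp$order == "Lepidoptera"], 80)
  expect_equal(comp$observation_share[comp$order == "Coleoptera"], 20)
  expect_equal(sum(comp$observation_share), 100)
  expect_equal(comp$n_species[comp$order == "Coleoptera"], 6)
  expect_equal(sum(comp$species_share), 100)

  single <- order_composition(make_records(n = 1))
  expect_equal(single$observation_share, 100)
  expect_warning(order_composition(make_records(n = 0)[0, ]), "empty")
})

test_that("orders below the display threshold are flagged, not dropped", {
  rec <- rbind(make_records(n = 992, order = "Lepidoptera"),
               make_records(n = 6, order = "Mecoptera"),
               make_records(n = 2, order = "Zygentoma"))
  comp <- order_composition(rec)
  expect_equal(nrow(comp), 3)
  expect_false(comp$display[comp$order == "Zygentoma"]) # 0.2% < 0.5%
  expect_true(comp$display[comp$order == "Mecoptera"])  # 0.6% >= 0.5%
  expect_equal(comp$observation_share[comp$order == "Mecoptera"], 0.6)
})

test_that("platform correlations recover identity and rank reversal", {
  ords <- c("Lepidoptera", "Coleoptera", "Diptera")
  p1 <- make_records(order = rep(ords, times = c(1, 2, 3)))
  p2 <- make_records(order = rep(ords, times = c(3, 2, 1)))
  p3 <- make_records(order = rep(ords, times = c(1, 2, 3)))
  res <- platform_order_correlation(list(a = p1, b = p2, c = p3))
  expect_equal(res$estimate["a", "c"], 1)
  expect_equal(res$estimate["a", "b"], -1)
  expect_equal(res$estimate, t(res$estimate))
  expect_equal(res$n, 3)

  few <- make_records(order = c("Lepidoptera", "Lepidoptera"))
  expect_warning(res2 <- platform_order_correlation(list(a = p1, d = few)),
                 "< 3 distinct orders")
  expect_true(is.na(res2$estimate["a", "d"]))
})

test_that("user matrix keeps only active users, columns sum to 1, sorted", {
  rec <- rbind(
    make_records(n = 11, user_id = "specialist", order = "Lepidoptera"),
    make_records(n = 20, user_id = "generalist",
                 order = rep(c("Lepidoptera", "Coleoptera"),
                             times = c(8, 12))),
    make_records(n = 5, user_id = "casual", order = "Diptera")
  )
  m <- user_order_matrix(rec)
  expect_equal(colnames(m), c("specialist", "generalist"))
  expect_false("casual" %in% colnames(m)) # 5 <= 10, excluded
  expect_equal(unname(colSums(m)), rep(1, 2))
  expect_equal(m["Lepidoptera", "specialist"], 1)
  expect_equal(m["Lepidoptera", "generalist"], 0.4)
  expect_warning(user_order_matrix(make_records(n = 3)), "no user")
})

test_that("user segmentation matches the Tukey fence oracle", {
  counts <- c(1, 1, 2, 2, 3, 100)
  rec <- make_records(n = sum(counts),
                      user_id = rep(sprintf("u%d", 1:6), counts))
  seg <- segment_users(rec)
  # oracle: Q3 + 1.5 IQR of the six counts
  q <- quantile(counts, c(0.25, 0.75), names = FALSE)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  expect_equal(seg$fence, fence)
  expect_equal(seg$leading, "u6")
  expect_setequal(seg$sporadic, sprintf("u%d", 1:5))
  expect_equal(unname(seg$shares["leading"]), 100 * 100 / 109)

  flat <- make_records(n = 25, user_id = rep(sprintf("f%d", 1:5), each = 5))
  seg2 <- segment_users(flat)
  expect_length(seg2$leading, 0)
  expect_length(seg2$sporadic, 5)
})

test_that("leading and sporadic sets are disjoint when the fence is high", {
  set.seed(2)
  for (i in 1:5) {
    counts <- pmax(1, round(rlnorm(40, 2, 1.2)))
    rec <- make_records(n = sum(counts),
                        user_id = rep(sprintf("w%02d", 1:40), counts))
    seg <- segment_users(rec)
    if (seg$fence > 10) {
      expect_length(intersect(seg$leading, seg$sporadic), 0)
    }
    expect_setequal(c(seg$leading, seg$sporadic, seg$other),
                    sprintf("w%02d", 1:40))
  }
})

test_that("Shannon diversity matches closed forms and a brute-force oracle", {
  one <- make_records(n = 5, species = "only f")
  expect_equal(unname(shannon_per_order(one)), 0)
  four <- make_records(n = 8, species = sprintf("sp%d f", rep(1:4, 2)))
  expect_equal(unname(shannon_per_order(four)), log(4))
  skew <- make_records(n = 10, species = rep(c("a f", "b f"), c(9, 1)))
  expect_equal(unname(shannon_per_order(skew)),
               -(0.9 * log(0.9) + 0.1 * log(0.1)))

  set.seed(9)
  for (i in 1:10) {
    k <- sample(2:12, 1)
    cnt <- sample(1:20, k, replace = TRUE)
    rec <- make_records(n = sum(cnt),
                        species = rep(sprintf("s%02d f", 1:k), cnt),
                        order = "Odonata")
    p <- cnt / sum(cnt)
    expect_equal(unname(shannon_per_order(rec)["Odonata"]),
                 -sum(p * log(p)), tolerance = 1e-12)
  }
})

test_that("group correlations handle linearity, reversal and log transform", {
  x <- setNames(c(1, 2, 3, 4, 5), letters[1:5])
  expect_equal(group_correlations(x, 2 * x, "pearson")$estimate, 1)
  y_rev <- setNames(c(5, 4, 3, 2, 1), letters[1:5])
  expect_equal(group_correlations(x, y_rev, "spearman")$estimate, -1)
  expect_warning(group_correlations(setNames(c(0, 2, 5), letters[1:3]),
                                    setNames(c(1, 2, 3), letters[1:3]),
                                    "pearson", log_transform = TRUE),
                 "offset")
})

test_that("proportionality index is 1 for exactly proportional sampling", {
  rec <- make_range_records(ranges = c(2, 4, 6, 9),
                            counts = 3 * c(2, 4, 6, 9))
  idx <- proportionality_index(rec, periods = NULL)
  expect_equal(idx$value, 1)
  expect_equal(idx$n_species, 4)
})

test_that("proportionality index matches the closed-form OLS oracle", {
  ranges <- c(1, 2, 3, 4)
  counts <- c(10, 2, 10, 4)
  rec <- make_range_records(ranges, counts)
  idx <- proportionality_index(rec, periods = NULL)
  expect_equal(idx$value, ols_r2_oracle(ranges, counts), tolerance = 1e-10)
})

test_that("proportionality index ignores species labels and count scaling", {
  ranges <- c(2, 3, 5, 7, 11)
  counts <- c(6, 5, 12, 8, 30)
  r1 <- make_range_records(ranges, counts)
  idx1 <- proportionality_index(r1, periods = NULL)
  # relabel species
  r2 <- r1
  r2$species <- sub("Species", "Taxon", r2$species)
  expect_equal(proportionality_index(r2, periods = NULL)$value, idx1$value)
  # uniform tripling of all record counts
  r3 <- make_range_records(ranges, 3 * counts)
  expect_equal(proportionality_index(r3, periods = NULL)$value, idx1$value,
               tolerance = 1e-10)
  # undefined with < 3 species
  expect_warning(
    out <- proportionality_index(make_range_records(c(1, 2), c(3, 3)),
                                 periods = default_periods()),
    "fewer than")
  expect_true(all(is.na(out$value[out$period != "2012-2022"])))
})
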