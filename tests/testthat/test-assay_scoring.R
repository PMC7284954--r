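test_that("weighted_disease_index matches the count-weighted mean", {
  expect_equal(weighted_disease_index(c(5, 0, 0, 0, 0)), 0.0)
  expect_equal(weighted_disease_index(c(0, 0, 0, 0, 3)), 4.0)
  expect_equal(weighted_disease_index(c(2, 1, 1, 0, 0)), 0.75)
  # matrix input vectorizes
  m <- rbind(c(5, 0, 0, 0, 0), c(0, 0, 0, 0, 3))
  colnames(m) <- paste0("n", 0:4)
  expect_equal(weighted_disease_index(m), c(0, 4))
})

test_that("weighted_disease_index rejects unscoreable input", {
  expect_error(weighted_disease_index(c(0, 0, 0, 0, 0)), "unscoreable")
  expect_error(weighted_disease_index(c(-1, 1, 0, 0, 0)), "non-negative")
  expect_error(weighted_disease_index(c(1, 2, 3)), "5 categories")
})

test_that("disease index is bounded, pure-category exact, and scale-invariant", {
  set.seed(41)
  for (i in 1:50) {
    counts <- rpois(5, 3)
    if (sum(counts) == 0) counts[1] <- 1
    di <- weighted_disease_index(counts)
    expect_gte(di, 0); expect_lte(di, 4)
    k <- sample(0:4, 1)
    pure <- integer(5); pure[k + 1] <- sample(1:9, 1)
    expect_equal(weighted_disease_index(pure), k)
    expect_equal(weighted_disease_index(counts * sample(2:5, 1)), di)
  }
})

test_that("standardized_di_10day reproduces hand-worked cases", {
  # points exactly on DI = 0.2 * day
  expect_equal(standardized_di_10day(c(3, 6, 9), di = 0.2 * c(3, 6, 9)), 2.0)
  # day 18 excluded; b = 50.4/224
  expect_equal(standardized_di_10day(c(4, 8, 12, 18), di = c(1.0, 1.6, 2.8, 3.9)),
               2.25)
  # death rule keeps only first two fully-dead points, then clips
  expect_equal(standardized_di_10day(c(2, 4, 6, 8), di = c(4, 4, 4, 4)), 4.0)
  fit <- fit_timecourse(c(2, 4, 6, 8), di = c(4, 4, 4, 4))
  expect_equal(fit$di10_raw, 12)
  expect_equal(fit$n_used, 2)
})

test_that("standardized_di_10day matches the normal-equation oracle", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    day <- sort(sample(1:16, n))
    di <- pmin(runif(n, 0, 4.2), 4)
    expect_equal(standardized_di_10day(day, di = di),
                 oracle_di10(day, di), tolerance = 1e-12)
  }
})

test_that("exclusion rules are idempotent and order-independent", {
  day <- c(3, 6, 9, 12, 15, 18)
  di <- c(1.2, 2.4, 4, 4, 4, 4)
  once <- fit_timecourse(day, di = di)
  # refit on the retained observations: same answer
  keep_day <- c(3, 6, 9, 12)  # day > 16 dropped, 3rd/4th dead points dropped
  again <- fit_timecourse(keep_day, di = di[1:4])
  expect_equal(once$di10, again$di10)
  # shuffled input rows give the same fit
  set.seed(1)
  o <- sample(seq_along(day))
  expect_equal(fit_timecourse(day[o], di = di[o])$di10, once$di10)
})

test_that("degenerate time courses raise errors", {
  expect_error(standardized_di_10day(c(18, 20), di = c(1, 2)), "insufficient data")
  expect_error(standardized_di_10day(0, di = 1), "slope undefined|insufficient")
  expect_error(standardized_di_10day(numeric(0), di = numeric(0)), "non-empty")
  expect_error(fit_timecourse(c(3, 3), di = c(1, 1)), "strictly increasing")
})

test_that("growth_rate applies the same machinery to leaf counts", {
  expect_equal(growth_rate(c(2, 4, 8), leaves = 0.5 * c(2, 4, 8)), 0.5)
  expect_equal(growth_rate(c(5, 10), leaves = c(4, 4)), 0.48)
  expect_error(growth_rate(c(17, 20), leaves = c(3, 4)), "insufficient data")
  # death truncation driven by the disease index
  gr <- growth_rate(c(2, 4, 6, 8), leaves = c(2, 4, 4, 4), di = c(4, 4, 4, 4))
  expect_equal(gr, (2 * 2 + 4 * 4) / (4 + 16))
})

test_that("OLS-with-intercept alternative differs when a nonzero intercept exists", {
  day <- c(2, 4, 6, 8)
  y <- 1 + 0.3 * day
  expect_equal(fit_timecourse(day, di = y, origin = FALSE)$slope, 0.3)
  expect_gt(fit_timecourse(day, di = y, origin = TRUE)$slope, 0.3)
})

test_that("mean_lesion_score averages sections and guards the scale", {
  expect_equal(mean_lesion_score(c(0, 0, 0)), 0)
  expect_equal(mean_lesion_score(c(1, 1, 1)), 1)
  expect_equal(mean_lesion_score(c(0, 0.5, 1, 0.5)), 0.5)
  expect_error(mean_lesion_score(numeric(0)), "no section scores")
  expect_error(mean_lesion_score(c(0, 0.3, 1)), "0, 0.5 or 1")
  expect_warning(mean_lesion_score(c(0, 1)), "3-7")
})

test_that("classification matches the published bands", {
  expect_equal(as.character(classify_seedling(6.6)), "Strong Pathogen")
  expect_equal(as.character(classify_seedling(2.2)), "Pathogen")
  expect_equal(as.character(classify_seedling(0.0)), "Nonpathogen")
  # chlorosis floor and weak band
  expect_equal(as.character(classify_seedling(0.02)), "Nonpathogen")
  expect_equal(as.character(classify_seedling(0.5)), "Weak Pathogen")
  # rounding half-up to one decimal decides the boundary
  expect_equal(as.character(classify_seedling(1.95)), "Pathogen")
  expect_equal(as.character(classify_seedling(4.05)), "Strong Pathogen")
  expect_error(classify_seedling(-0.1), "non-negative")

  expect_equal(as.character(classify_mature(0.05)), "Nonpathogen")
  expect_equal(as.character(classify_mature(1.0)), "Strong Pathogen")
  expect_equal(as.character(classify_mature(0.2)), "Weak Pathogen")
  expect_equal(as.character(classify_mature(0.5)), "Pathogen")
  expect_error(classify_mature(1.2), "lie in")
})

test_that("classification is monotone in the index", {
  grid_s <- seq(0, 6, by = 0.01)
  cls <- classify_seedling(grid_s)
  expect_true(all(diff(as.integer(cls)) >= 0))
  grid_m <- seq(0, 1, by = 0.001)
  clm <- classify_mature(grid_m)
  expect_true(all(diff(as.integer(clm)) >= 0))
})

test_that("count_above_threshold behaves on edges", {
  expect_equal(count_above_threshold(numeric(0), 2), 0)
  x <- c(0.5, 1.5, 2.5)
  expect_equal(count_above_threshold(x, 0), 3)
  expect_equal(count_above_threshold(c(x, NA), 2), 1)
})

test_that("score_seedling_assay aggregates replicates per isolate", {
  obs <- rbind(
    data.frame(isolate_id = "A", lineage = "australis", replicate = 1,
               day = c(5, 10), n0 = c(2, 0), n1 = c(2, 2), n2 = c(0, 2),
               n3 = 0, n4 = 0),
    data.frame(isolate_id = "A", lineage = "australis", replicate = 2,
               day = c(5, 10), n0 = c(2, 0), n1 = c(2, 2), n2 = c(0, 2),
               n3 = 0, n4 = 0)
  )
  res <- score_seedling_assay(obs)
  expect_equal(nrow(res), 1)
  expect_equal(res$n_replicates, 2)
  # per replicate: DI = 0.5 at day 5, 1.5 at day 10 -> b = 17.5/125 = 0.14
  expect_equal(res$standardized_di, 1.4)
  expect_equal(as.character(res$seedling_class), "Weak Pathogen")
})

test_that("parameter recovery: noiseless slopes are recovered within rounding", {
  cfg <- seedling_sim_config(seed = 11, n_isolates = 20, n_replicates = 2,
                             noise = FALSE,
                             class_mix = c(strong = 0, weak = 1, nonpathogen = 0))
  sim <- simulate_seedling_assay(cfg)
  for (r in seq_len(nrow(sim$truth))) {
    d <- sim$observations[sim$observations$isolate_id == sim$truth$isolate_id[r] &
                          sim$observations$replicate == sim$truth$replicate[r], ]
    di10 <- standardized_di_10day(d$day, counts = d)
    # integer leaf counts quantize the index; error bounded by 10*0.5/total
    expect_lt(abs(di10 - sim$truth$di10[r]), 0.35)
  }
})
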