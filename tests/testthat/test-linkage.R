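test_that("double-crossover filter removes exactly the single nested discordant call", {
  # single homozygote nested in a heterozygous tract -> scored as missing
  f <- filter_double_crossovers(gm("HHAHH"))
  expect_equal(f$removals$marker, "m3")
  expect_true(is.na(unclass(f$genotypes)[1L, 3L]))
  cc <- count_crossovers(f$genotypes)
  expect_equal(sum(cc$intervals$events), 0L)

  # runs of two survive and yield two crossovers
  f2 <- filter_double_crossovers(gm("HHAAHH"))
  expect_equal(nrow(f2$removals), 0L)
  expect_equal(sum(count_crossovers(f2$genotypes)$intervals$events), 2L)

  # a flip at the chromosome end has no flank on both sides
  f3 <- filter_double_crossovers(gm("AHHHH"))
  expect_equal(nrow(f3$removals), 0L)
  expect_equal(sum(count_crossovers(f3$genotypes)$intervals$events), 1L)

  # nearest non-missing neighbours are used across missing calls
  f4 <- filter_double_crossovers(gm("H.A.H"))
  expect_equal(f4$removals$marker, "m3")
})

test_that("filtering is idempotent and applied simultaneously, not iterated", {
  set.seed(42)
  for (rep in 1:20) {
    g <- random_gm(30, 8, miss = 0.15)
    f1 <- filter_double_crossovers(g)
    f2 <- filter_double_crossovers(f1$genotypes)
    expect_equal(nrow(f2$removals), 0L)
    expect_identical(unclass(f2$genotypes), unclass(f1$genotypes))
  }
  # alternating singletons: every interior call has opposite-state flanks,
  # so all three are judged (against the original matrix) in one pass
  f <- filter_double_crossovers(gm("HAHAH"))
  expect_equal(sort(f$removals$marker), c("m2", "m3", "m4"))
})

test_that("crossover counting scores state changes and merged spans correctly", {
  rows <- c(rep("HHHH", 90), rep("HHAA", 10))   # 10 flips in interval 2-3
  g <- gm(rows)
  cc <- count_crossovers(filter_double_crossovers(g)$genotypes)
  expect_equal(cc$intervals$events, c(0L, 10L, 0L))
  expect_equal(cc$intervals$r[2L], 0.10)
  expect_equal(cc$intervals$n_scored, rep(100L, 3L))

  # middle call missing: event attributed to the merged two-marker span
  g2 <- gm("H.A")
  cc2 <- count_crossovers(g2, filtered = TRUE)
  expect_equal(cc2$intervals$events, c(0L, 0L))
  expect_equal(nrow(cc2$merged_events), 1L)
  expect_equal(cc2$merged_events$left_marker, "m1")
  expect_equal(cc2$merged_events$right_marker, "m3")
  expect_equal(cc2$per_individual$crossovers, 1L)
})

test_that("counting refuses unfiltered input and mismatched marker maps", {
  g <- gm("HHAHH")
  expect_error(count_crossovers(g), "filter_double_crossovers")
  other <- marker_map("2", paste0("x", 1:5), 1:5 * 2e5)
  expect_error(count_crossovers(filter_double_crossovers(g)$genotypes, other),
               "does not match")
})

test_that("per-individual crossovers reconcile with interval events", {
  set.seed(7)
  for (rep in 1:10) {
    g <- random_gm(40, 8, miss = 0)
    cc <- count_crossovers(g, filtered = TRUE)
    expect_equal(sum(cc$per_individual$crossovers), sum(cc$intervals$events))
  }
  # with missing data the merged-span events make up the difference
  g <- random_gm(40, 8, miss = 0.2)
  cc <- count_crossovers(g, filtered = TRUE)
  expect_equal(sum(cc$per_individual$crossovers),
               sum(cc$intervals$events) + nrow(cc$merged_events))
})

test_that("Kosambi map function matches its closed form and is interference-consistent", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.01), 25 * log(1.02 / 0.98), tolerance = 1e-12)
  expect_equal(kosambi_cm(0.01), 1.000133, tolerance = 1e-6)
  expect_equal(kosambi_cm(0.10), 25 * log(1.5), tolerance = 1e-12)
  expect_equal(kosambi_cm(0.10), 10.136628, tolerance = 1e-6)
  # strictly increasing, and always at least the raw 100 r
  r <- seq(0, 0.49, by = 0.01)
  expect_true(all(diff(kosambi_cm(r)) > 0))
  expect_true(all(kosambi_cm(r) >= 100 * r))
  expect_error(kosambi_cm(0.5), "0.5")
  # additivity under the Kosambi addition rule, to machine precision
  r1 <- runif(50, 0, 0.45); r2 <- runif(50, 0, 0.45)
  r12 <- (r1 + r2) / (1 + 4 * r1 * r2)
  expect_equal(kosambi_cm(r12), kosambi_cm(r1) + kosambi_cm(r2),
               tolerance = 1e-12)
})

test_that("cM/Mb conversion scales with physical length and reports 0 for 0 events", {
  cm <- kosambi_cm(10 / 1000)
  expect_equal(rate_cm_per_mb(cm, 150000), 6.66755, tolerance = 1e-4)
  expect_equal(rate_cm_per_mb(kosambi_cm(0), 150000), 0)
  expect_equal(rate_cm_per_mb(cm, 300000), rate_cm_per_mb(cm, 150000) / 2)
  expect_error(rate_cm_per_mb(1, 0), "positive")
})

test_that("bootstrap CI brackets the point estimate; zero-event intervals use the binomial bound", {
  set.seed(1)
  ci <- permutation_ci(1000, 10000, 150000, replicates = 10000)
  rate <- rate_cm_per_mb(kosambi_cm(0.1), 150000)
  expect_lt(ci["ci_low"], rate)
  expect_gt(ci["ci_high"], rate)
  expect_gte(ci["ci_low"], 0)
  ci0 <- permutation_ci(0, 1000, 150000, replicates = 1000)
  expect_equal(unname(ci0), c(0, 0))
  expect_warning(permutation_ci(10, 100, 1e5, replicates = 50), "100")

  expect_equal(zero_event_upper_bound(1), 0.95)
  expect_equal(zero_event_upper_bound(59), 1 - 0.05^(1 / 59), tolerance = 1e-12)
  expect_equal(zero_event_upper_bound(59), 0.0495076, tolerance = 1e-5)
  expect_equal(zero_event_upper_bound(1158), 0.0025837, tolerance = 1e-4)
  expect_error(zero_event_upper_bound(0), "at least 1")
})

test_that("build_map attaches the binomial upper bound to zero-event intervals", {
  g <- gm(rep("HHH", 50))
  m <- build_map(g, replicates = 200, seed = 1)
  expect_equal(m$intervals$rate, c(0, 0))
  expect_equal(m$intervals$ci_low, c(0, 0))
  ub <- rate_cm_per_mb(kosambi_cm(zero_event_upper_bound(50)), 1e5)
  expect_equal(m$intervals$ci_high, rep(ub, 2L))
})

test_that("heterogeneity test calibrates under the null and detects a 10x interval", {
  expect_error(heterogeneity_test(data.frame(events = 1, n_scored = 10,
                                             left = 0, right = 1e5)),
               "at least 2")
  # df is the interval count minus the two size-model parameters
  iv <- data.frame(events = c(10, 12, 9, 11), n_scored = rep(1000, 4),
                   left = c(0, 1, 3, 6) * 1e5, right = c(1, 3, 6, 10) * 1e5)
  ht <- heterogeneity_test(iv)
  expect_equal(ht$df, 2L)
  # null calibration: equal rates and sizes -> ~uniform p
  set.seed(11)
  p <- replicate(200, {
    ev <- rbinom(6, 1000, 0.05)
    heterogeneity_test(data.frame(events = ev, n_scored = rep(1000, 6),
                                  left = (0:5) * 1e5, right = (1:6) * 1e5))$p
  })
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.12)
  # strong signal: one interval at 10x the rate
  ev <- c(rbinom(5, 2000, 0.01), rbinom(1, 2000, 0.1))
  ht2 <- heterogeneity_test(data.frame(events = ev, n_scored = rep(2000, 6),
                                       left = (0:5) * 1e5, right = (1:6) * 1e5))
  expect_lt(ht2$p, 1e-5)
})

test_that("recmap methods print and summarize without error", {
  sc <- cross_scenario(r = c(0.05, 0.08), individuals = 300, seed = 2)
  mm <- marker_map("2", c("a", "b", "c"), c(1e5, 5e5, 9e5))
  m <- build_map(simulate_backcross(sc, mm)$genotypes, replicates = 200, seed = 3)
  expect_output(print(m), "Recombination map")
  expect_output(print(summary(m)), "heterogeneity|Total crossovers")
  expect_silent(grDevices::pdf(NULL)) ; plot(m); grDevices::dev.off()
})
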