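test_that("modification_fraction implements intensity-weighted pooling", {
  # symmetric case: one of two equal-intensity single-N peptides deamidated
  rec <- make_records(c("ANGK", "ANGK"),
                      mods = list(mods1(2, "deamidation"),
                                  mods1(integer(0), character(0))),
                      intensity = c(100, 100))
  expect_equal(modification_fraction(rec, "N", "deamidation"), 50)

  # saturation
  rec2 <- make_records(c("ANGNK", "ANGK"),
                       mods = list(mods1(c(2, 4), "deamidation"),
                                   mods1(2, "deamidation")))
  expect_equal(modification_fraction(rec2, "N", "deamidation"), 100)

  # hand-evaluated weighted case: A (I=300, 1 of 2 N) + B (I=100, 0 of 1 N)
  rec3 <- make_records(c("ANGNK", "ANGK"),
                       mods = list(mods1(2, "deamidation"),
                                   mods1(integer(0), character(0))),
                       intensity = c(300, 100))
  expect_equal(modification_fraction(rec3, "N", "deamidation"),
               100 * 300 / (300 * 2 + 100 * 1), tolerance = 1e-12)

  # undefined (no residue anywhere) is NA, not 0
  rec4 <- make_records("AGGK")
  expect_true(is.na(modification_fraction(rec4, "N", "deamidation")))
  expect_false(identical(modification_fraction(rec4, "N", "deamidation"), 0))

  # the unweighted aggregation switch: equal weights per record
  expect_equal(modification_fraction(rec3, "N", "deamidation",
                                     weighting = "unweighted"),
               100 * 1 / 3, tolerance = 1e-12)
  expect_equal(modification_fraction(rec, "N", "deamidation",
                                     weighting = "unweighted"), 50)
})

test_that("estimator is scale-invariant and a convex combination", {
  sim <- simulate_evidence(simulation_config(seed = 3, n_ancient = 80,
                                             n_contaminant = 0,
                                             samples = "s1"))
  rec <- sim$records
  est <- modification_fraction(rec, c("N", "Q"), "deamidation")
  rec_scaled <- rec
  rec_scaled$intensity <- rec_scaled$intensity * 1e3
  expect_equal(modification_fraction(rec_scaled, c("N", "Q"), "deamidation"),
               est, tolerance = 1e-9)
  # bounded by the per-record ratios
  ratios <- vapply(seq_len(nrow(rec)), function(i) {
    one <- rec[i, ]
    modification_fraction(one, c("N", "Q"), "deamidation")
  }, numeric(1))
  ratios <- ratios[!is.na(ratios)]
  expect_gte(est, min(ratios))
  expect_lte(est, max(ratios))
})

test_that("N and Q are estimated separately and panels are respected", {
  rec <- make_records(c("ANGK", "AQGK"),
                      mods = list(mods1(2, "deamidation"),
                                  mods1(integer(0), character(0))))
  expect_equal(modification_fraction(rec, "N", "deamidation"), 100)
  expect_equal(modification_fraction(rec, "Q", "deamidation"), 0)
  prof <- group_profile(assign_groups(rec, character(0)),
                        panel = tibble::tibble(residue = "M",
                                               mod_name = "oxidation"),
                        n_boot = 50, seed = 1)
  expect_equal(nrow(prof), 0)  # no M anywhere -> no rows
})

test_that("bootstrap CI is degenerate when resampling cannot vary", {
  one <- make_records("ANGK", mods = list(mods1(2, "deamidation")))
  est <- bootstrap_ci(one, "N", "deamidation", n_boot = 200, seed = 5)
  expect_equal(est$point_pct, 100)
  expect_equal(est$ci_low_pct, 100)
  expect_equal(est$ci_high_pct, 100)

  fifty <- one[rep(1, 50), ]
  fifty$mods <- rep(list(mods1(2, "deamidation")), 50)
  est2 <- bootstrap_ci(fifty, "N", "deamidation", n_boot = 200, seed = 5)
  expect_equal(est2$ci_high_pct - est2$ci_low_pct, 0)
})

test_that("bootstrap is deterministic for a fixed seed and leaves the RNG alone", {
  sim <- simulate_evidence(simulation_config(seed = 9, n_ancient = 60,
                                             n_contaminant = 0, samples = "s1"))
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  a <- bootstrap_ci(sim$records, c("N", "Q"), "deamidation", seed = 7)
  after <- runif(1)
  b <- bootstrap_ci(sim$records, c("N", "Q"), "deamidation", seed = 7)
  expect_identical(a, b)
  expect_identical(before, after)  # global RNG stream undisturbed
})

test_that("point estimate recovers the simulated site probability at n=2000", {
  # the estimate at a single n=2000 draw still carries ~1 point of Monte
  # Carlo noise, so the bias is judged on the mean over replicates
  ests <- vapply(1:5, function(s) {
    sim <- simulate_evidence(simulation_config(
      seed = 20 + s, n_ancient = 2000, n_contaminant = 0,
      deamidation_prob_ancient = 0.4, samples = "s1"))
    modification_fraction(sim$records, c("N", "Q"), "deamidation")
  }, numeric(1))
  expect_lt(abs(mean(ests) - 40), 2)
})

test_that("group profiles separate ancient from modern deamidation", {
  sim <- simulate_evidence(simulation_config(
    seed = 31, n_ancient = 400, n_contaminant = 400,
    deamidation_prob_ancient = 0.5, samples = "s1"))
  rec <- assign_groups(filter_records(sim$records, quiet = TRUE),
                       sim$contaminants)
  prof <- group_profile(
    rec, panel = tibble::tibble(residue = "NQ", mod_name = "deamidation"),
    n_boot = 500, seed = 2)
  orig <- prof[prof$group == "original", ]
  cont <- prof[prof$group == "contaminant", ]
  expect_gt(orig$point_pct, cont$point_pct)
  expect_gt(orig$ci_low_pct, cont$ci_high_pct)  # non-overlapping CIs

  # empty contaminant group: rows simply absent
  sim0 <- simulate_evidence(simulation_config(seed = 32, n_ancient = 50,
                                              n_contaminant = 0,
                                              samples = "s1"))
  prof0 <- group_profile(
    assign_groups(sim0$records, sim0$contaminants),
    panel = tibble::tibble(residue = "NQ", mod_name = "deamidation"),
    n_boot = 50, seed = 3)
  expect_false("contaminant" %in% prof0$group)
})
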