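# Aggregation, method-comparison statistics, sensitivity analysis.

test_that("three-level aggregation matches hand-computed values", {
  df <- data.frame(subject = c(1, 1, 2, 2), v = c(1, 3, 5, 7))
  agg <- aggregate_trials(df)
  s <- agg$summary[agg$summary$variable == "v", ]
  expect_equal(s$overall_mean, 4)
  expect_equal(s$intra_subject, sqrt(2), tolerance = 1e-12)
  expect_equal(s$inter_subject, stats::sd(c(2, 6)), tolerance = 1e-12)
  expect_equal(c(s$min_subject_mean, s$max_subject_mean), c(2, 6))

  # identical trials: both variabilities vanish
  df2 <- data.frame(subject = rep(1:3, each = 4), v = 2.5)
  s2 <- aggregate_trials(df2)$summary
  expect_equal(s2$intra_subject, 0)
  expect_equal(s2$inter_subject, 0)

  # permutation invariance over trials and subjects
  set.seed(3)
  df3 <- data.frame(subject = rep(1:4, each = 5), v = rnorm(20))
  p <- sample(nrow(df3))
  expect_equal(aggregate_trials(df3)$summary,
               aggregate_trials(df3[p, ])$summary)
  expect_error(aggregate_trials(df3[0, ]),
               class = "heelstrike_input_error")
})

test_that("single-trial subjects have their SD flagged absent", {
  df <- data.frame(subject = c(1, 2, 2), v = c(1, 2, 4))
  agg <- aggregate_trials(df)
  ss <- agg$subject_summary
  expect_true(is.na(ss$sd[ss$subject == 1]))
  expect_equal(ss$sd[ss$subject == 2], stats::sd(c(2, 4)))
})

test_that("aggregation recovers generating variance components", {
  set.seed(17)
  hits <- replicate(8, {
    mu <- rnorm(12, 0, 1)                        # between-subject var 1.0
    df <- data.frame(subject = rep(1:12, each = 10),
                     v = rep(mu, each = 10) + rnorm(120, 0, 0.5))
    s <- aggregate_trials(df)$summary
    c(s$inter_subject^2, s$intra_subject^2)
  })
  # sampling check at n = 12: recovered within 50% on average
  expect_equal(mean(hits[1, ]), 1.0, tolerance = 0.5)
  expect_equal(mean(hits[2, ]), 0.25, tolerance = 0.5)
})

test_that("Friedman statistic matches closed forms and the reference", {
  X <- matrix(rep(c(10, 20, 30, 40, 50), each = 12), nrow = 12)
  f <- friedman_statistic(X)
  expect_equal(f$chi2, 48)
  expect_equal(f$df, 4L)
  expect_lt(f$p, 1e-9)

  Xt <- matrix(5, nrow = 12, ncol = 5)
  ft <- friedman_statistic(Xt)
  expect_equal(ft$chi2, 0)
  expect_equal(ft$p, 1)

  set.seed(21)
  for (i in 1:100) {
    n <- sample(3:15, 1); k <- sample(3:6, 1)
    X <- matrix(rnorm(n * k), n, k)
    f <- friedman_statistic(X)
    ref <- stats::friedman.test(X)
    expect_equal(f$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(f$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(friedman_statistic(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "heelstrike_input_error")
})

test_that("exact signed-rank p matches enumeration and the reference", {
  r <- signed_rank_exact(1:12)
  expect_equal(r$W_stat, 78)
  expect_equal(r$p, 2 / 4096, tolerance = 1e-14)
  expect_true(r$significant)

  sym <- signed_rank_exact(c(1, -1, 2, -2))
  expect_gte(sym$p, 0.99)

  expect_error(signed_rank_exact(c(0, 0)),
               class = "heelstrike_degenerate_error")

  set.seed(8)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    d <- round(rnorm(n, mean = 0.4), 3)
    d <- d[d != 0]
    if (length(d) < 3) next
    r <- signed_rank_exact(d)
    ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    expect_equal(r$W_stat, unname(ref$statistic))
    if (!anyDuplicated(abs(d)))
      expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("signed-rank power on shifted data matches the reference", {
  set.seed(31)
  agree <- replicate(200, {
    d <- rnorm(12, mean = 1, sd = 1)
    r <- signed_rank_exact(d, alpha = 0.05)
    ref <- stats::wilcox.test(d, exact = TRUE)
    c(r$p, ref$p.value)
  })
  expect_equal(agree[1, ], agree[2, ], tolerance = 1e-12)
  expect_equal(mean(agree[1, ] < 0.05), mean(agree[2, ] < 0.05))
})

test_that("zero heel-point offset reproduces the baseline bit-for-bit", {
  tr <- base_trial()
  sens <- heel_point_sensitivity(tr$channels, tr$markers,
                                 body_mass = 76.7,
                                 offset = c(0, 0, 0))
  expect_identical(coef(sens$baseline), coef(sens$shifted))
  expect_true(all(sens$deltas$relative_change == 0))
})

test_that("work is offset-invariant under pure translation", {
  tr <- base_trial()
  sens <- heel_point_sensitivity(tr$channels, tr$markers,
                                 body_mass = 76.7,
                                 offset = c(0.01, -0.01, -0.01))
  d <- sens$deltas
  expect_lt(abs(d$relative_change[d$variable == "W"]), 1e-9)
  expect_lt(abs(d$relative_change[d$variable == "dE_e"]), 1e-9)
})

test_that("segment rotation makes the energetics offset-sensitive but bounded", {
  deltas <- vapply(c(61, 62, 63), function(sd) {
    cfg <- sim_config(segment_tilt = c(0, 5), seed = sd,
                      noise_marker_sd = 5e-5, noise_channel_sd = 0,
                      sync_jitter = 0)
    tr <- simulate_trial(cfg)
    sens <- heel_point_sensitivity(tr$channels, tr$markers,
                                   body_mass = 76.7,
                                   offset = c(0.01, -0.01, -0.01))
    d <- sens$deltas
    d$relative_change[d$variable == "W"]
  }, numeric(1))
  expect_true(all(abs(deltas) > 0))
  expect_true(all(abs(deltas) < 0.25))
  expect_equal(length(unique(sign(deltas))), 1L)
})
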