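# hand-built replicate tables for the pure-arithmetic properties
fake_replicates <- function(delta_cost, delta_effect,
                            timepoint = "post", outcome = "qaly",
                            perspective = "societal") {
  out <- tibble::tibble(
    replicate = seq_along(delta_cost),
    timepoint = timepoint, perspective = perspective, outcome = outcome,
    delta_cost = delta_cost, delta_effect = delta_effect
  )
  structure(out, class = c("cea_replicates", class(out)))
}

test_that("ICER division matches the published worked-example arithmetic", {
  expect_equal(icer(1231, 0.30), 4103.333, tolerance = 1e-6)
  expect_equal(icer(1088, 0.16), 6800)
  expect_equal(icer(0, 0.3), 0)
  expect_warning(out <- icer(c(100, 50), c(0.5, 0)), "undefined")
  expect_equal(out, c(200, NA_real_))
})

test_that("net benefit is linear in willingness to pay and zero at the ICER", {
  expect_equal(net_benefit(50000, 0.09, 1231), 3269)
  expect_equal(net_benefit(0, 0.42, 1231), -1231)
  de <- 0.3; dc <- 1231
  expect_equal(net_benefit(icer(dc, de), de, dc), 0, tolerance = 1e-9)
  expect_error(net_benefit(-1, 0.1, 10), "nonnegative")
})

test_that("bootstrap replicates are reproducible and consistent with the sample", {
  an <- small_analysis(n = 30, seed = 8)
  r1 <- bootstrap_cea(an, B = 120, seed = 99, method = "cellmeans")
  r2 <- bootstrap_cea(an, B = 120, seed = 99, method = "cellmeans")
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- bootstrap_cea(an, B = 120, seed = 100, method = "cellmeans")
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))

  # replicate means track the full-sample estimator (bootstrap consistency)
  point <- incremental_estimates(an, method = "cellmeans")
  agg <- r1 %>%
    group_by(timepoint, perspective, outcome) %>%
    summarise(de = mean(delta_effect), dc = mean(delta_cost), .groups = "drop") %>%
    left_join(point, by = c("timepoint", "perspective", "outcome"))
  mc_se_e <- r1 %>%
    group_by(timepoint, perspective, outcome) %>%
    summarise(se = sd(delta_effect) / sqrt(dplyr::n()), .groups = "drop")
  expect_true(all(abs(agg$de - agg$delta_effect) <
                    5 * pmax(mc_se_e$se, 1e-8) + 1e-8))
})

test_that("mixed-model and cell-mean bootstrap agree on complete balanced data", {
  an <- small_analysis(n = 20, seed = 14)
  rm_ <- bootstrap_cea(an, B = 8, seed = 5, method = "mixed",
                       perspectives = "societal")
  rc <- bootstrap_cea(an, B = 8, seed = 5, method = "cellmeans",
                      perspectives = "societal")
  expect_equal(rm_$delta_effect, rc$delta_effect, tolerance = 1e-5)
  expect_equal(rm_$delta_cost, rc$delta_cost, tolerance = 1e-4)
})

test_that("quadrant proportions sum to one and put ties on the positive side", {
  q <- quadrant_proportions(fake_replicates(c(10, 20, 30), c(0.1, 0.2, 0.3)))
  expect_equal(unlist(q[, c("ne", "nw", "se", "sw")]),
               c(ne = 1, nw = 0, se = 0, sw = 0))
  qt <- quadrant_proportions(fake_replicates(c(0, -5), c(0, 0.1)))
  expect_equal(qt$ne, 0.5) # (0, 0) counts as northeast
  expect_equal(qt$se, 0.5)

  an <- small_analysis(n = 30, seed = 8)
  qs <- quadrant_proportions(bootstrap_cea(an, B = 60, seed = 1,
                                           method = "cellmeans"))
  expect_true(all(abs(qs$ne + qs$nw + qs$se + qs$sw - 1) < 1e-12))
  expect_error(quadrant_proportions(fake_replicates(numeric(0), numeric(0))),
               "empty")
})

test_that("quadrants split evenly under a null cost and effect difference", {
  set.seed(33)
  reps <- fake_replicates(rnorm(4000), rnorm(4000))
  q <- quadrant_proportions(reps)
  expect_lt(abs((q$ne + q$nw) - 0.5), 0.03) # costlier half
  expect_lt(abs((q$ne + q$se) - 0.5), 0.03) # more-effective half
})

test_that("the acceptability curve has the correct limits and bounds", {
  reps <- fake_replicates(
    delta_cost = c(-100, 50, 200, 400),
    delta_effect = c(0.1, 0.2, -0.05, 0.3)
  )
  curve <- ceac(reps, c(0, 1000, 1e7))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  # lambda = 0: cost-saving fraction; lambda -> inf: positive-effect fraction
  expect_equal(curve$probability[curve$lambda == 0], 0.25)
  expect_equal(curve$probability[curve$lambda == 1e7], 0.75)
  expect_error(ceac(reps, numeric(0)), "empty")
  expect_error(ceac(reps, c(10, 10)), "ascending")
})

test_that("the curve is monotone when every replicate effect is nonnegative", {
  set.seed(91)
  for (k in 1:5) {
    reps <- fake_replicates(rnorm(300, 500, 800), runif(300, 0, 0.4))
    p <- ceac(reps, seq(0, 40000, 500))$probability
    expect_true(all(diff(p) >= 0))
  }
})

test_that("a single replicate gives a step function jumping at its ICER", {
  # exactly representable pair so the tie at lambda = ICER is a true zero
  reps <- fake_replicates(1000, 0.5)
  ratio <- icer(1000, 0.5)
  grid <- sort(c(ratio - 1, ratio, ratio + 1, 0, 60000))
  p <- ceac(reps, grid)
  expect_equal(p$probability[p$lambda < ratio], c(0, 0))
  expect_equal(p$probability[p$lambda == ratio], 0) # tie: not cost-effective
  expect_equal(p$probability[p$lambda > ratio], c(1, 1))
})

test_that("bootstrap remission effects follow the binomial-difference law", {
  cfg <- trial_config(n_per_arm = 200)
  an <- small_analysis(config = cfg, seed = 55)
  reps <- bootstrap_cea(an, B = 2000, seed = 56, outcomes = "remission",
                        perspectives = "clinic", timepoints = "post",
                        method = "cellmeans")
  post <- an %>% filter(timepoint == "post")
  p_i <- mean(post$remission[post$arm == "intervention"])
  p_c <- mean(post$remission[post$arm == "control"])
  n <- 200
  set.seed(57)
  oracle <- rbinom(20000, n, p_i) / n - rbinom(20000, n, p_c) / n
  ks <- suppressWarnings(stats::ks.test(reps$delta_effect, oracle))
  expect_lt(unname(ks$statistic), 0.05)
})
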