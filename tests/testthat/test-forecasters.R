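# Toy 4-reading medoids with 3-reading prefixes and 1-step continuations
toy2 <- toy_cluster_model(rbind(c(5, 5, 5, 5.2), c(8, 8, 8, 8.1)))

test_that("MTSC copies the continuation of the nearest medoid", {
  expect_equal(mtsc_forecast(c(5.5, 5.4, 5.6), toy2, 1L), 5.2)
  expect_equal(mtsc_forecast(c(8, 8, 8), toy2, 1L), 8.1)

  one <- toy_cluster_model(matrix(c(6, 6, 6, 6.4, 6.6), 1))
  expect_equal(mtsc_forecast(c(9, 9, 9), one, 2L), c(6.4, 6.6))

  set.seed(3)
  model <- toy_cluster_model(matrix(runif(5 * 72, 4, 12), 5, 72))
  for (rep in 1:20) {
    h <- sample(c(3L, 6L), 1)
    fc <- mtsc_forecast(runif(72 - h, 4, 12), model, h)
    # output is always exactly the tail of some stored medoid
    tails <- model$medoid_series[, (72 - h + 1):72, drop = FALSE]
    expect_true(any(apply(tails, 1, function(t) isTRUE(all.equal(t, fc)))))
  }
  expect_error(mtsc_forecast(rep(5, 10), toy2, 4L), class = "range_error")
  expect_error(mtsc_forecast(rep(5, 5), toy2, 1L), class = "shape_error")
})

test_that("WMTSC weights follow the softmax of inverse distances", {
  w <- wmtsc_weights(c(1, 2))
  expect_equal(w, c(exp(1), exp(0.5)) / (exp(1) + exp(0.5)))
  expect_equal(round(w, 4), c(0.6225, 0.3775))

  # prefix (5,5,5) sits at distances exactly (1, 2) from these medoid
  # prefixes; continuations 4 and 8 blend to ~5.510 per component
  m <- toy_cluster_model(rbind(c(5, 5, 6, 4, 4, 4), c(5, 5, 7, 8, 8, 8)))
  out <- wmtsc_forecast(c(5, 5, 5), m, 3L, details = TRUE)
  expect_equal(out$distances, c(1, 2))
  expect_equal(round(out$weights, 4), c(0.6225, 0.3775))
  expect_equal(round(out$forecast, 3), rep(5.510, 3))

  # equal distances -> uniform weights -> plain average
  eq <- toy_cluster_model(rbind(c(5, 7, 4, 4), c(7, 5, 8, 8)))
  expect_equal(wmtsc_forecast(c(6, 6), eq, 2L), c(6, 6))

  # exact match short-circuits to that medoid
  expect_equal(wmtsc_forecast(c(8, 8, 8), toy2, 1L), 8.1)
  expect_equal(wmtsc_weights(c(0, 0, 1)), c(0.5, 0.5, 0))
})

test_that("WMTSC weights are a proper convex combination on random inputs", {
  set.seed(29)
  for (rep in 1:200) {
    k <- sample(2:8, 1); h <- sample(c(3L, 6L), 1)
    model <- toy_cluster_model(matrix(runif(k * 72, 3, 15), k, 72))
    out <- wmtsc_forecast(runif(72 - h, 3, 15), model, h, details = TRUE)
    expect_true(all(out$weights >= 0))
    expect_lt(abs(sum(out$weights) - 1), 1e-9)
    tails <- model$medoid_series[, (72 - h + 1):72, drop = FALSE]
    expect_true(all(out$forecast >= apply(tails, 2, min) - 1e-12))
    expect_true(all(out$forecast <= apply(tails, 2, max) + 1e-12))
  }
})

test_that("WMTSC collapses to MTSC as one distance vanishes", {
  set.seed(37)
  for (rep in 1:20) {
    k <- sample(2:5, 1); h <- 3L
    model <- toy_cluster_model(matrix(runif(k * 72, 4, 12), k, 72))
    j <- sample(k, 1)
    prefix <- model$medoid_series[j, 1:(72 - h)]
    prefix[1] <- prefix[1] + 1e-8   # d'_j = 1e-8, others O(1)
    expect_equal(wmtsc_forecast(prefix, model, h),
                 model$medoid_series[j, (72 - h + 1):72],
                 tolerance = 1e-6)
  }
})

test_that("Holt recursions are exact on constants, lines, and the hand trace", {
  expect_equal(holt_forecast(rep(6, 20), 0.3, 0.7, 4L), rep(6, 4))

  y <- 4 + 0.1 * (1:30)
  expect_lt(max(abs(holt_forecast(y, 1, 1, 6L) - (4 + 0.1 * (31:36)))), 1e-9)

  # step-by-step trace: l2=5.5 b2=0.5; l3=5.65 b3=0.325 -> 5.975
  expect_equal(holt_forecast(c(5.0, 5.5, 5.3), 0.5, 0.5, 1L), 5.975,
               tolerance = 1e-12)

  expect_error(holt_forecast(5, 0.5, 0.5, 1L), class = "size_error")
  expect_error(holt_forecast(c(5, 6), 0, 0.5, 1L), class = "config_error")
})

test_that("Holt grid search attains the exhaustive-scan minimum", {
  grid <- seq(0.1, 1, by = 0.1)
  # constant series: every pair ties at zero -> smallest grid values
  expect_identical(holt_fit(rep(7, 20))[c("alpha", "beta")],
                   list(alpha = 0.1, beta = 0.1))
  expect_equal(holt_fit(rep(7, 20))$sse, 0)

  set.seed(47)
  for (rep in 1:10) {
    y <- 6 + as.numeric(arima.sim(list(ar = 0.7), 40, sd = 0.4))
    fit <- holt_fit(y, grid, grid)
    all_sse <- outer(grid, grid, Vectorize(function(a, b)
      glucluster:::holt_state(y, a, b)$sse))
    expect_equal(fit$sse, min(all_sse), tolerance = 1e-12)
  }
})

test_that("tree learners reproduce zero-variance targets and are seeded", {
  train <- matrix(6, 25, 72)  # identical constant series
  for (kind in c("random_forest", "gradient_boosting")) {
    model <- suppressWarnings(fit_global(train, kind, h = 3L, seed = 1L))
    p <- predict_global(model, rep(6, 69))
    expect_equal(p, rep(6, 3), tolerance = 1e-6)
  }

  coh <- generate_cohort(cohort_config(40, gap_rate_single = 0,
                                       gap_rate_long = 0, seed = 51L))
  for (kind in c("random_forest", "gradient_boosting")) {
    m1 <- fit_global(coh$values, kind, h = 3L, seed = 9L)
    m2 <- fit_global(coh$values, kind, h = 3L, seed = 9L)
    q <- coh$values[1:5, 1:69]
    expect_identical(predict_global(m1, q), predict_global(m2, q))
  }
})

test_that("cluster routing follows the nearest-medoid assignment", {
  set.seed(61)
  coh <- generate_cohort(cohort_config(
    60, archetypes = default_archetypes(c("stable_target", "stable_elevated")),
    gap_rate_single = 0, gap_rate_long = 0, seed = 61L))
  cm <- fit_cluster_model(coh$values, k = 2L)
  rt <- fit_cluster_routed(coh$values, cm, "gradient_boosting", 3L, seed = 2L)

  # routed to the same cluster assign_nearest_cluster reports; a prefix equal
  # to a medoid prefix routes to that cluster's learner
  for (i in c(1, 10, 30)) {
    p <- coh$values[i, 1:69]
    cl <- assign_nearest_cluster(p, cm, 69L)$cluster
    expect_equal(predict_cluster_routed(rt, p),
                 as.numeric(predict_learner(rt$learners[[cl]],
                                            matrix(p, 1))))
  }
  expect_error(predict_cluster_routed(rt, rep(6, 10)), class = "shape_error")
})

test_that("with one cluster, routed and global learners coincide", {
  coh <- generate_cohort(cohort_config(30, gap_rate_single = 0,
                                       gap_rate_long = 0, seed = 71L))
  cm <- fit_cluster_model(coh$values, k = 1L)
  # fit_cluster_routed seeds cluster 1 at seed + 100
  rt <- fit_cluster_routed(coh$values, cm, "gradient_boosting", 3L, seed = 5L)
  gl <- fit_global(coh$values, "gradient_boosting", 3L, seed = 105L)
  q <- coh$values[1:8, 1:69]
  expect_equal(predict_cluster_routed(rt, q), predict_global(gl, q))
})

test_that("undersized clusters fall back to the global learner", {
  set.seed(81)
  x <- rbind(matrix(6 + rnorm(30 * 72, 0, 0.1), 30, 72),
             matrix(12 + rnorm(3 * 72, 0, 0.1), 3, 72))
  cm <- fit_cluster_model(x, k = 2L)
  rt <- fit_cluster_routed(x, cm, "gradient_boosting", 3L, seed = 1L,
                           min_cluster_size = 10L)
  small <- which(tabulate(cm$labels, 2L) < 10L)
  expect_null(rt$learners[[small]])
  expect_false(is.null(rt$fallback))
  p <- x[31, 1:69]
  expect_true(all(is.finite(predict_cluster_routed(rt, p))))
})

test_that("a learner trained on one homogeneous cluster beats a mixed global", {
  # homogeneous training data help when the target pattern is noiseless:
  # a model trained only on downward-trend nights forecasts held-out
  # downward-trend nights better than one trained on the mixed cohort
  arch4 <- default_archetypes(c("stable_target", "stable_elevated",
                                "downward_trend", "upward_trend"))
  coh <- generate_cohort(cohort_config(
    250, archetypes = arch4, noise_phi = 0, noise_sigma = 0,
    offset_sigma = 0.5, gap_rate_single = 0, gap_rate_long = 0, seed = 91L))
  down_id <- 3L
  h <- 6L; P <- 72L - h
  train <- coh$values[1:200, ]; lab <- coh$archetype_id[1:200]
  hold <- coh$values[201:250, ][coh$archetype_id[201:250] == down_id, ,
                                drop = FALSE]
  cl <- glucluster:::fit_learner(train[lab == down_id, 1:P],
                                 train[lab == down_id, (P + 1):72],
                                 "gradient_boosting", seed = 3L)
  gl <- fit_global(train, "gradient_boosting", h, seed = 3L)
  truth <- hold[, (P + 1):72]
  mae_cl <- compute_metrics(
    truth, glucluster:::predict_learner(cl, hold[, 1:P]))$mae
  mae_gl <- compute_metrics(truth, predict_global(gl, hold[, 1:P]))$mae
  expect_lt(mae_cl, mae_gl)
})

test_that("learner predictions on medoid prefixes stay in a plausible range", {
  coh <- generate_cohort(cohort_config(50, gap_rate_single = 0,
                                       gap_rate_long = 0, seed = 15L))
  cm <- fit_cluster_model(coh$values, k_range = c(2L, 5L))
  rt <- fit_cluster_routed(coh$values, cm, "random_forest", 3L, seed = 1L)
  p <- predict_cluster_routed(rt, cm$medoid_series[, 1:69, drop = FALSE])
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 2.2 * 0.8 & p <= 22.2 * 1.2))
})
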