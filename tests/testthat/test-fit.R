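test_that("dataset validation catches malformed observations", {
  df <- data.frame(individual_id = "a", class = "Baseline", time_min = 1,
                   gc_value = 2)
  d <- observed_dataset(df)
  expect_equal(d$class, "baseline")
  expect_error(observed_dataset(df[, -4]), "missing required column")
  df2 <- rbind(df, data.frame(individual_id = "a", class = "stress",
                              time_min = 25, gc_value = -1))
  expect_error(observed_dataset(df2), "row\\(s\\): 2")
  df3 <- df
  df3$class <- "lunch"
  expect_error(observed_dataset(df3), "unknown sampling class")
})

test_that("the likelihood equals a brute-force Gaussian computation", {
  # independent oracle: simulate, interpolate, sum log-densities
  p <- default_p
  data <- observed_dataset(data.frame(
    individual_id = "x", class = c("baseline", "stress_induced", "post_dex"),
    time_min = c(1, 25, 70), gc_value = c(3, 25, 8)))
  sigma <- 1.7
  # fully independent route: separate dense simulation, interpolation and
  # Gaussian density sum (agreement limited by the integrator tolerance)
  traj <- simulate_response(p, events = default_events(), horizon = 101)
  pred_indep <- stats::approx(traj$time, traj$O, xout = data$time_min)$y
  oracle <- -sum(stats::dnorm(data$gc_value, mean = pred_indep, sd = sigma,
                              log = TRUE))
  expect_equal(neg_log_likelihood(p, data, sigma = sigma), oracle,
               tolerance = 1e-6)
  # likelihood arithmetic itself, on shared predictions, to near machine
  # precision: fixed-sigma density sum and the profiled-sigma closed form
  pred <- predict_gc(p, data$time_min)
  expect_equal(neg_log_likelihood(p, data, sigma = sigma),
               -sum(stats::dnorm(data$gc_value, mean = pred, sd = sigma,
                                 log = TRUE)), tolerance = 1e-12)
  rss <- sum((data$gc_value - pred)^2)
  n <- 3
  expect_equal(neg_log_likelihood(p, data),
               n / 2 * (log(2 * pi * rss / n) + 1), tolerance = 1e-12)
})

test_that("likelihood arithmetic: duplication doubles, permutation is neutral", {
  p <- default_p
  data <- observed_dataset(data.frame(
    individual_id = rep("x", 4),
    class = c("baseline", "stress_induced", "post_dex", "post_acth"),
    time_min = c(1, 25, 70, 100), gc_value = c(3, 25, 8, 30)))
  nll1 <- neg_log_likelihood(p, data)
  nll2 <- neg_log_likelihood(p, rbind(data, data))
  expect_equal(nll2, 2 * nll1, tolerance = 1e-10)
  shuffled <- data[c(3, 1, 4, 2), ]
  expect_equal(neg_log_likelihood(p, shuffled), nll1, tolerance = 1e-12)
})

test_that("the truth minimises the likelihood for noise-free data", {
  p <- default_p
  times <- c(1, 25, 70, 100)
  pred <- predict_gc(p, times)
  data <- observed_dataset(data.frame(
    individual_id = "x",
    class = c("baseline", "stress_induced", "post_dex", "post_acth"),
    time_min = times, gc_value = pred))
  nll_truth <- neg_log_likelihood(p, data, sigma = 1)
  expect_true(is.finite(neg_log_likelihood(p, data)))  # profiled 0-RSS limit
  for (fac in c(0.8, 1.25)) {
    for (f in c("G_tot", "k_O", "b_O", "b")) {
      perturbed <- do.call(update_params, stats::setNames(
        list(p, p[[f]] * fac), c("p", f)))
      expect_gt(neg_log_likelihood(perturbed, data, sigma = 1), nll_truth)
    }
  }
})

test_that("fitting noise-free data from the truth stays at the truth", {
  p <- default_p
  pop <- generate_population(population_spec(n = 4, gr_cv = 0,
                                             noise_cv = 0, seed = 3))
  fit <- fit_hpa(pop$observations,
                 parameter_mask(free = c("G_tot", "k_O", "b_O"), start = p),
                 sigma = 1)
  expect_true(fit$convergence)
  est <- coef(fit)
  expect_equal(est[["G_tot"]], p$G_tot, tolerance = 0.02)
  expect_equal(est[["k_O"]], p$k_O, tolerance = 0.02)
  expect_equal(est[["b_O"]], p$b_O, tolerance = 0.02)
  expect_lt(sum((fit$fitted$gc_value - fit$fitted$fitted_gc)^2), 1e-4)
})

test_that("a mask must free at least one known parameter", {
  expect_error(parameter_mask(free = character(0)), "at least one")
  expect_error(parameter_mask(free = "G_total"), "unknown parameter")
})

test_that("visual starting values respond to the data as designed", {
  pop <- generate_population(population_spec(n = 8, seed = 11))
  st <- visual_start(pop$observations)
  expect_s3_class(st, "hpa_params")
  # no stress contrast, no stressor
  flat <- pop$observations
  flat$gc_value <- 5
  st0 <- visual_start(flat)
  expect_equal(st0$b, 0, tolerance = 1e-8)
  # scale equivariance: c-fold GC values give c-fold production start,
  # unchanged stressor and clearance starts
  scaled <- pop$observations
  scaled$gc_value <- scaled$gc_value * 3
  st3 <- visual_start(scaled)
  expect_equal(st3$k_O, 3 * st$k_O, tolerance = 1e-8)
  expect_equal(st3$b, st$b, tolerance = 1e-8)
  expect_equal(st3$b_O, st$b_O, tolerance = 1e-8)
  # missing classes fall back with a warning
  base_only <- pop$observations[pop$observations$class == "baseline", ]
  expect_warning(stf <- visual_start(base_only), "missing")
  expect_equal(stf$b, hpa_params()$b)
})

test_that("multi-start fitting is reproducible for a fixed seed", {
  pop <- generate_population(population_spec(n = 3, gr_cv = 0.3,
                                             noise_cv = 0.1, seed = 5))
  mask <- parameter_mask(free = c("G_tot", "k_O"))
  f1 <- fit_hpa(pop$observations, mask, n_starts = 2, seed = 9, maxit = 300)
  f2 <- fit_hpa(pop$observations, mask, n_starts = 2, seed = 9, maxit = 300)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$starts$nll, f2$starts$nll)
})

test_that("per-individual GR fits track among-individual GR variation", {
  pop <- generate_population(population_spec(n = 6, gr_cv = 0.5,
                                             noise_cv = 0.05, seed = 21))
  res <- fit_gr_per_individual(pop$observations, log_scale = TRUE,
                               maxit = 400)
  expect_equal(nrow(res), 6)
  expect_true(all(res$converged))
  merged <- merge(res, pop$truth, by = "individual_id")
  expect_gt(stats::cor(merged$G_tot.x, merged$G_tot.y,
                       method = "spearman"), 0.5)
})
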