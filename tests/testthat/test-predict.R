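test_that("GC decreases with GR abundance at every sampling class", {
  sw <- sweep_gr(default_p, default_gr_grid(default_p, n_gr = 5))
  for (cls in c("baseline", "stress_induced", "post_dex", "post_acth")) {
    expect_true(all(diff(sw[[cls]]) < 0), info = cls)
  }
  # a degenerate grid of one repeated value gives identical rows
  same <- sweep_gr(default_p, rep(default_p$G_tot, 3))
  expect_equal(same[1, -1], same[2, -1], ignore_attr = TRUE)
  expect_equal(same[1, -1], same[3, -1], ignore_attr = TRUE)
  expect_error(sweep_gr(default_p, c(1, 2)), "at least 3")
  expect_error(sweep_gr(default_p, c(-1, 1, 2)), "positive")
})

test_that("stressor sweeps show saturation of the physiological response", {
  gr3 <- default_p$G_tot * c(1 / 3, 1, 3)
  sw <- sweep_stressor(default_p, gr_grid = gr3,
                       b_grid = default_b_grid(default_p, n_b = 4))
  # no stressor, no excursion
  sw0 <- sweep_stressor(default_p, gr_grid = gr3, b_grid = c(1e-9, 1e-8))
  expect_true(all(sw0$range_O < 1e-4))
  expect_true(all(sw0$range_O_G < 1e-4))
  for (g in gr3) {
    sub <- sw[sw$G_tot == g, ]
    sub <- sub[order(sub$b), ]
    # response range grows with stressor intensity...
    expect_true(all(diff(sub$range_O_G) > 0))
    # ...but is bounded by the receptor pool
    expect_true(all(sub$range_O_G < g))
  }
  # higher GR, stronger physiological response at fixed stressor
  for (b in unique(sw$b)) {
    sub <- sw[sw$b == b, ]
    sub <- sub[order(sub$G_tot), ]
    expect_true(all(diff(sub$peak_O_G) > 0))
  }
})

test_that("the saturation diagnostic behaves as a sensitivity measure", {
  # unsaturated limit: response ranges scale linearly with b, so the
  # high/mid ratio equals the intensity ratio
  tiny <- sweep_stressor(default_p, gr_grid = c(2, 3, 4),
                         b_grid = c(0.05, 0.1, 0.2))
  si <- sensitivity_index(tiny)
  expect_equal(si$saturation_ratio, rep(0.2 / 0.1, 3), tolerance = 0.05)
  # a single intensity is not a sweep
  one_b <- sweep_stressor(default_p, gr_grid = c(2, 3, 4), b_grid = 600)
  expect_error(sensitivity_index(one_b), "at least 2")
  # on the default grids, low-GR individuals saturate earlier: their
  # high/mid ratio sits closer to 1
  sw <- sweep_stressor(default_p,
                       gr_grid = default_p$G_tot * c(1 / sqrt(10), sqrt(10)),
                       b_grid = default_b_grid(default_p))
  si2 <- sensitivity_index(sw)
  expect_lt(si2$saturation_ratio[1], si2$saturation_ratio[2])
})

test_that("among-individual GR variation flips the GC/response association", {
  assoc <- association_analysis(default_p, gr_cv = 0.5, n = 40, seed = 2,
                                horizon = 150)
  r30 <- assoc$correlations$spearman_peak[assoc$correlations$time_min == 30]
  expect_lt(r30, 0)
  # within one individual the same association is positive
  within <- stressor_association(default_p,
                                 b_grid = default_b_grid(default_p, n_b = 8),
                                 time_min = 30, horizon = 150)
  expect_gt(within$spearman, 0)
})

test_that("degenerate GR distributions are reported, not an error", {
  assoc <- association_analysis(default_p, gr_cv = 0, n = 10, seed = 1,
                                horizon = 120)
  expect_true(assoc$degenerate)
  expect_true(all(is.na(assoc$correlations$spearman_peak)))
  expect_output(print(assoc), "degenerate")
  expect_error(association_analysis(default_p, n = 5), ">= 10")
})
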