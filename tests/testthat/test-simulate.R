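test_that("baseline steady state satisfies its defining equations", {
  p <- default_p
  s0 <- baseline_state(p)
  expect_lt(sqrt(sum(hpa_rhs(0, s0, update_params(p, b = 0))^2)), 1e-8)
  # receptor pools add up
  expect_equal(s0[["G"]] + s0[["O_G"]], p$G_tot)
  expect_equal(s0[["M"]] + s0[["O_M"]], p$M_tot)
  # no input at all: everything drains to zero, receptors free
  z <- baseline_state(hpa_params(B = 0))
  expect_equal(unname(z[c("C", "A", "O", "O_G", "O_M", "D", "D_G")]),
               rep(0, 7))
  expect_equal(z[["G"]], hpa_params()$G_tot)
})

test_that("baseline state matches the closed-form linear chain without binding", {
  # k_fb = 0 and negligible binding: C* = B/b_C, A* = k_A C*/b_A,
  # O* = k_O A*/b_O
  p <- suppressWarnings(hpa_params(B = 2, k_fb = 0, k_G = 1e-10, k_mG = 1,
                                   k_M = 1e-10, k_mM = 1))
  s0 <- suppressWarnings(baseline_state(p))
  C_star <- p$B / p$b_C
  A_star <- p$k_A * C_star / p$b_A
  O_star <- p$k_O * A_star / p$b_O
  expect_equal(s0[["C"]], C_star, tolerance = 1e-6)
  expect_equal(s0[["A"]], A_star, tolerance = 1e-6)
  expect_equal(s0[["O"]], O_star, tolerance = 1e-6)
})

test_that("an unstressed simulation stays at the steady state", {
  p <- update_params(default_p, b = 0)
  traj <- simulate_response(p, horizon = 120,
                            output_grid = seq(0, 120, by = 1))
  for (v in c("C", "A", "O", "O_G", "O_M", "G", "M")) {
    expect_equal(traj[[v]], rep(traj[[v]][1], nrow(traj)),
                 tolerance = 1e-6)
  }
})

test_that("a stressor produces a rise-and-fall GC excursion", {
  traj <- stress_traj
  expect_gt(max(traj$O), traj$O[1] * 5)
  t_pk <- traj$time[which.max(traj$O)]
  expect_gt(t_pk, 5)
  expect_lt(t_pk, 60)
  # decline after the peak, approaching baseline again at long times
  late <- simulate_response(default_p, events = NULL, horizon = 600,
                            output_grid = c(0, 600))
  expect_equal(late$O[2], late$O[1], tolerance = 0.05)
})

test_that("adaptive and fixed-step integrations agree", {
  # coarse-dt cross-check (the fine-dt check lives with the acceptance runs)
  grid <- seq(0, 120, by = 1)
  a <- simulate_response(default_p, events = default_events(), horizon = 120,
                         output_grid = grid)
  b <- simulate_response(default_p, events = default_events(), horizon = 120,
                         output_grid = grid, method = "rk4", dt = 0.01)
  expect_lt(max(abs(a$O - b$O)) / max(a$O), 1e-4)
})

test_that("injection events jump the target compartment by the dose", {
  ev <- injection_events(time = c(30, 80), target = c("DEX", "ACTH"),
                         amount = c(150, 2500))
  traj <- simulate_response(default_p, events = ev, horizon = 120)
  i30 <- which(traj$time == 30)
  before <- traj[i30 - 1, ]
  at <- traj[i30, ]
  # D jumps by the dose (it was 0), other components continuous
  expect_equal(at$D, 150, tolerance = 1e-4)
  for (v in c("C", "A", "O", "O_G", "O_M", "G", "M")) {
    expect_equal(at[[v]], before[[v]], tolerance = 2e-2 * max(1, before[[v]]))
  }
  i80 <- which(traj$time == 80)
  expect_equal(traj$A[i80] - traj$A[i80 - 1], 2500, tolerance = 1)
  # the ACTH bolus produces a second GC peak after minute 80
  post <- traj[traj$time > 80, ]
  expect_gt(max(post$O), traj$O[i80])
  j <- which.max(post$O)
  expect_gt(j, 1)                       # interior local maximum
  expect_lt(j, nrow(post))
  expect_error(simulate_response(default_p, events = injection_events(
    time = 500, target = "ACTH", amount = 1)), "horizon")
  expect_error(injection_events(10, "ACTH", -5), ">= 0")
  expect_error(injection_events(10, "cortisol", 5), "target")
})

test_that("receptor conservation holds along stored trajectories", {
  expect_lt(max(conservation_error(default_traj)), 1e-6)
  expect_lt(max(conservation_error(stress_traj)), 1e-6)
})

test_that("measure interpolates free GC at labelled times", {
  m <- measure(default_traj, sampling_scheme())
  expect_named(m, c("baseline", "stress_induced", "post_dex", "post_acth"))
  # exact grid point: interpolation is the stored value
  expect_equal(m[["post_acth"]], default_traj$O[default_traj$time == 100])
  # mid-interval value lies between its neighbours
  coarse <- simulate_response(default_p, horizon = 10,
                              output_grid = seq(0, 10, by = 2))
  mm <- measure(coarse, c(probe = 3))
  expect_true(mm >= min(coarse$O[2:3]) && mm <= max(coarse$O[2:3]))
  # constant trajectory: every label reads the same value
  flat <- simulate_response(update_params(default_p, b = 0), horizon = 120)
  expect_equal(diff(range(measure(flat))), 0, tolerance = 1e-6)
  expect_error(measure(default_traj, c(late = 999)), "outside")
})

test_that("response summaries capture peak, range and exposure", {
  s <- response_summary(stress_traj)
  expect_equal(s$peak_O, max(stress_traj$O))
  expect_equal(s$t_peak_O, stress_traj$time[which.max(stress_traj$O)])
  expect_gt(s$range_O_G, 0)
  expect_gt(s$auc_O, 0)
  flat <- simulate_response(update_params(default_p, b = 0), horizon = 60)
  sf <- response_summary(flat)
  expect_equal(sf$range_O, 0, tolerance = 1e-6)
  expect_equal(sf$range_O_G, 0, tolerance = 1e-6)
  # stronger stressor, wider GC range
  expect_gt(s$range_O, sf$range_O)
  # the physiological response (GC-GR complex) peaks after plasma GC:
  # genomic receptor binding lags the hormone
  expect_gt(s$t_peak_O_G, s$t_peak_O)
})

test_that("lower GR abundance delays the GC peak", {
  lo <- simulate_response(update_params(default_p, G_tot = 1), events = NULL,
                          horizon = 180)
  hi <- simulate_response(update_params(default_p, G_tot = 9), events = NULL,
                          horizon = 180)
  t_lo <- lo$time[which.max(lo$O)]
  t_hi <- hi$time[which.max(hi$O)]
  expect_gte(t_lo, t_hi)
})
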