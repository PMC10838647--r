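# shared fixtures: computed once per test run, reused across files
default_p <- hpa_params()

# default-protocol trajectory on the standard 0.1-min grid
default_traj <- simulate_response(default_p, events = default_events(),
                                  horizon = 180)

# stressor-only trajectory (no injections)
stress_traj <- simulate_response(default_p, events = NULL, horizon = 180)

# literal term-by-term transcription of the model equations (stimulus,
# cascade with occupancy feedback, mass-action binding, exogenous GR ligand,
# no-outflow-from-empty-pool clamp), kept independent of hpa_rhs
rhs_transcription <- function(t, s, p) {
  pt <- p$B + p$b * p$alpha * exp(-p$alpha * t)
  OG <- s[["O_G"]]; OM <- s[["O_M"]]; DG <- s[["D_G"]]
  d <- c(
    C   = pt - p$b_C * s[["C"]] - p$k_CG * (OG + DG) - p$k_CM * OM,
    A   = p$k_A * s[["C"]] - p$b_A * s[["A"]] - p$k_AG * (OG + DG) -
            p$k_AM * OM,
    O   = p$k_O * s[["A"]] - p$b_O * s[["O"]] + p$k_mM * OM + p$k_mG * OG -
            p$k_M * s[["O"]] * s[["M"]] - p$k_G * s[["O"]] * s[["G"]],
    O_G = p$k_G * s[["O"]] * s[["G"]] - p$k_mG * OG,
    O_M = p$k_M * s[["O"]] * s[["M"]] - p$k_mM * OM,
    G   = p$k_mG * OG - p$k_G * s[["O"]] * s[["G"]] +
            p$k_mG * DG - p$k_G * s[["D"]] * s[["G"]],
    M   = p$k_mM * OM - p$k_M * s[["O"]] * s[["M"]],
    D   = -p$k_G * s[["D"]] * s[["G"]] + p$k_mG * DG - p$b_O * s[["D"]],
    D_G = p$k_G * s[["D"]] * s[["G"]] - p$k_mG * DG)
  zero <- s <= 0 & d < 0
  d[zero] <- 0
  d
}

# random valid state/parameter draws for property-style loops
random_state <- function() {
  v <- stats::runif(9, 0, 10)
  hpa_state(C = v[1], A = v[2], O = v[3], O_G = v[4], O_M = v[5],
            G = v[6], M = v[7], D = v[8], D_G = v[9])
}

random_params <- function() {
  suppressWarnings(hpa_params(
    B = stats::runif(1, 0, 5), b = stats::runif(1, 0, 500),
    alpha = stats::runif(1, 0.01, 0.3),
    b_C = stats::runif(1, 0.05, 1), b_A = stats::runif(1, 0.05, 1),
    b_O = stats::runif(1, 0.01, 0.3),
    k_A = stats::runif(1, 0.1, 2), k_O = stats::runif(1, 0.005, 0.3),
    k_fb = stats::runif(1, 0, 0.3),
    k_G = stats::runif(1, 0.001, 0.5), k_mG = stats::runif(1, 0.001, 1),
    k_M = stats::runif(1, 0.001, 0.5), k_mM = stats::runif(1, 0.001, 1),
    G_tot = stats::runif(1, 0.5, 15), M_tot = stats::runif(1, 0.1, 5)))
}
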