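#' Stimulus driving the HPA axis
#'
#' The input to the hypothalamus is the sum of a constant baseline energetic
#' demand `B` and an acute stressor that decays exponentially with time:
#' `p(t) = B + b * alpha * exp(-alpha * t)`. The factor `alpha` normalises
#' the stressor pulse so that its time integral over `[0, Inf)` equals `b`:
#' the stressor-intensity parameter is the total extra demand imposed by the
#' stressor, and `1/alpha` is its persistence time scale.
#'
#' @param t time since stressor onset, minutes (scalar or vector, >= 0).
#' @param params an [hpa_params()] object supplying `B`, `b`, `alpha`.
#' @return The demand level `p(t)`, same length as `t`.
#' @examples
#' stimulus(0, hpa_params(B = 1, b = 10, alpha = 0.1)) # 1 + 10 * 0.1 = 2
#' @export
stimulus <- function(t, params) {
  if (any(!is.finite(t))) stop("'t' must be finite")
  if (any(t < 0)) stop("'t' must be >= 0")
  params$B + params$b * params$alpha * exp(-params$alpha * t)
}

#' Equilibrium receptor occupancy (saturation form)
#'
#' Closed-form concentration of ligand-receptor complex at chemical
#' equilibrium: `bound = R_tot * O / (O + K)`, where `K` is the Michaelis
#' constant (release/binding rate ratio; the ligand concentration at half
#' occupancy). This is the model's readout of GC-mediated physiological
#' response when applied to GR (`R_tot = G_tot`, `K = K_G`).
#'
#' @param O free ligand concentration (scalar or vector, >= 0).
#' @param R_tot total receptor abundance (>= 0).
#' @param K Michaelis constant (> 0).
#' @return Bound-complex concentration, in `[0, R_tot]`, increasing in `O`.
#' @examples
#' equilibrium_binding(O = 1, R_tot = 5, K = 1) # half-saturation: 2.5
#' @export
equilibrium_binding <- function(O, R_tot, K) {
  if (any(!is.finite(K)) || any(K <= 0)) stop("'K' must be finite and > 0")
  if (any(O < 0)) stop("'O' must be >= 0")
  if (any(R_tot < 0)) stop("'R_tot' must be >= 0")
  R_tot * O / (O + K)
}

#' Time derivative of the HPA-axis system state
#'
#' The full right-hand side of the model: the stimulus drives CRH synthesis,
#' CRH drives ACTH, ACTH drives GC; receptor-bound GC (and GR-bound
#' dexamethasone) feeds back negatively on CRH and ACTH production; GC
#' exchanges with free GR and MR by mass action; dexamethasone binds GR with
#' the same kinetics as GC and degrades at the GC clearance rate.
#'
#' Concentrations are physical, so a non-positive component with a negative
#' derivative has its derivative clamped to zero (this can only trigger for
#' `C` and `A`, whose feedback sinks do not vanish at zero; every mass-action
#' term already vanishes with its substrate). Receptor conservation is exact
#' by construction: the free-receptor derivatives are minus the sum of the
#' corresponding complex derivatives, so `G + O_G + D_G` and `M + O_M` are
#' invariants of the flow.
#'
#' @param t time in minutes (enters through the stimulus).
#' @param state named numeric vector with components
#'   `C, A, O, O_G, O_M, G, M, D, D_G` (see [hpa_state()]).
#' @param params an [hpa_params()] object.
#' @return Named numeric vector of the nine time derivatives.
#' @export
hpa_rhs <- function(t, state, params) {
  if (any(!is.finite(state))) stop("state components must be finite")
  s <- state
  p <- params

  # total feedback-competent GR occupancy: endogenous + exogenous ligand
  occ_G <- s[["O_G"]] + s[["D_G"]]
  occ_M <- s[["O_M"]]

  bind_G <- p$k_G * s[["O"]] * s[["G"]] - p$k_mG * s[["O_G"]]
  bind_M <- p$k_M * s[["O"]] * s[["M"]] - p$k_mM * s[["O_M"]]
  bind_D <- p$k_G * s[["D"]] * s[["G"]] - p$k_mG * s[["D_G"]]

  dC <- stimulus(t, p) - p$b_C * s[["C"]] - p$k_CG * occ_G - p$k_CM * occ_M
  dA <- p$k_A * s[["C"]] - p$b_A * s[["A"]] - p$k_AG * occ_G - p$k_AM * occ_M
  dO <- p$k_O * s[["A"]] - p$b_O * s[["O"]] - bind_G - bind_M
  dO_G <- bind_G
  dO_M <- bind_M
  dG <- -(bind_G + bind_D)
  dM <- -bind_M
  dD <- -bind_D - p$b_O * s[["D"]]
  dD_G <- bind_D

  d <- c(C = dC, A = dA, O = dO, O_G = dO_G, O_M = dO_M,
         G = dG, M = dM, D = dD, D_G = dD_G)

  # nonnegativity clamp: no outflow from an empty pool
  clamp <- state[state_names] <= 0 & d < 0
  d[clamp] <- 0
  d
}
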