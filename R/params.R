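#' Model parameters for the HPA-axis cascade
#'
#' Constructs and validates the full parameter set of the dynamic HPA-axis
#' model: the stimulus (baseline demand `B`, stressor intensity `b`, stressor
#' decay rate `alpha`), the hormone cascade (production and degradation rates
#' of CRH, ACTH and glucocorticoids), the negative-feedback strengths of the
#' GC-GR and GC-MR complexes at the hypothalamus and pituitary, and the
#' mass-action binding kinetics and total abundances of the two receptors.
#'
#' Time is measured in minutes throughout; hormone and receptor levels are in
#' arbitrary model concentration units (observed plasma GC is mapped onto the
#' model's free-GC variable one-to-one).
#'
#' The four feedback constants (`k_CG`, `k_CM`, `k_AG`, `k_AM`) default to a
#' single shared value `k_fb`, so that differences between the receptors come
#' only from their abundance and affinity; they can be overridden
#' individually.
#'
#' @param B baseline stimulus level (minimum energy demand), >= 0.
#' @param b stressor intensity; scales the acute input, >= 0.
#' @param alpha stressor decay rate (per minute), > 0.
#' @param b_C,b_A,b_O degradation rates of CRH, ACTH and GC (per minute).
#' @param k_A ACTH production rate per unit CRH (per minute).
#' @param k_O GC production rate per unit ACTH (per minute).
#' @param k_fb shared feedback strength applied to all four
#'   receptor-occupancy feedback terms (per minute per occupancy unit).
#' @param k_CG,k_CM,k_AG,k_AM individual feedback constants; default `k_fb`.
#' @param k_G,k_mG GR binding and release rate constants; the ratio
#'   `K_G = k_mG / k_G` is the GR Michaelis (half-saturation) constant.
#' @param k_M,k_mM MR binding and release rate constants; `K_M = k_mM / k_M`.
#' @param G_tot,M_tot total GR and MR abundance in HPA tissue.
#'
#' @return An object of class `hpa_params`: a named list of the rates above.
#' @details The defaults are a calibrated reference set producing a
#'   realistic songbird-like acute stress response: baseline plasma GC near
#'   2-3 units with GR mostly unbound (occupancy ~0.3), a ~11-fold GC peak
#'   near 20-25 min at which GR approaches saturation (occupancy ~0.8),
#'   recovery towards baseline within 2-3 h, and MR affinity much higher
#'   than GR affinity (`K_M = 0.2` vs `K_G = 6`) so that MR is saturated
#'   at baseline while GR is recruited during the acute response. Receptor
#'   binding is deliberately slow relative to hormone clearance (GR complex
#'   half-life of roughly two hours), so receptor-mediated feedback lags the
#'   plasma GC rise, as expected for genomic receptor action. A warning
#'   (not an error) is raised if `K_M >= K_G`, since MR is expected to be
#'   the high-affinity receptor.
#' @examples
#' p <- hpa_params()
#' p$G_tot
#' michaelis_constants(p)
#' @seealso [stimulus()], [hpa_rhs()], [simulate_response()]
#' @export
hpa_params <- function(B = 1.6, b = 600, alpha = 0.1,
                       b_C = 0.5, b_A = 0.25, b_O = 0.05,
                       k_A = 1.2, k_O = 0.01,
                       k_fb = 0.1,
                       k_CG = k_fb, k_CM = k_fb, k_AG = k_fb, k_AM = k_fb,
                       k_G = 0.001, k_mG = 0.006,
                       k_M = 0.02, k_mM = 0.004,
                       G_tot = 3, M_tot = 1) {
  p <- list(B = B, b = b, alpha = alpha,
            b_C = b_C, b_A = b_A, b_O = b_O,
            k_A = k_A, k_O = k_O,
            k_CG = k_CG, k_CM = k_CM, k_AG = k_AG, k_AM = k_AM,
            k_G = k_G, k_mG = k_mG, k_M = k_M, k_mM = k_mM,
            G_tot = G_tot, M_tot = M_tot)
  p <- lapply(p, as.numeric)
  class(p) <- "hpa_params"
  validate_params(p)
  p
}

#' Validate an `hpa_params` object
#'
#' Checks non-negativity of all rates, strict positivity where the model
#' requires it (`alpha`, `k_G`, `k_M`), finiteness, and that the derived
#' Michaelis constants are finite and positive. Warns if MR affinity is not
#' higher than GR affinity (`K_M >= K_G`).
#'
#' @param p an `hpa_params` object (or coercible named list).
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_params <- function(p) {
  fields <- c("B", "b", "alpha", "b_C", "b_A", "b_O", "k_A", "k_O",
              "k_CG", "k_CM", "k_AG", "k_AM",
              "k_G", "k_mG", "k_M", "k_mM", "G_tot", "M_tot")
  missing <- setdiff(fields, names(p))
  if (length(missing) > 0) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  }
  vals <- unlist(p[fields])
  if (!all(is.finite(vals))) {
    stop("non-finite parameter value(s): ",
         paste(fields[!is.finite(vals)], collapse = ", "))
  }
  if (any(vals < 0)) {
    stop("negative parameter value(s): ",
         paste(fields[vals < 0], collapse = ", "))
  }
  for (f in c("alpha", "k_G", "k_M")) {
    if (p[[f]] <= 0) stop("'", f, "' must be > 0")
  }
  K <- michaelis_constants(p)
  if (!all(is.finite(unlist(K))) || any(unlist(K) <= 0)) {
    stop("Michaelis constants K_G = k_mG/k_G and K_M = k_mM/k_M must be ",
         "finite and > 0 (check k_mG, k_mM)")
  }
  if (K$K_M >= K$K_G) {
    warning("K_M >= K_G: MR is expected to have higher GC affinity ",
            "(smaller Michaelis constant) than GR", call. = FALSE)
  }
  invisible(p)
}

#' Derived Michaelis constants of the two receptors
#'
#' @param p an `hpa_params` object.
#' @return A list with `K_G = k_mG / k_G` and `K_M = k_mM / k_M`, the ligand
#'   concentrations at half receptor occupancy.
#' @export
michaelis_constants <- function(p) {
  list(K_G = p$k_mG / p$k_G, K_M = p$k_mM / p$k_M)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced and the result
#' re-validated. Convenient for sweeps and fitting.
#'
#' @param p an `hpa_params` object.
#' @param ... named replacement values, e.g. `G_tot = 10`.
#' @return A new `hpa_params` object.
#' @examples
#' p2 <- update_params(hpa_params(), G_tot = 10, b = 5)
#' @export
update_params <- function(p, ...) {
  repl <- list(...)
  unknown <- setdiff(names(repl), names(p))
  if (length(unknown) > 0) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  }
  p[names(repl)] <- lapply(repl, as.numeric)
  class(p) <- "hpa_params"
  validate_params(p)
  p
}

#' @export
print.hpa_params <- function(x, ...) {
  K <- michaelis_constants(x)
  cat("HPA-axis model parameters\n")
  cat(sprintf("  stimulus:  B = %g, b = %g, alpha = %g /min\n",
              x$B, x$b, x$alpha))
  cat(sprintf("  cascade:   b_C = %g, k_A = %g, b_A = %g, k_O = %g, b_O = %g /min\n",
              x$b_C, x$k_A, x$b_A, x$k_O, x$b_O))
  cat(sprintf("  feedback:  k_CG = %g, k_CM = %g, k_AG = %g, k_AM = %g\n",
              x$k_CG, x$k_CM, x$k_AG, x$k_AM))
  cat(sprintf("  GR:        k_G = %g, k_mG = %g (K_G = %g), G_tot = %g\n",
              x$k_G, x$k_mG, K$K_G, x$G_tot))
  cat(sprintf("  MR:        k_M = %g, k_mM = %g (K_M = %g), M_tot = %g\n",
              x$k_M, x$k_mM, K$K_M, x$M_tot))
  invisible(x)
}

# State layout shared by the ODE right-hand side, the integrator and the
# trajectory container. Order is load-bearing: conservation checks and the
# event handler index into it.
state_names <- c("C", "A", "O", "O_G", "O_M", "G", "M", "D", "D_G")

#' Construct a system state vector
#'
#' The instantaneous state of the model: CRH (`C`), ACTH (`A`), free plasma
#' GC (`O`), the GC-GR and GC-MR complexes (`O_G`, `O_M`), free receptors
#' (`G`, `M`), and free and GR-bound exogenous ligand (dexamethasone;
#' `D`, `D_G`).
#'
#' @param C,A,O,O_G,O_M,G,M,D,D_G non-negative concentrations.
#' @return A named numeric vector of class `hpa_state`.
#' @export
hpa_state <- function(C = 0, A = 0, O = 0, O_G = 0, O_M = 0,
                      G = 0, M = 0, D = 0, D_G = 0) {
  s <- c(C = C, A = A, O = O, O_G = O_G, O_M = O_M,
         G = G, M = M, D = D, D_G = D_G)
  if (!all(is.finite(s))) stop("state components must be finite")
  if (any(s < 0)) stop("state components must be >= 0")
  class(s) <- c("hpa_state", "numeric")
  s
}
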