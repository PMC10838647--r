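#' Baseline (unstressed) steady state of the HPA axis
#'
#' Solves for the stationary state of the model under the baseline demand
#' only (`b = 0`, stimulus constantly `B`), with no exogenous ligand. At
#' stationarity the binding reactions are at chemical equilibrium, so the
#' nine-dimensional fixed-point problem reduces to a single scalar root in
#' free GC: given `O`, the complexes follow the equilibrium saturation form,
#' CRH and ACTH follow from their production/degradation balance, and the
#' remaining condition is `k_O * A(O) = b_O * O`. The root is bracketed and
#' solved by bisection/interpolation ([stats::uniroot()]), then verified
#' against the full right-hand side.
#'
#' @param params an [hpa_params()] object.
#' @param tol residual tolerance: the Euclidean norm of [hpa_rhs()] at the
#'   returned state must be below this (default `1e-8`).
#' @return An [hpa_state()] vector at which the (b = 0) right-hand side
#'   vanishes to within `tol`.
#' @examples
#' s0 <- baseline_state(hpa_params())
#' s0[["O"]] # baseline plasma GC
#' @export
baseline_state <- function(params, tol = 1e-8) {
  p0 <- update_params(params, b = 0)
  K <- michaelis_constants(p0)

  if (p0$B == 0) {
    # no input: the whole cascade drains to zero, receptors all free
    s <- hpa_state(G = p0$G_tot, M = p0$M_tot)
    return(s)
  }

  state_of <- function(O) {
    O_G <- equilibrium_binding(O, p0$G_tot, K$K_G)
    O_M <- equilibrium_binding(O, p0$M_tot, K$K_M)
    C <- max((p0$B - p0$k_CG * O_G - p0$k_CM * O_M) / p0$b_C, 0)
    A <- max((p0$k_A * C - p0$k_AG * O_G - p0$k_AM * O_M) / p0$b_A, 0)
    hpa_state(C = C, A = A, O = O, O_G = O_G, O_M = O_M,
              G = p0$G_tot - O_G, M = p0$M_tot - O_M)
  }
  # residual of the GC balance; strictly decreasing in O, positive at O = 0
  resid <- function(O) {
    s <- state_of(O)
    p0$k_O * s[["A"]] - p0$b_O * s[["O"]]
  }
  upper <- max(p0$k_O * p0$k_A * p0$B / (p0$b_A * p0$b_C * p0$b_O), 1)
  while (resid(upper) > 0) upper <- upper * 2
  root <- stats::uniroot(resid, c(0, upper), tol = .Machine$double.eps^0.75)
  s <- state_of(root$root)

  res <- hpa_rhs(0, s, p0)
  if (sqrt(sum(res^2)) >= tol) {
    stop(sprintf(
      "baseline steady state did not converge: residual RHS norm %.3e >= %.1e",
      sqrt(sum(res^2)), tol))
  }
  s
}

#' Timed hormone-challenge events
#'
#' An event applies an instantaneous bolus to one model compartment during a
#' simulation: `ACTH` adds to the ACTH pool `A` (the standard
#' maximum-production challenge) and `DEX` adds to the free dexamethasone
#' pool `D` (a synthetic GR agonist probing maximal negative feedback; it
#' occupies GR and suppresses the axis but is excluded from plasma GC
#' measurements).
#'
#' @param time event times, minutes (>= 0).
#' @param target character, each `"ACTH"` or `"DEX"`.
#' @param amount bolus sizes, concentration units (>= 0).
#' @return A data frame of class `hpa_events` with columns
#'   `time`, `target`, `amount`, sorted by time.
#' @examples
#' injection_events(time = c(30, 80), target = c("DEX", "ACTH"),
#'                  amount = c(3, 10))
#' @export
injection_events <- function(time = numeric(), target = character(),
                             amount = numeric()) {
  if (length(time) != length(target) || length(time) != length(amount)) {
    stop("'time', 'target' and 'amount' must have equal length")
  }
  target <- toupper(as.character(target))
  if (!all(target %in% c("ACTH", "DEX"))) {
    stop("event target must be 'ACTH' or 'DEX'")
  }
  if (any(time < 0)) stop("event times must be >= 0")
  if (any(amount < 0)) stop("event amounts must be >= 0")
  ev <- data.frame(time = as.numeric(time), target = target,
                   amount = as.numeric(amount))
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("hpa_events", "data.frame")
  ev
}

#' Default challenge protocol
#'
#' The standard field-endocrinology protocol emulated by the package: a
#' dexamethasone injection at minute 30 (immediately after the
#' stress-induced sample, so that the 60-80 min samples probe feedback
#' capacity) and an ACTH injection at minute 80 (so that the 100 min sample
#' probes maximal GC production). Doses are in model concentration units and
#' were calibrated once, together with the default parameters, so that the
#' four sampling classes order as baseline < post-DEX < stress-induced <
#' post-ACTH.
#'
#' @return An [injection_events()] data frame.
#' @export
default_events <- function() {
  injection_events(time = c(30, 80), target = c("DEX", "ACTH"),
                   amount = c(150, 2500))
}

#' Labelled sampling scheme
#'
#' Maps the standard sampling-class labels to sampling times (minutes). The
#' default places each class at the conventional field protocol time:
#' baseline within 3 min of disturbance, stress-induced at 25 min, post-DEX
#' at 70 min, post-ACTH at 100 min.
#'
#' @param baseline,stress_induced,post_dex,post_acth sampling times in
#'   minutes; set a class to `NULL` to drop it.
#' @return Named numeric vector of class `hpa_scheme`.
#' @export
sampling_scheme <- function(baseline = 1, stress_induced = 25,
                            post_dex = 70, post_acth = 100) {
  s <- c(baseline = baseline, stress_induced = stress_induced,
         post_dex = post_dex, post_acth = post_acth)
  s <- unlist(s[!vapply(s, is.null, logical(1))])
  if (anyDuplicated(names(s))) stop("sampling labels must be unique")
  if (any(s < 0)) stop("sampling times must be >= 0")
  class(s) <- c("hpa_scheme", "numeric")
  s
}

#' Sampling-class time windows
#'
#' The time windows within which each sampling class is drawn when
#' generating synthetic individuals: baseline 0-3 min, stress-induced
#' 20-30 min, post-DEX 60-80 min, post-ACTH at 100 min.
#'
#' @return A named list of `c(min, max)` windows, minutes.
#' @export
class_windows <- function() {
  list(baseline = c(0, 3), stress_induced = c(20, 30),
       post_dex = c(60, 80), post_acth = c(100, 100))
}

#' Simulate an acute stress response
#'
#' Integrates the model forward from the baseline steady state (so that
#' "baseline" samples measure a stationary value, not a transient), applying
#' injection events as instantaneous jumps in the target compartment with a
#' hard restart of the integrator at each event time.
#'
#' @param params an [hpa_params()] object.
#' @param events an [injection_events()] data frame, or `NULL` for none.
#' @param horizon simulation end time, minutes (> 0).
#' @param output_grid times at which the state is stored; default a regular
#'   0.1-min grid over `[0, horizon]`. Event times are always included.
#' @param init initial state; default [baseline_state()].
#' @param method integrator passed to [deSolve::ode()]: `"lsoda"` (adaptive,
#'   default) or `"rk4"` (fixed step, for cross-checking).
#' @param rtol,atol adaptive error control tolerances.
#' @param dt internal fixed step size when `method = "rk4"`.
#' @return An object of class `hpa_trajectory`: a data frame with column
#'   `time` and the nine state components, with the parameters and event log
#'   attached as attributes.
#' @examples
#' traj <- simulate_response(hpa_params(), events = default_events(),
#'                           horizon = 120, output_grid = seq(0, 120, 1))
#' max(traj$O) # peak plasma GC
#' @export
simulate_response <- function(params, events = NULL, horizon = 180,
                              output_grid = NULL, init = NULL,
                              method = c("lsoda", "rk4"),
                              rtol = 1e-8, atol = 1e-10, dt = 0.001) {
  method <- match.arg(method)
  validate_params(params)
  if (!is.finite(horizon) || horizon <= 0) stop("'horizon' must be > 0")
  if (is.null(output_grid)) output_grid <- seq(0, horizon, by = 0.1)
  output_grid <- sort(unique(as.numeric(output_grid)))
  if (min(output_grid) < 0 || max(output_grid) > horizon) {
    stop("'output_grid' must lie within [0, horizon]")
  }
  if (is.null(events)) {
    events <- injection_events()
  } else if (!inherits(events, "hpa_events")) {
    events <- injection_events(events$time, events$target, events$amount)
  }
  if (nrow(events) > 0 && max(events$time) > horizon) {
    stop("event times must lie within the simulation horizon")
  }
  if (is.null(init)) init <- baseline_state(params)
  y <- unclass(init)[state_names]

  rhs_desolve <- function(t, y, parms) list(hpa_rhs(t, y, parms))
  integrate_segment <- function(y0, times) {
    if (length(times) == 1) {
      return(matrix(c(times, y0), nrow = 1,
                    dimnames = list(NULL, c("time", state_names))))
    }
    if (method == "lsoda") {
      out <- deSolve::ode(y = y0, times = times, func = rhs_desolve,
                          parms = params, method = "lsoda",
                          rtol = rtol, atol = atol, maxsteps = 50000)
    } else {
      # fixed-step RK4 on an internal dt grid, interpolated onto `times`
      t0 <- times[1]
      t1 <- times[length(times)]
      fine <- seq(t0, t1, by = dt)
      if (fine[length(fine)] < t1) fine <- c(fine, t1)
      raw <- deSolve::ode(y = y0, times = fine, func = rhs_desolve,
                          parms = params, method = "rk4")
      out <- cbind(times, vapply(seq_along(y0), function(j) {
        stats::approx(raw[, 1], raw[, j + 1], xout = times,
                      ties = "ordered")$y
      }, numeric(length(times))))
    }
    istate <- attr(out, "istate")
    if ((!is.null(istate) && istate[1] < 0) || any(!is.finite(out[, -1]))) {
      stop(sprintf(
        "integration failed in segment [%g, %g] min (method %s); %d of %d output times computed",
        times[1], times[length(times)], method,
        sum(stats::complete.cases(out)), length(times)))
    }
    colnames(out) <- c("time", state_names)
    out
  }

  ev_times <- events$time
  breaks <- sort(unique(c(0, ev_times, horizon)))
  rows <- list()
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]
    t1 <- breaks[i + 1]
    # apply any bolus scheduled at the segment start
    for (j in which(ev_times == t0)) {
      slot <- if (events$target[j] == "ACTH") "A" else "D"
      y[slot] <- y[slot] + events$amount[j]
    }
    seg_times <- sort(unique(c(t0, output_grid[output_grid >= t0 &
                                                 output_grid <= t1], t1)))
    seg <- integrate_segment(y, seg_times)
    y <- seg[nrow(seg), -1]
    keep <- seg[, "time"] %in% output_grid
    # drop the event-time row from the *pre*-event segment so that the
    # stored value at an event time is the post-jump state
    if (t1 %in% ev_times) keep[nrow(seg)] <- FALSE
    rows[[i]] <- seg[keep, , drop = FALSE]
  }
  traj <- as.data.frame(do.call(rbind, rows))
  traj <- traj[!duplicated(traj$time), , drop = FALSE]
  rownames(traj) <- NULL
  # integration keeps states nonnegative up to solver error; snap tiny
  # negative round-off to zero
  num <- as.matrix(traj[state_names])
  num[num < 0 & num > -1e-9] <- 0
  traj[state_names] <- num
  structure(traj, params = params, events = events,
            class = c("hpa_trajectory", "data.frame"))
}

#' @export
print.hpa_trajectory <- function(x, ...) {
  cat(sprintf("HPA-axis trajectory: %d time points over [%g, %g] min\n",
              nrow(x), min(x$time), max(x$time)))
  ev <- attr(x, "events")
  if (!is.null(ev) && nrow(ev) > 0) {
    cat(sprintf("  events: %s\n",
                paste(sprintf("%s %+g @ %g min", ev$target, ev$amount,
                              ev$time), collapse = ", ")))
  }
  cat(sprintf("  plasma GC: baseline %.4g, peak %.4g at %g min\n",
              x$O[1], max(x$O), x$time[which.max(x$O)]))
  invisible(x)
}

#' Extract labelled plasma GC measurements from a trajectory
#'
#' Returns the free plasma glucocorticoid concentration (state component `O`
#' only; GR-bound hormone and dexamethasone are not seen by a plasma GC
#' assay) at each labelled sampling time, linearly interpolated between
#' stored grid points.
#'
#' @param traj an `hpa_trajectory`.
#' @param scheme a [sampling_scheme()] (or named numeric vector of times).
#' @return Named numeric vector of GC values, one per sampling label.
#' @export
measure <- function(traj, scheme = sampling_scheme()) {
  times <- as.numeric(scheme)
  if (any(times < min(traj$time)) || any(times > max(traj$time))) {
    stop("sampling times outside the trajectory time range")
  }
  out <- stats::approx(traj$time, traj$O, xout = times, ties = "ordered")$y
  names(out) <- names(scheme)
  out
}

#' Summarise a stress-response trajectory
#'
#' @param traj an `hpa_trajectory` with at least one stored time point.
#' @return A one-row data frame with: peak free GC (`peak_O`) and its time
#'   (`t_peak_O`), peak GC-GR complex (`peak_O_G`) and its time
#'   (`t_peak_O_G`), the ranges (max - min over the response) of free GC and
#'   of the GC-GR complex (`range_O`, `range_O_G`), and the time-integrated
#'   free GC (`auc_O`, trapezoidal; cumulative GC exposure).
#' @export
response_summary <- function(traj) {
  if (nrow(traj) < 1) stop("empty trajectory")
  auc <- if (nrow(traj) > 1) {
    sum(diff(traj$time) * (utils::head(traj$O, -1) + utils::tail(traj$O, -1)) / 2)
  } else 0
  data.frame(
    peak_O = max(traj$O),
    t_peak_O = traj$time[which.max(traj$O)],
    peak_O_G = max(traj$O_G),
    t_peak_O_G = traj$time[which.max(traj$O_G)],
    range_O = max(traj$O) - min(traj$O),
    range_O_G = max(traj$O_G) - min(traj$O_G),
    auc_O = auc
  )
}

#' Receptor-conservation error of a stored trajectory
#'
#' Maximum relative deviation of the two conserved totals,
#' `G + O_G + D_G = G_tot` and `M + O_M = M_tot`, over all stored points.
#'
#' @param traj an `hpa_trajectory`.
#' @return Named numeric vector `c(GR = ..., MR = ...)` of max relative errors.
#' @export
conservation_error <- function(traj) {
  p <- attr(traj, "params")
  if (is.null(p)) stop("trajectory has no attached parameters")
  gr <- abs(traj$G + traj$O_G + traj$D_G - p$G_tot) / p$G_tot
  mr <- abs(traj$M + traj$O_M - p$M_tot) / p$M_tot
  c(GR = max(gr), MR = max(mr))
}
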