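#' Default sweep grids
#'
#' The GR sweep covers a 10-fold range around the reference `G_tot`
#' (log-spaced, 9 points); the stressor sweep an 8-fold range around the
#' reference `b` (log-spaced, 6 points).
#'
#' @param params an [hpa_params()] supplying the reference values.
#' @param n_gr,n_b number of grid points.
#' @return For `default_gr_grid`/`default_b_grid`: a numeric vector.
#' @export
default_gr_grid <- function(params = hpa_params(), n_gr = 9) {
  exp(seq(log(params$G_tot / sqrt(10)), log(params$G_tot * sqrt(10)),
          length.out = n_gr))
}

#' @rdname default_gr_grid
#' @export
default_b_grid <- function(params = hpa_params(), n_b = 6) {
  exp(seq(log(params$b / sqrt(8)), log(params$b * sqrt(8)),
          length.out = n_b))
}

#' Sweep GR abundance against the four GC sampling classes
#'
#' Re-simulates the full sampling protocol at each value of total GR
#' abundance, holding every other parameter fixed, and records the labelled
#' GC measurements and response summaries. This is the in-silico version of
#' comparing individuals that differ only in GR abundance.
#'
#' @param base_params reference [hpa_params()].
#' @param gr_grid positive GR abundances (>= 3 values).
#' @param events injection protocol (default [default_events()]).
#' @param scheme a [sampling_scheme()].
#' @param horizon simulation horizon, minutes.
#' @return A data frame of class `hpa_sweep`: one row per grid point with
#'   `G_tot`, one column per sampling label, and the [response_summary()]
#'   columns.
#' @examples
#' \donttest{
#' sw <- sweep_gr(hpa_params(), default_gr_grid(n_gr = 5))
#' all(diff(sw$stress_induced) < 0) # GC decreases with GR at all classes
#' }
#' @export
sweep_gr <- function(base_params, gr_grid = default_gr_grid(base_params),
                     events = default_events(), scheme = sampling_scheme(),
                     horizon = 180) {
  if (length(gr_grid) < 3) stop("'gr_grid' must have at least 3 points")
  if (any(gr_grid <= 0)) stop("'gr_grid' must be positive")
  rows <- lapply(gr_grid, function(g) {
    traj <- simulate_response(update_params(base_params, G_tot = g),
                              events = events, horizon = horizon)
    cbind(data.frame(G_tot = g), as.data.frame(t(measure(traj, scheme))),
          response_summary(traj))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hpa_sweep", "data.frame")
  attr(out, "swept") <- "G_tot"
  out
}

#' Sweep stressor intensity (and GR abundance) factorially
#'
#' Simulates every combination of GR abundance and stressor intensity `b`
#' (no injections: the pure acute-stressor response) and records the
#' response summaries, in particular the ranges (max - min) of plasma GC
#' and of the GC-GR complex — the model's readouts of GC exposure and of
#' physiological-response magnitude.
#'
#' @param base_params reference [hpa_params()].
#' @param gr_grid positive GR abundances.
#' @param b_grid positive stressor intensities.
#' @param horizon simulation horizon, minutes.
#' @param events optional injection protocol (default none).
#' @return A data frame of class `hpa_sweep`: one row per `(G_tot, b)` cell
#'   with the [response_summary()] columns.
#' @export
sweep_stressor <- function(base_params,
                           gr_grid = default_gr_grid(base_params),
                           b_grid = default_b_grid(base_params),
                           horizon = 180, events = NULL) {
  if (any(gr_grid <= 0) || any(b_grid <= 0)) stop("grids must be positive")
  cells <- expand.grid(G_tot = gr_grid, b = b_grid,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    p <- update_params(base_params, G_tot = cells$G_tot[i], b = cells$b[i])
    traj <- simulate_response(p, events = events, horizon = horizon)
    cbind(cells[i, , drop = FALSE], response_summary(traj))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hpa_sweep", "data.frame")
  attr(out, "swept") <- c("G_tot", "b")
  out
}

#' Saturation diagnostic of the physiological response
#'
#' For each GR abundance in a stressor sweep, the ratio of the
#' physiological-response range (`range_O_G`) at the highest stressor
#' intensity to that at the middle intensity of the grid. A ratio near 1
#' means the response has stopped growing with stressor intensity — the
#' response is saturated and the individual cannot scale it up further
#' (low endocrine flexibility). In an unsaturated (linear) regime the
#' ratio approaches `b_high / b_mid`.
#'
#' @param sweep the result of [sweep_stressor()].
#' @return A data frame with one row per `G_tot`: `G_tot`, `b_mid`,
#'   `b_high`, and `saturation_ratio`.
#' @export
sensitivity_index <- function(sweep) {
  if (!all(c("G_tot", "b", "range_O_G") %in% names(sweep))) {
    stop("'sweep' must come from sweep_stressor()")
  }
  bs <- sort(unique(sweep$b))
  if (length(bs) < 2) stop("need at least 2 stressor intensities per G_tot")
  b_mid <- bs[ceiling(length(bs) / 2)]
  b_high <- bs[length(bs)]
  out <- lapply(sort(unique(sweep$G_tot)), function(g) {
    hi <- sweep$range_O_G[sweep$G_tot == g & sweep$b == b_high]
    mid <- sweep$range_O_G[sweep$G_tot == g & sweep$b == b_mid]
    data.frame(G_tot = g, b_mid = b_mid, b_high = b_high,
               saturation_ratio = hi / mid)
  })
  do.call(rbind, out)
}

#' Association between single-timepoint GC and physiological response
#'
#' Simulates a population of individuals that differ only in GR abundance
#' (drawn from a log-normal distribution, seeded), exposes each to the same
#' acute stressor, and tabulates plasma GC at fixed sampling times together
#' with the magnitude of the GC-mediated physiological response (peak
#' GC-GR complex). Rank (Spearman) and Pearson correlations between the
#' response and GC at each sampling time quantify how well a
#' single-timepoint GC sample predicts the physiological response across
#' individuals.
#'
#' With among-individual variation in GR, these correlations can be
#' negative even though within any individual the GC-to-response mapping
#' is strictly increasing — GR abundance raises the response while
#' lowering plasma GC.
#'
#' @param base_params reference [hpa_params()].
#' @param gr_median,gr_cv median and coefficient of variation of the
#'   log-normal GR distribution (`gr_cv = 0` gives identical individuals;
#'   correlations are then reported as `NA` with a note, not an error).
#' @param b stressor intensity shared by all individuals.
#' @param sampling_times GC sampling times, minutes (default 0, 30, 120:
#'   baseline, stress-induced, recovery).
#' @param n number of simulated individuals (>= 10).
#' @param seed integer seed for the GR draw.
#' @param horizon simulation horizon, minutes.
#' @return An object of class `hpa_association`: list with `individuals`
#'   (per-individual `G_tot`, GC at each time, `peak_O_G`, `range_O_G`,
#'   `auc_O_G`) and `correlations` (per sampling time, Spearman and
#'   Pearson correlation of each response readout with GC).
#' @export
association_analysis <- function(base_params = hpa_params(),
                                 gr_median = base_params$G_tot,
                                 gr_cv = 0.5, b = base_params$b,
                                 sampling_times = c(0, 30, 120),
                                 n = 200, seed = 1, horizon = 180) {
  if (n < 10) stop("'n' must be >= 10")
  if (gr_median <= 0 || gr_cv < 0) stop("invalid GR distribution")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  sdlog <- sqrt(log(1 + gr_cv^2))
  gts <- stats::rlnorm(n, meanlog = log(gr_median), sdlog = sdlog)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())

  grid <- sort(unique(c(seq(0, horizon, by = 0.5), sampling_times)))
  rows <- lapply(gts, function(g) {
    p <- update_params(base_params, G_tot = g, b = b)
    traj <- simulate_response(p, events = NULL, horizon = horizon,
                              output_grid = grid)
    gc <- stats::approx(traj$time, traj$O, xout = sampling_times,
                        ties = "ordered")$y
    s <- response_summary(traj)
    out <- data.frame(G_tot = g, peak_O_G = s$peak_O_G,
                      range_O_G = s$range_O_G)
    out[paste0("gc_", sampling_times)] <- as.list(gc)
    out
  })
  ind <- do.call(rbind, rows)

  degenerate <- stats::sd(ind$G_tot) == 0
  cors <- do.call(rbind, lapply(sampling_times, function(tt) {
    gc <- ind[[paste0("gc_", tt)]]
    one <- function(y, method) {
      if (degenerate || stats::sd(gc) == 0 || stats::sd(y) == 0)
        return(NA_real_)
      stats::cor(gc, y, method = method)
    }
    data.frame(time_min = tt,
               spearman_peak = one(ind$peak_O_G, "spearman"),
               pearson_peak = one(ind$peak_O_G, "pearson"),
               spearman_range = one(ind$range_O_G, "spearman"))
  }))
  structure(list(individuals = ind, correlations = cors,
                 degenerate = degenerate, n = n, seed = seed, b = b),
            class = "hpa_association")
}

#' @export
print.hpa_association <- function(x, ...) {
  cat(sprintf(
    "Single-timepoint GC vs physiological response (n = %d individuals)\n",
    x$n))
  if (isTRUE(x$degenerate)) {
    cat("  degenerate GR distribution (no variation): correlations undefined\n")
  }
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' Within-individual GC/response association across stressor intensities
#'
#' For a single individual (fixed parameters), varies the stressor
#' intensity over a grid and correlates plasma GC at a fixed sampling time
#' with the physiological-response magnitude (peak GC-GR complex). Because
#' the occupancy saturation curve is monotone in GC, this within-individual
#' correlation is positive — the counterpart of the possibly negative
#' among-individual correlation from [association_analysis()].
#'
#' @param params an [hpa_params()] object (one individual).
#' @param b_grid stressor intensities.
#' @param time_min GC sampling time, minutes.
#' @param horizon simulation horizon.
#' @return A list with `table` (per-`b` GC and response readouts) and
#'   `spearman` (rank correlation between them).
#' @export
stressor_association <- function(params = hpa_params(),
                                 b_grid = default_b_grid(params, n_b = 12),
                                 time_min = 30, horizon = 180) {
  if (length(b_grid) < 3) stop("'b_grid' must have at least 3 values")
  grid <- sort(unique(c(seq(0, horizon, by = 0.5), time_min)))
  rows <- lapply(b_grid, function(b) {
    traj <- simulate_response(update_params(params, b = b), events = NULL,
                              horizon = horizon, output_grid = grid)
    data.frame(b = b,
               gc = stats::approx(traj$time, traj$O, xout = time_min,
                                  ties = "ordered")$y,
               peak_O_G = response_summary(traj)$peak_O_G)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       spearman = stats::cor(tab$gc, tab$peak_O_G, method = "spearman"))
}
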