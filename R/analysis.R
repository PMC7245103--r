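#' Sweep a model parameter and record steady-state composition
#'
#' For each grid value the parameter is substituted into the rate model, the
#' network's base constants are re-derived, an ensemble is run, and the
#' time-averaged abundances of the tracked species (by default the targets
#' {Mo36}, {Mo132}, {Mo154}) are recorded. Replicate seeds are derived from
#' `seed` so the whole sweep is reproducible.
#'
#' @param network An annotated `reaction_network` (topology and templates are
#'   reused across grid points; constants are re-assigned per point).
#' @param params Baseline [rate_params()].
#' @param parameter One of `"D"`, `"k_nano"`, `"template_factor"`,
#'   `"k_bi_base"`, `"k_d"`.
#' @param grid Strictly monotone, non-empty numeric grid.
#' @param init_counts,horizon,n_reps Passed to [run_ensemble()].
#' @param seed Integer; grid point i uses seed base `seed + (i-1) * n_reps`.
#' @param tracked Species ids to record; default all target species.
#' @param sample_grid,window Sampling grid and averaging window for the
#'   underlying ensembles.
#' @return An object of class `sweep_result` with `parameter`, `grid` and
#'   `summaries` (data.frame: `value` plus one column per tracked species).
#' @export
sweep_parameter <- function(network, params, parameter, grid,
                            init_counts, horizon, n_reps, seed,
                            tracked = NULL, sample_grid = NULL,
                            window = c(0.5, 1)) {
  allowed <- c("D", "k_nano", "template_factor", "k_bi_base", "k_d")
  if (!parameter %in% allowed)
    stop("parameter must be one of: ", paste(allowed, collapse = ", "))
  if (length(grid) == 0L) stop("sweep grid must be non-empty")
  if (length(grid) > 1L && is.unsorted(grid, strictly = TRUE) &&
      is.unsorted(rev(grid), strictly = TRUE))
    stop("sweep grid must be strictly monotone")
  if (is.null(tracked)) {
    tracked <- network$species$id[network$species$is_target]
    if (!length(tracked)) tracked <- network$species$id
  }
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    p_i <- do.call(update_params,
                   c(list(params), stats::setNames(list(grid[i]), parameter)))
    net_i <- assign_base_constants(network, p_i)
    ens <- run_ensemble(net_i, p_i, init_counts, horizon, n_reps,
                        seed_base = seed + (i - 1L) * n_reps,
                        grid = sample_grid, window = window)
    rows[[i]] <- c(value = grid[i], ens$time_averaged_abundance[tracked])
  }
  summaries <- as.data.frame(do.call(rbind, rows))
  names(summaries) <- c("value", tracked)
  structure(list(parameter = parameter, grid = grid, summaries = summaries,
                 tracked = tracked, n_reps = n_reps, seed = seed,
                 window = window),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>", x$parameter, "over", length(x$grid), "points,",
      x$n_reps, "replicates each\n")
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Locate a critical transition along a sweep
#'
#' Finds the midpoint of the steepest change of the (optionally smoothed)
#' abundance curve of `species` along the sweep grid — the point where the
#' steady-state {Mo154} abundance collapses as the dimerization ratio
#' crosses its critical value. A flat curve yields an explicit no-transition
#' result rather than a number.
#'
#' @param sweep A `sweep_result`.
#' @param species Tracked species id whose curve is analysed.
#' @param smooth Half-width (in grid points) of a moving-average smoother
#'   applied before differencing; 0 (default) disables smoothing.
#' @return An object of class `critical_point` with fields `critical_value`
#'   (`NA` when no transition), `no_transition`, `index`, `method`.
#' @export
detect_critical_point <- function(sweep, species, smooth = 0L) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (!species %in% names(sweep$summaries))
    stop("species '", species, "' was not tracked in this sweep")
  v <- sweep$summaries$value
  a <- sweep$summaries[[species]]
  if (smooth > 0L) {
    k <- 2L * as.integer(smooth) + 1L
    a <- stats::filter(a, rep(1 / k, k), sides = 2)
    keep <- !is.na(a)
    a <- as.numeric(a[keep]); v <- v[keep]
  }
  d <- diff(a)
  if (length(d) == 0L || max(abs(d)) == 0) {
    return(structure(list(critical_value = NA_real_, no_transition = TRUE,
                          index = NA_integer_, species = species,
                          method = "steepest-change midpoint",
                          smooth = smooth),
                     class = "critical_point"))
  }
  i <- which.max(abs(d))
  structure(list(critical_value = (v[i] + v[i + 1]) / 2, no_transition = FALSE,
                 index = i, species = species,
                 method = "steepest-change midpoint", smooth = smooth),
            class = "critical_point")
}

#' @export
print.critical_point <- function(x, ...) {
  if (x$no_transition) {
    cat("<critical_point> no transition detected for", x$species, "\n")
  } else {
    cat("<critical_point>", x$species, "transition at",
        signif(x$critical_value, 4), sprintf("(%s)\n", x$method))
  }
  invisible(x)
}

#' Fit two-sided scaling exponents around a critical point
#'
#' Least-squares fit of `log(abundance)` against `log(|D - D_c|)` separately
#' on each side of the transition, over a relative-distance window
#' (`|D - D_c| / D_c` within `windows`). Sides with fewer than three usable
#' points (positive abundance inside the window) are reported as
#' undetermined. The two exponents need not agree: the scaling differs on
#' the two sides of the transition.
#'
#' @param sweep A `sweep_result` over `D`.
#' @param critical_value The transition location (e.g. from
#'   [detect_critical_point()]).
#' @param species Species whose curve is fitted.
#' @param windows Relative-distance window per side, default `c(0.01, 0.25)`.
#' @return An object of class `critical_fit`: `critical_value`, `windows`,
#'   and per-side lists (`left`, `right`) with `exponent`, `se`, `n`,
#'   `r_squared` (`NA` exponent when undetermined).
#' @export
fit_scaling_exponents <- function(sweep, critical_value, species,
                                  windows = c(0.01, 0.25)) {
  stopifnot(inherits(sweep, "sweep_result"), is.finite(critical_value),
            length(windows) == 2L, windows[1] < windows[2])
  v <- sweep$summaries$value
  a <- sweep$summaries[[species]]
  if (is.null(a)) stop("species '", species, "' was not tracked in this sweep")
  fit_side <- function(keep_side) {
    rel <- abs(v - critical_value) / abs(critical_value)
    keep <- keep_side & rel >= windows[1] & rel <= windows[2] & a > 0 &
      v != critical_value
    if (sum(keep) < 3L)
      return(list(exponent = NA_real_, se = NA_real_, n = sum(keep),
                  r_squared = NA_real_, undetermined = TRUE))
    fit <- stats::lm(log(a[keep]) ~ log(abs(v[keep] - critical_value)))
    s <- summary(fit)
    list(exponent = unname(stats::coef(fit)[2]),
         se = s$coefficients[2, 2], n = sum(keep),
         r_squared = s$r.squared, undetermined = FALSE)
  }
  structure(list(critical_value = critical_value, species = species,
                 windows = windows,
                 left = fit_side(v < critical_value),
                 right = fit_side(v > critical_value)),
            class = "critical_fit")
}

#' @export
print.critical_fit <- function(x, ...) {
  fmt <- function(s, nm) {
    if (s$undetermined) cat(" ", nm, ": undetermined (", s$n, "points )\n")
    else cat(sprintf("  %s: exponent %.3f +/- %.3f (n=%d, R2=%.3f)\n",
                     nm, s$exponent, s$se, s$n, s$r_squared))
  }
  cat("<critical_fit> around", signif(x$critical_value, 4), "for", x$species,
      "- windows", paste(x$windows, collapse = "-"), "\n")
  fmt(x$left, "left"); fmt(x$right, "right")
  invisible(x)
}

#' Normalized-minimum coexistence metric
#'
#' Given two species' time-averaged abundances and their maxima over the
#' sweep, returns `min(a1/max1, a2/max2)`: 1 when both species sit at their
#' sweep maxima, 0 when either is absent. Applied along a dimerization-ratio
#' sweep it peaks in the narrow window where the {Mo132} ball and the
#' {Mo154} wheel coexist.
#'
#' @param abundances Numeric vector of length 2 (one value per species).
#' @param maxima Numeric vector of length 2: each species' maximum over the
#'   sweep.
#' @return A value in \[0, 1\].
#' @export
coexistence_metric <- function(abundances, maxima) {
  stopifnot(length(abundances) == 2L, length(maxima) == 2L)
  if (any(maxima <= 0) || any(abundances <= 0)) return(0)
  min(abundances / maxima)
}

#' Coexistence curve along a sweep
#'
#' Evaluates [coexistence_metric()] at every grid point of a sweep, using
#' each species' maximum over the whole sweep as its normalizer.
#'
#' @param sweep A `sweep_result` tracking both species.
#' @param species The two species ids, default the {Mo132} ball and {Mo154}
#'   wheel.
#' @return Data.frame with columns `value` and `coexistence`.
#' @export
coexistence_curve <- function(sweep, species = c("M132e", "M154c")) {
  stopifnot(inherits(sweep, "sweep_result"), length(species) == 2L)
  miss <- setdiff(species, names(sweep$summaries))
  if (length(miss)) stop("species not tracked: ", paste(miss, collapse = ", "))
  a1 <- sweep$summaries[[species[1]]]
  a2 <- sweep$summaries[[species[2]]]
  maxima <- c(max(a1), max(a2))
  coex <- vapply(seq_along(a1), function(i)
    coexistence_metric(c(a1[i], a2[i]), maxima), numeric(1))
  data.frame(value = sweep$summaries$value, coexistence = coex)
}

extract_series <- function(x, species = NULL) {
  if (inherits(x, "kinetic_trace")) return(list(t = x$times, y = x$signal))
  if (inherits(x, "trajectory")) {
    if (is.null(species)) stop("species must be given for a trajectory")
    return(list(t = x$grid, y = as.numeric(x$counts[species, ])))
  }
  if (inherits(x, "ensemble_result")) {
    if (is.null(species)) stop("species must be given for an ensemble")
    return(list(t = x$grid, y = as.numeric(x$mean[species, ])))
  }
  if (is.data.frame(x) && ncol(x) >= 2L) return(list(t = x[[1]], y = x[[2]]))
  stop("cannot extract a time series from object of class ",
       paste(class(x), collapse = "/"))
}

#' Kinetic lag (induction) time of a growth curve
#'
#' The classical tangent construction: the time axis intercept, relative to
#' the initial baseline, of the tangent at the point of maximum growth rate
#' (slopes from [finite_difference_rate()]). Zero for curves that grow
#' fastest from the start; positive for sigmoidal autocatalytic growth with
#' an induction period.
#'
#' @param x A `kinetic_trace`, `trajectory`, `ensemble_result`, or a
#'   two-column data.frame (time, signal).
#' @param species Species id, required for trajectory/ensemble input.
#' @param baseline_points Number of initial points averaged into the
#'   baseline (default 3).
#' @param smooth Moving-average half-width applied to the signal before
#'   differencing (0 disables).
#' @return Lag time (same units as the time axis).
#' @export
lag_time <- function(x, species = NULL, baseline_points = 3L, smooth = 0L) {
  s <- extract_series(x, species)
  t <- s$t; y <- s$y
  if (length(t) < 3L) stop("need at least 3 points")
  if (smooth > 0L) {
    k <- 2L * as.integer(smooth) + 1L
    ys <- stats::filter(y, rep(1 / k, k), sides = 2)
    keep <- !is.na(ys)
    y <- as.numeric(ys[keep]); t <- t[keep]
  }
  rate <- fd_rate(t, y)
  i <- which.max(rate)
  m <- rate[i]
  if (m <= 0) stop("trace is non-increasing: no growth phase to locate")
  y0 <- mean(y[seq_len(min(baseline_points, length(y)))])
  t[i] - (y[i] - y0) / m
}

#' Seeding experiment: lag and initial rate vs seed amount
#'
#' Re-runs matched ensembles (identical replicate seeds) with increasing
#' initial amounts of a preformed seed species added to the starting
#' mixture, mirroring seeding of the reaction with preformed {Mo36}. For
#' each seed amount the lag time and the maximum early growth rate of the
#' tracked species' mean trajectory are reported; seeding removes the
#' induction period and the initial rate saturates once the autocatalyst is
#' no longer limiting.
#'
#' @inheritParams run_ensemble
#' @param seed_grid Non-negative seed amounts (molecule counts); should
#'   include 0 for the unseeded reference.
#' @param seed_species Species added at t = 0, default the {Mo36} template.
#' @param tracked Species whose formation is followed, default the {Mo154}
#'   wheel.
#' @param rate_fraction Fraction of the horizon over which the initial rate
#'   is measured (default 0.5).
#' @return Data.frame with columns `seed_amount`, `lag`, `initial_rate`.
#' @export
seeding_experiment <- function(network, params, init_counts, horizon,
                               n_reps, seed_base, seed_grid,
                               seed_species = "M36c", tracked = "M154c",
                               grid = NULL, rate_fraction = 0.5) {
  stopifnot(all(seed_grid >= 0))
  out <- lapply(seed_grid, function(s_amt) {
    init2 <- init_counts
    init2[seed_species] <- (if (seed_species %in% names(init2))
      init2[[seed_species]] else 0) + s_amt
    ens <- run_ensemble(network, params, init2, horizon, n_reps, seed_base,
                        grid = grid)
    y <- as.numeric(ens$mean[tracked, ])
    t <- ens$grid
    lag <- tryCatch(lag_time(data.frame(t, y)), error = function(e) NA_real_)
    early <- t <= rate_fraction * horizon
    r_early <- fd_rate(t[early], y[early])
    data.frame(seed_amount = s_amt, lag = lag,
               initial_rate = max(r_early))
  })
  do.call(rbind, out)
}
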