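#' @useDynLib mobluesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Static part of the effective rate constant: everything except the
# template factor, which depends on the instantaneous template count.
static_rate_constants <- function(network, params) {
  validate_rate_params(params)
  rx <- network$reactions
  sp <- network$species
  if (!nrow(rx)) return(numeric(0))
  if (anyNA(rx$base_k))
    stop("network has unassigned base constants; run assign_base_constants()")
  nuc <- stats::setNames(sp$nuclearity, sp$id)
  fs <- stats::setNames(sp$free_sites, sp$id)
  k <- rx$base_k
  bi <- rx$kind == "synthesis" & !rx$plain_rate
  if (any(bi)) {
    m1 <- nuc[rx$r1[bi]] * params$mass_per_mo
    m2 <- nuc[rx$r2[bi]] * params$mass_per_mo
    mu <- m1 * m2 / (m1 + m2)
    c_mult <- 1 + params$k_nano / (1 + fs[rx$p1[bi]])
    k[bi] <- rx$base_k[bi] * sqrt(params$temperature / mu) / params$volume * c_mult
  }
  stats::setNames(as.numeric(k), rx$id)
}

#' Effective rate constants of every reaction
#'
#' Unimolecular reactions keep their base constant. Bimolecular syntheses
#' get the collision prefactor `sqrt(temperature / mu) / volume` with
#' reduced mass `mu = m_A m_B / (m_A + m_B)`, the completion-bias multiplier
#' `1 + k_nano / (1 + free_sites(product))`, and — when `state` is supplied
#' and the reaction's template is present (count >= 1) — the template
#' factor. Inhibitor binding/release reactions use their constants as given.
#'
#' @param network A `reaction_network` with assigned base constants.
#' @param params A [rate_params()] object.
#' @param state Optional named count vector; enables template acceleration.
#' @return Named numeric vector of effective constants, one per reaction.
#' @export
effective_rate_constant <- function(network, params, state = NULL) {
  k <- static_rate_constants(network, params)
  if (!is.null(state)) {
    rx <- network$reactions
    tmpl <- rx$template_id
    has_tmpl <- !is.na(tmpl)
    if (any(has_tmpl)) {
      tc <- ifelse(tmpl[has_tmpl] %in% names(state), state[tmpl[has_tmpl]], 0)
      f <- if (params$template_mode == "proportional")
        1 + (params$template_factor - 1) * tc
      else ifelse(tc >= 1, params$template_factor, 1)
      k[has_tmpl] <- k[has_tmpl] * f
    }
  }
  k
}

#' Mass-action propensities at a given state
#'
#' `k_eff * N_A` for unimolecular reactions, `k_eff * N_A * N_B` for
#' bimolecular reactions with distinct reactants, and
#' `k_eff * N_A (N_A - 1) / 2` for identical reactants.
#'
#' @inheritParams effective_rate_constant
#' @param state Named non-negative count vector (missing species count 0).
#' @return Named numeric vector of propensities, one per reaction.
#' @export
propensity <- function(network, params, state) {
  x <- full_state(network, state)
  k <- effective_rate_constant(network, params, x)
  rx <- network$reactions
  h <- numeric(nrow(rx))
  uni <- is.na(rx$r2)
  h[uni] <- x[rx$r1[uni]]
  same <- !uni & rx$r1 == rx$r2
  h[same] <- x[rx$r1[same]] * (x[rx$r1[same]] - 1) / 2
  diff2 <- !uni & rx$r1 != rx$r2
  h[diff2] <- x[rx$r1[diff2]] * x[rx$r2[diff2]]
  stats::setNames(as.numeric(k * h), rx$id)
}

full_state <- function(network, counts) {
  x <- stats::setNames(numeric(nrow(network$species)), network$species$id)
  if (length(counts)) {
    if (is.null(names(counts))) stop("counts must be named by species id")
    unknown <- setdiff(names(counts), names(x))
    if (length(unknown)) stop("unknown species in counts: ",
                              paste(unknown, collapse = ", "))
    if (any(counts < 0)) stop("counts must be non-negative")
    x[names(counts)] <- counts
  }
  x
}

#' Advance the state by one Gillespie step
#'
#' Reference (pure-R) implementation of the direct method: the waiting time
#' is exponential with rate equal to the propensity sum and the fired
#' reaction is chosen with probability proportional to its propensity. The
#' compiled engine used by [run_simulation()] implements the identical
#' update.
#'
#' @inheritParams propensity
#' @param horizon Time to advance to when no reaction can fire.
#' @return List with `state` (named counts), `time_increment`, and `fired`
#'   (reaction id, or `NA` if all propensities vanish).
#' @export
ssa_step <- function(network, params, state, horizon = Inf) {
  x <- full_state(network, state)
  a <- propensity(network, params, x)
  total <- sum(a)
  if (total <= 0)
    return(list(state = x, time_increment = horizon, fired = NA_character_))
  dt <- stats::rexp(1, rate = total)
  j <- sample.int(length(a), 1L, prob = a)
  rx <- network$reactions[j, ]
  x[rx$r1] <- x[rx$r1] - 1
  if (!is.na(rx$r2)) x[rx$r2] <- x[rx$r2] - 1
  x[rx$p1] <- x[rx$p1] + 1
  if (!is.na(rx$p2)) x[rx$p2] <- x[rx$p2] + 1
  if (any(x < 0)) stop("internal error: negative species count")
  list(state = x, time_increment = dt, fired = rx$id)
}

#' Simulate a reaction network with the Gillespie direct method
#'
#' Runs the exact stochastic simulation algorithm (compiled core) from an
#' initial count vector to a time horizon, recording species counts on a
#' sampling grid. Total Mo mass is asserted at every sampled time. Given the
#' same network, parameters and seed the trajectory is bit-identical.
#'
#' @param network A `reaction_network` with assigned base constants.
#' @param params A [rate_params()] object.
#' @param init_counts Named initial counts (species not named start at 0).
#' @param horizon Simulation end time (> 0).
#' @param grid Sampling times; default 201 equispaced points on
#'   `[0, horizon]`.
#' @param seed Optional integer seed (applied via `set.seed`).
#' @param check_mass Assert Mo-mass conservation at each sample (default
#'   `TRUE`).
#' @return An object of class `trajectory`: list with `grid`, `counts`
#'   (species x time matrix), `events`, `init`, `seed`.
#' @examples
#' net <- mob_network(12, rate_params(), targets = NULL, growth = "all_pairs",
#'                    template_rules = list())
#' tr <- run_simulation(net, rate_params(), c(M1 = 60), horizon = 2, seed = 1)
#' tr
#' @export
run_simulation <- function(network, params, init_counts, horizon,
                           grid = NULL, seed = NULL, check_mass = TRUE) {
  stopifnot(inherits(network, "reaction_network"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("horizon must be a positive number")
  if (is.null(grid)) grid <- seq(0, horizon, length.out = 201L)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  x0 <- full_state(network, init_counts)
  if (!is.null(seed)) set.seed(seed)
  rx <- network$reactions
  sp <- network$species
  keff <- static_rate_constants(network, params)
  to_idx <- function(ids) {
    i <- match(ids, sp$id)
    i[is.na(ids)] <- 0L
    i - 1L  # 0-based; NA slots become -1
  }
  res <- ssa_run_cpp(
    r1 = to_idx(rx$r1), r2 = to_idx(rx$r2),
    p1 = to_idx(rx$p1), p2 = to_idx(rx$p2),
    keff = as.numeric(keff),
    tmpl = to_idx(rx$template_id),
    tmpl_factor = params$template_factor,
    tmpl_proportional = identical(params$template_mode, "proportional"),
    nuclearity = sp$nuclearity,
    init = as.numeric(x0), grid = as.numeric(grid),
    check_mass = isTRUE(check_mass))
  counts <- res$counts
  dimnames(counts) <- list(sp$id, NULL)
  structure(list(grid = grid, counts = counts, events = res$events,
                 init = x0, seed = seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", nrow(x$counts), "species,", length(x$grid),
      "samples on [0,", max(x$grid), "],", x$events, "reaction events\n")
  invisible(x)
}

#' Time-averaged species abundances of a trajectory
#'
#' Averages sampled counts over a fraction of the trajectory, by default the
#' second half so the transient assembly phase is discarded.
#'
#' @param traj A `trajectory`.
#' @param species Species ids (default: all).
#' @param window Two fractions of the horizon delimiting the averaging
#'   window, default `c(0.5, 1)`.
#' @return Named numeric vector of time-averaged abundances.
#' @export
time_average <- function(traj, species = NULL, window = c(0.5, 1)) {
  stopifnot(inherits(traj, "trajectory"), length(window) == 2L,
            window[1] < window[2])
  tmax <- max(traj$grid)
  keep <- traj$grid >= window[1] * tmax & traj$grid <= window[2] * tmax
  m <- traj$counts[, keep, drop = FALSE]
  avg <- rowMeans(m)
  if (!is.null(species)) avg <- avg[species]
  avg
}

#' Run a replicate ensemble
#'
#' Repeats [run_simulation()] with replicate seeds `seed_base + r`
#' (r = 1..n), and aggregates the mean and variance trajectory plus the
#' replicate-averaged time-averaged abundances over the stated window.
#'
#' @inheritParams run_simulation
#' @param n_reps Number of replicates (>= 1).
#' @param seed_base Integer; replicate r uses seed `seed_base + r`.
#' @param window Averaging window passed to [time_average()].
#' @return An object of class `ensemble_result`: `n_replicates`, `seeds`,
#'   `grid`, `mean` and `var` count matrices, `time_averaged_abundance`,
#'   `window`, `mean_events`.
#' @export
run_ensemble <- function(network, params, init_counts, horizon,
                         n_reps, seed_base, grid = NULL,
                         window = c(0.5, 1), check_mass = FALSE) {
  stopifnot(n_reps >= 1)
  seeds <- seed_base + seq_len(n_reps)
  mean_m <- NULL; m2 <- NULL; tavg <- NULL; ev <- 0
  for (r in seq_len(n_reps)) {
    tr <- run_simulation(network, params, init_counts, horizon, grid = grid,
                         seed = seeds[r], check_mass = check_mass)
    ta <- time_average(tr, window = window)
    if (is.null(mean_m)) {
      mean_m <- tr$counts * 0
      m2 <- tr$counts * 0
      tavg <- ta * 0
      grid_out <- tr$grid
    }
    delta <- tr$counts - mean_m
    mean_m <- mean_m + delta / r
    m2 <- m2 + delta * (tr$counts - mean_m)
    tavg <- tavg + ta / n_reps
    ev <- ev + tr$events / n_reps
  }
  var_m <- if (n_reps > 1) m2 / (n_reps - 1) else m2 * 0
  structure(list(n_replicates = n_reps, seeds = seeds, grid = grid_out,
                 mean = mean_m, var = var_m,
                 time_averaged_abundance = tavg,
                 window = window, mean_events = ev),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result>", x$n_replicates, "replicates,",
      nrow(x$mean), "species; averaging window",
      paste(x$window, collapse = "-"), "of horizon\n")
  top <- sort(x$time_averaged_abundance, decreasing = TRUE)
  top <- top[top > 0][seq_len(min(5, sum(top > 0)))]
  if (length(top))
    cat("  top time-averaged:",
        paste(names(top), round(top, 2), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
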