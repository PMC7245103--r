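#' Construct a kinetic trace
#'
#' A (time, signal) series from a stopped-flow-style experiment: absorbance
#' or concentration sampled at strictly increasing times, with optional
#' wavelength and condition metadata (e.g. 350 nm for {Mo36}, 440 nm for
#' {PMo12}).
#'
#' @param times Strictly increasing numeric vector (seconds).
#' @param signal Finite numeric vector, same length.
#' @param wavelength Optional wavelength in nm.
#' @param conditions Optional named list (e.g. `list(Mo = 0.25, H = 0.047)`).
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, signal, wavelength = NA_real_,
                          conditions = list()) {
  if (length(times) != length(signal)) stop("times and signal lengths differ")
  if (length(times) >= 2L && is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (!all(is.finite(signal))) stop("signal must be finite")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 wavelength = wavelength, conditions = conditions),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat("<kinetic_trace>", length(x$times), "points on [",
      min(x$times), ",", max(x$times), "]")
  if (is.finite(x$wavelength)) cat(" @", x$wavelength, "nm")
  cat("\n")
  invisible(x)
}

# central differences in the interior, one-sided at the ends;
# shared by the rate-curve and lag-time operations
fd_rate <- function(t, y) {
  n <- length(t)
  if (n < 3L) stop("finite differences need at least 3 points")
  if (is.unsorted(t, strictly = TRUE)) stop("times must be strictly increasing")
  r <- numeric(n)
  r[1] <- (y[2] - y[1]) / (t[2] - t[1])
  r[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  r[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  r
}

#' Finite-difference rate curve of a kinetic trace
#'
#' d(signal)/dt computed directly from the data: central differences in the
#' interior, one-sided at the ends, on the same time grid. For sigmoidal
#' autocatalytic traces the rate curve is unimodal with its peak at the
#' inflection point.
#'
#' @param trace A `kinetic_trace` (or two-column data.frame) with at least
#'   3 points.
#' @return Data.frame with columns `time` and `rate`.
#' @export
finite_difference_rate <- function(trace) {
  s <- if (inherits(trace, "kinetic_trace")) list(t = trace$times, y = trace$signal)
       else list(t = trace[[1]], y = trace[[2]])
  data.frame(time = s$t, rate = fd_rate(s$t, s$y))
}

#' Beer-Lambert conversion between absorbance and concentration
#'
#' `concentration = absorbance / (epsilon * path)`; the two functions are
#' exact inverses. Molar absorptivities of the clusters are instrument- and
#' wavelength-specific and must be supplied by the user.
#'
#' @param absorbance Absorbance (AU).
#' @param epsilon Molar absorptivity (1/(M cm)), > 0.
#' @param path Optical path length (cm), > 0.
#' @return Concentration in M.
#' @export
beer_lambert_concentration <- function(absorbance, epsilon, path = 1) {
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (!is.finite(path) || path <= 0) stop("path must be > 0")
  absorbance / (epsilon * path)
}

#' @rdname beer_lambert_concentration
#' @param concentration Concentration (M).
#' @return Absorbance in AU.
#' @export
beer_lambert_absorbance <- function(concentration, epsilon, path = 1) {
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (!is.finite(path) || path <= 0) stop("path must be > 0")
  concentration * epsilon * path
}

#' Closed-form product concentration of the two-step autocatalytic scheme
#'
#' The minimal sigmoidal model: slow continuous nucleation `A -> B` (rate
#' constant `k1`, 1/s) plus autocatalytic growth `A + B -> 2B` (`k2`,
#' 1/(M s)). With `M = A0 + B0` conserved, the solution is logistic in
#' `k1/k2 + B`:
#' `B(t) = (M r - k1/k2) / (1 + r)` with
#' `r = ((k1/k2 + B0) / A0) * exp((k1 + k2 M) t)`.
#' The `k2 = 0` limit is the first-order approach
#' `B = M - A0 exp(-k1 t)`.
#'
#' @param t Time(s), seconds.
#' @param k1 Uncatalyzed rate constant (1/s), >= 0.
#' @param k2 Autocatalytic rate constant (1/(M s)), >= 0.
#' @param A0 Initial precursor concentration (M), >= 0, in product units
#'   (e.g. total Mo / 36 for {Mo36}).
#' @param B0 Initial product (seed) concentration (M), >= 0.
#' @return Product concentration B(t), same length as `t`.
#' @export
autocatalytic_solution <- function(t, k1, k2, A0, B0 = 0) {
  if (any(c(k1, k2, A0, B0) < 0)) stop("parameters must be non-negative")
  M <- A0 + B0
  if (A0 == 0) return(rep(M, length(t)))
  if (k2 * M <= k1 * 1e-12 || k2 == 0) return(M - A0 * exp(-k1 * t))
  a <- k1 / k2
  r <- ((a + B0) / A0) * exp((k1 + k2 * M) * t)
  ifelse(is.infinite(r), M, (M * r - a) / (1 + r))
}

#' Generate a synthetic sigmoidal kinetic trace
#'
#' Evaluates the two-step autocatalytic closed form
#' ([autocatalytic_solution()]) on a time grid and adds Gaussian noise —
#' the synthetic stand-in for a stopped-flow concentration trace, used for
#' parameter-recovery studies.
#'
#' @inheritParams autocatalytic_solution
#' @param times Sampling times (s).
#' @param noise_sd Standard deviation of additive Gaussian noise (M).
#' @param seed Optional integer seed; the trace is deterministic given it.
#' @return A `kinetic_trace` in concentration units, with the generating
#'   parameters recorded in `conditions`.
#' @export
simulate_sigmoid <- function(k1, k2, A0, B0 = 0, times, noise_sd = 0,
                             seed = NULL) {
  y <- autocatalytic_solution(times, k1, k2, A0, B0)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(times), sd = noise_sd)
  }
  kinetic_trace(times, y,
                conditions = list(k1 = k1, k2 = k2, A0 = A0, B0 = B0,
                                  noise_sd = noise_sd))
}

#' Fit the two-step autocatalytic model to a kinetic trace
#'
#' Weighted least squares (Levenberg-Marquardt, via minpack.lm) of the
#' closed-form solution against a concentration trace. Any of `k1`, `k2`,
#' `A0`, `B0` can be fixed — e.g. `B0` to a known seed concentration.
#' Non-convergence and degenerate (flat) traces return a failure object with
#' diagnostics rather than an error.
#'
#' @param trace A `kinetic_trace` in concentration units (convert absorbance
#'   first with [beer_lambert_concentration()]).
#' @param init Optional named list of starting values (`k1`, `k2`, `A0`,
#'   `B0`); sensible defaults are derived from the trace.
#' @param fixed Optional named list of parameters to hold fixed.
#' @param weights Optional per-point weights (default uniform).
#' @return An object of class `sigmoid_fit`: estimates `k1`, `k2`, `A0`,
#'   `B0`, `converged`, `covariance`, `residual_norm`, `message`.
#' @export
fit_sigmoid <- function(trace, init = NULL, fixed = list(), weights = NULL) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$times; y <- trace$signal
  fail <- function(msg) structure(
    list(k1 = NA_real_, k2 = NA_real_, A0 = NA_real_, B0 = NA_real_,
         converged = FALSE, covariance = NULL, residual_norm = NA_real_,
         message = msg, fixed = fixed),
    class = "sigmoid_fit")
  if (length(t) < 5L) return(fail("too few points"))
  span <- diff(range(y))
  if (span <= 0 || span < 1e-12 * max(abs(y), 1e-300))
    return(fail("flat trace: no kinetics to fit"))

  guess <- list(
    A0 = max(span, 1e-12),
    B0 = max(min(y), 1e-6 * span),
    k1 = 1 / diff(range(t)),
    k2 = max(fd_rate(t, y)) / max(span^2 / 4, 1e-300)
  )
  if (!is.null(init)) guess[names(init)] <- init
  guess[names(fixed)] <- fixed
  free <- setdiff(c("k1", "k2", "A0", "B0"), names(fixed))
  if (!length(free)) return(fail("all parameters fixed; nothing to fit"))

  # optimize on log scale to enforce positivity and even out magnitudes
  to_par <- function(g) log(pmax(unlist(g[free]), 1e-300))
  model <- function(par) {
    p <- guess
    p[free] <- as.list(exp(par))
    autocatalytic_solution(t, p$k1, p$k2, p$A0, p$B0)
  }
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  resid_fn <- function(par) sqrt(w) * (y - model(par))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = to_par(guess), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    return(fail(if (is.null(fit)) "optimizer error" else fit$message))
  }
  est <- guess
  est[free] <- as.list(exp(fit$par))
  # delta-method covariance on the natural scale from the log-scale fit
  cov_log <- tryCatch(
    {
      dof <- max(length(y) - length(free), 1L)
      s2 <- sum(fit$fvec^2) / dof
      s2 * solve(fit$hessian / 2)
    },
    error = function(e) NULL)
  cov_nat <- if (!is.null(cov_log)) {
    g <- diag(exp(fit$par), nrow = length(free))
    m <- g %*% cov_log %*% g
    dimnames(m) <- list(free, free)
    m
  } else NULL
  structure(list(k1 = est$k1, k2 = est$k2, A0 = est$A0, B0 = est$B0,
                 converged = TRUE, covariance = cov_nat,
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 message = fit$message, fixed = fixed, free = free),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<sigmoid_fit> FAILED:", x$message, "\n")
    return(invisible(x))
  }
  cat("<sigmoid_fit> k1 =", signif(x$k1, 4), "1/s, k2 =", signif(x$k2, 4),
      "1/(M s), A0 =", signif(x$A0, 4), "M, B0 =", signif(x$B0, 4), "M\n")
  cat("  residual norm:", signif(x$residual_norm, 4))
  if (length(x$fixed)) cat("  (fixed:", paste(names(x$fixed), collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

#' Read and write kinetic-trace CSV files
#'
#' Two-column CSV (`time_s`, `signal`), with wavelength and conditions in an
#' optional JSON sidecar (`<file>.json`).
#'
#' @param path CSV path.
#' @return `read_trace_csv`: a `kinetic_trace`.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop("malformed trace CSV '", path, "': ", conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("trace CSV '", path, "' must have >= 1 row and 2 columns (time_s, signal)")
  bad <- which(!is.finite(df[[1]]) | !is.finite(df[[2]]))
  if (length(bad))
    stop("trace CSV '", path, "': non-numeric value at data line ", bad[1])
  wl <- NA_real_; cond <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    wl <- meta$wavelength %||% NA_real_
    cond <- meta$conditions %||% list()
  }
  kinetic_trace(df[[1]], df[[2]], wavelength = wl, conditions = cond)
}

#' @rdname read_trace_csv
#' @param trace A `kinetic_trace`.
#' @param sidecar Write the metadata sidecar JSON (default `TRUE`).
#' @export
write_trace_csv <- function(trace, path, sidecar = TRUE) {
  stopifnot(inherits(trace, "kinetic_trace"))
  utils::write.csv(data.frame(time_s = trace$times, signal = trace$signal),
                   path, row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(list(wavelength = trace$wavelength,
                              conditions = trace$conditions),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
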