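#' Model rate parameters
#'
#' Collects every tunable constant of the coarse-grained assembly model in
#' model units (k_B = 1, Mo mass = 1, volume = 1 unless stated otherwise):
#'
#' * `k_uni_default` — rate constant for every unimolecular degradation
#'   (default 1.0).
#' * `k_bi_base` — base bimolecular synthesis constant before the collision
#'   prefactor `sqrt(temperature / mu) / volume` is applied.
#' * `D` — dimerization ratio: the corner-bonded {Mo2} channel forms `D`
#'   times faster than the edge-bonded (reduced) channel. Experimentally this
#'   axis corresponds to pH / reduction potential.
#' * `k_nano` — completion-bias strength: bimolecular rate constants are
#'   multiplied by `1 + k_nano / (1 + free_sites(product))`, so products with
#'   few free bonding sites (nearly complete structures) are preferred when
#'   `k_nano` is large and unbiased when `k_nano = 0`.
#' * `template_factor` — templated syntheses proceed this many times faster
#'   when at least one template molecule is present (default 10.0).
#' * `k_d` — degradation constant of the stable giant clusters ({Mo132},
#'   {Mo154}); must be much smaller than 1.
#' * `temperature`, `volume`, `mass_per_mo` — enter the bimolecular collision
#'   prefactor `sqrt(temperature / mu) / volume`, with reduced mass
#'   `mu = m_A m_B / (m_A + m_B)` and `m_X = nuclearity(X) * mass_per_mo`.
#' * `k_ladder_factor` — multiplier on the base constant of the
#'   small-cluster condensation steps (products of nuclearity 3..6): the
#'   {Mo6} hexad condenses slowly unless the step is template-accelerated,
#'   which makes the hexad supply the controllable currency of the
#'   autocatalytic set.
#' * `corner_link_factor` — optional multiplier on lineage-growth syntheses
#'   that incorporate a corner-bonded dimer (default 1: no asymmetry).
#' * `kd_applies_to_mo36` — whether {Mo36} also degrades at `k_d`
#'   (default `FALSE`: it degrades at `k_uni_default` like other
#'   intermediates).
#' * `template_mode` — `"presence"` (step function: factor applies when the
#'   template count is >= 1) or `"proportional"`
#'   (`1 + (template_factor - 1) * count`).
#'
#' @param k_uni_default,k_bi_base,D,k_nano,template_factor,k_d,temperature,volume,mass_per_mo
#'   Numeric scalars, see above.
#' @param kd_applies_to_mo36 Logical.
#' @param template_mode `"presence"` or `"proportional"`.
#' @return An object of class `rate_params` (a validated named list).
#' @examples
#' p <- rate_params(D = 2, k_nano = 8)
#' p$D
#' @export
rate_params <- function(k_uni_default = 1.0,
                        k_bi_base = 1.0,
                        D = 1.0,
                        k_nano = 1.0,
                        template_factor = 10.0,
                        k_d = 1e-6,
                        temperature = 1.0,
                        volume = 10.0,
                        mass_per_mo = 1.0,
                        k_ladder_factor = 1.0,
                        corner_link_factor = 0.15,
                        kd_applies_to_mo36 = FALSE,
                        template_mode = c("proportional", "presence")) {
  template_mode <- match.arg(template_mode)
  p <- list(k_uni_default = k_uni_default, k_bi_base = k_bi_base, D = D,
            k_nano = k_nano, template_factor = template_factor, k_d = k_d,
            temperature = temperature, volume = volume,
            mass_per_mo = mass_per_mo,
            k_ladder_factor = k_ladder_factor,
            corner_link_factor = corner_link_factor,
            kd_applies_to_mo36 = isTRUE(kd_applies_to_mo36),
            template_mode = template_mode)
  validate_rate_params(p)
  structure(p, class = "rate_params")
}

validate_rate_params <- function(p) {
  pos <- c("k_uni_default", "k_bi_base", "D", "temperature", "volume",
           "mass_per_mo", "k_d")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      stop("rate_params: '", f, "' must be a positive finite scalar")
  }
  if (!is.numeric(p$k_nano) || p$k_nano < 0) stop("rate_params: k_nano must be >= 0")
  if (!is.numeric(p$corner_link_factor) || p$corner_link_factor <= 0)
    stop("rate_params: corner_link_factor must be > 0")
  if (!is.numeric(p$k_ladder_factor) || p$k_ladder_factor <= 0)
    stop("rate_params: k_ladder_factor must be > 0")
  if (!is.numeric(p$template_factor) || p$template_factor < 1)
    stop("rate_params: template_factor must be >= 1")
  invisible(p)
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params>\n")
  for (f in c("D", "k_nano", "template_factor", "k_d", "k_bi_base",
              "k_uni_default", "temperature", "volume", "mass_per_mo",
              "k_ladder_factor", "corner_link_factor")) {
    cat(sprintf("  %-16s %g\n", f, x[[f]]))
  }
  cat(sprintf("  %-16s %s\n", "template_mode", x$template_mode))
  cat(sprintf("  %-16s %s\n", "kd_applies_to_mo36", x$kd_applies_to_mo36))
  invisible(x)
}

#' Modify rate parameters
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#' Used by parameter sweeps.
#'
#' @param params A `rate_params` object.
#' @param ... Named fields to replace, e.g. `D = 0.5`.
#' @return A new `rate_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "rate_params"))
  mods <- list(...)
  unknown <- setdiff(names(mods), names(params))
  if (length(unknown)) stop("unknown rate_params field(s): ",
                            paste(unknown, collapse = ", "))
  p <- unclass(params)
  p[names(mods)] <- mods
  validate_rate_params(p)
  structure(p, class = "rate_params")
}
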