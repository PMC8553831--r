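#' Model and run parameters
#'
#' Bundles every constant of the bioenergetic consumer-resource model together
#' with the evolutionary rules and run-control settings. Defaults are the
#' standard configuration of the evolving food-web model: a basal resource
#' with constant inflow `n0 = 1` and outflow `l = 0.5` (so the consumer-free
#' equilibrium biomass is `n0/l = 2`), assimilation efficiency 0.85,
#' interference-competition strength 0.05, allometric attack-rate exponent
#' 0.75, metabolic loss `x = 0.3 * m^-0.25`, extinction threshold `1e-8`, a
#' feeding-range floor of 0.3, introductions every 100 time units with
#' invasion probability `p = 0.2`, and mutant trait standard deviation 0.1.
#'
#' Handling time scales as `h = 0.4 * m^-0.75`. With the type-II functional
#' response used here, the ratio of maximum mass-specific ingestion to
#' metabolic loss is `e / (m * h * x)`; the -0.75 exponent makes that ratio
#' mass-independent at `0.85 / (0.4 * 0.3) ~ 7.1`, the classic bioenergetic
#' consumption-to-metabolism ratio (y ~ 8, times assimilation efficiency).
#' A -0.25 exponent instead makes the ratio decay as `m^-0.5`, so no consumer
#' heavier than `m ~ 50` can ever grow and assembly from the m = 100 ancestor
#' is impossible; the exponent is exposed for sensitivity analysis but the
#' mass-independent scaling is the default.
#'
#' @param n0 basal resource biomass input rate (sets the system time scale).
#' @param l basal resource loss rate.
#' @param m0 basal resource body mass (also the body-mass floor for species).
#' @param e assimilation efficiency of consumed biomass.
#' @param c0 interference-competition strength.
#' @param h_coeff,h_exp handling-time allometry `h = h_coeff * m^h_exp`.
#' @param x_coeff,x_exp metabolic-loss allometry `x = x_coeff * m^x_exp`.
#' @param a_exp attack-rate body-mass exponent (`a = m^a_exp * N`).
#' @param p probability that a new species is an invader (mutant otherwise).
#' @param z_mutant trait standard deviation for mutant offspring.
#' @param z_invader invader strangeness: trait standard deviation for invaders.
#' @param eps extinction threshold; also the introduction biomass.
#' @param s_floor minimum feeding range (kernel SD in log10 mass units).
#' @param intro_interval time between species introductions.
#' @param horizon total simulated time.
#' @param community_interval recording interval for resource and community
#'   biomass (and realized-feeding-range snapshots).
#' @param turnover_interval recording interval for composition snapshots.
#' @param ancestor named vector `c(m=, f=, s=)` of ancestor traits.
#' @param rtol,atol relative and absolute integrator tolerances.
#' @param cannibalism logical; include a consumer's own biomass among its
#'   potential prey (the kernel tail at its own mass). The model places no
#'   exclusion on self-links, so the default is `TRUE`.
#' @param trait_scale `"log10"` (default) mutates body mass and feeding center
#'   on the log10 scale and feeding range linearly; `"linear"` mutates all
#'   three linearly.
#' @param floor_mode `"reject"` (default) redraws trait values below the
#'   floors; `"clamp"` truncates them to the floor.
#' @param turnover_method `"jaccard"` (default) or `"relative"`; see
#'   [turnover_series()].
#' @param max_redraws redraw budget per trait before [draw_traits()] errors.
#' @param max_restarts how many fresh seeds [run_simulation()] may try after a
#'   community-level extinction or integration failure.
#'
#' @return An object of class `fw_params` (a validated named list).
#' @examples
#' p <- fw_params(z_invader = 2, horizon = 1e4)
#' p$z_invader
#' @export
fw_params <- function(n0 = 1.0, l = 0.5, m0 = 1.0, e = 0.85, c0 = 0.05,
                      h_coeff = 0.4, h_exp = -0.75,
                      x_coeff = 0.3, x_exp = -0.25,
                      a_exp = 0.75,
                      p = 0.2, z_mutant = 0.1, z_invader = 0.1,
                      eps = 1e-8, s_floor = 0.3,
                      intro_interval = 100, horizon = 25e6,
                      community_interval = 50000, turnover_interval = 10000,
                      ancestor = c(m = 100, f = 1, s = 0.4),
                      rtol = 1e-6, atol = 1e-12,
                      cannibalism = TRUE,
                      trait_scale = c("log10", "linear"),
                      floor_mode = c("reject", "clamp"),
                      turnover_method = c("jaccard", "relative"),
                      max_redraws = 10000L,
                      max_restarts = 20L) {
  trait_scale <- match.arg(trait_scale)
  floor_mode <- match.arg(floor_mode)
  turnover_method <- match.arg(turnover_method)

  pr <- list(n0 = n0, l = l, m0 = m0, e = e, c0 = c0,
             h_coeff = h_coeff, h_exp = h_exp,
             x_coeff = x_coeff, x_exp = x_exp, a_exp = a_exp,
             p = p, z_mutant = z_mutant, z_invader = z_invader,
             eps = eps, s_floor = s_floor,
             intro_interval = intro_interval, horizon = horizon,
             community_interval = community_interval,
             turnover_interval = turnover_interval,
             ancestor = ancestor,
             rtol = rtol, atol = atol,
             cannibalism = isTRUE(cannibalism),
             trait_scale = trait_scale, floor_mode = floor_mode,
             turnover_method = turnover_method,
             max_redraws = as.integer(max_redraws),
             max_restarts = as.integer(max_restarts))

  for (nm in c("c0", "x_coeff")) {
    v <- pr[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("`%s` must be a single non-negative finite number", nm))
  }
  for (nm in c("n0", "l", "m0", "e", "h_coeff",
               "eps", "s_floor", "intro_interval", "horizon",
               "community_interval", "turnover_interval", "rtol", "atol",
               "z_mutant", "z_invader")) {
    v <- pr[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive finite number", nm))
  }
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  if (!all(c("m", "f", "s") %in% names(ancestor)))
    stop("`ancestor` needs named elements m, f, s")
  if (ancestor[["m"]] < m0) stop("ancestor body mass must be >= m0")
  if (ancestor[["s"]] < s_floor) stop("ancestor feeding range must be >= s_floor")
  if (z_invader < z_mutant)
    warning("z_invader < z_mutant: invaders will be less novel than mutants")
  if (horizon < intro_interval)
    stop("`horizon` must be at least one introduction interval")

  structure(pr, class = "fw_params")
}

#' @export
print.fw_params <- function(x, ...) {
  cat("<fw_params>\n")
  cat(sprintf("  resource: n0=%g l=%g m0=%g (B0*=%g consumer-free)\n",
              x$n0, x$l, x$m0, x$n0 / x$l))
  cat(sprintf("  bioenergetics: e=%g c0=%g h=%g*m^%g x=%g*m^%g a~m^%g\n",
              x$e, x$c0, x$h_coeff, x$h_exp, x$x_coeff, x$x_exp, x$a_exp))
  cat(sprintf("  evolution: p=%g z_mutant=%g z_invader=%g eps=%g s_floor=%g\n",
              x$p, x$z_mutant, x$z_invader, x$eps, x$s_floor))
  cat(sprintf("  run: horizon=%g intro=%g community=%g turnover=%g\n",
              x$horizon, x$intro_interval, x$community_interval,
              x$turnover_interval))
  invisible(x)
}

#' Handling time and metabolic loss allometries
#'
#' Body-mass power laws for the per-unit-biomass handling time and the
#' respiration/mortality loss rate of a consumer.
#'
#' @param m body mass (vectorised); must be positive.
#' @param params an [fw_params()] object supplying coefficient and exponent.
#' @return Numeric vector of rates.
#' @examples
#' metabolic_loss(16)              # 0.3 * 16^-0.25 = 0.15
#' handling_time(16, fw_params(h_exp = -0.25))  # 0.4 * 16^-0.25 = 0.2
#' @export
handling_time <- function(m, params = fw_params()) {
  if (any(!is.finite(m)) || any(m <= 0)) stop("body mass must be positive")
  params$h_coeff * m^params$h_exp
}

#' @rdname handling_time
#' @export
metabolic_loss <- function(m, params = fw_params()) {
  if (any(!is.finite(m)) || any(m <= 0)) stop("body mass must be positive")
  params$x_coeff * m^params$x_exp
}
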