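#' Right-hand side of the community dynamics
#'
#' Evaluates the coupled biomass equations. For every consumer `i`,
#' \deqn{dB_i/dt = \sum_{j \in resources} e\, g_{ij} B_i B_j
#'   - \sum_{j \in consumers} g_{ji} B_j B_i
#'   - \sum_{j \ne i} c_{ij} B_i B_j - x_i B_i,}
#' where the resources of `i` are the basal resource and all extant species,
#' and for the basal resource
#' \deqn{dB_0/dt = n_0 - \sum_j g_{j0} B_j B_0 - l B_0.}
#' This is a pure-R reference implementation used for testing and
#' diagnostics; [integrate_community()] uses the same equations in compiled
#' code.
#'
#' @param state an [fw_state()] object.
#' @param params an [fw_params()] object.
#' @param fluxes if `TRUE`, also return the per-link consumption flux matrix
#'   (prey in rows, basal resource first; consumers in columns) where entry
#'   `(k, i)` is `g_ik B_i B_k`, the biomass flow from prey `k` into consumer
#'   `i` before assimilation.
#' @return A list with `dB0`, `dB` and (optionally) `flux`.
#' @export
community_rhs <- function(state, params = fw_params(), fluxes = FALSE) {
  S <- nrow(state$species)
  y <- c(state$B0, state$B)
  if (any(!is.finite(y))) stop("non-finite biomass in state")
  if (S == 0) {
    out <- list(dB0 = params$n0 - params$l * state$B0, dB = numeric(0))
    if (fluxes) out$flux <- matrix(0, 1, 0)
    return(out)
  }
  A <- .attack_matrix(state$species, params)
  C <- .competition_matrix(state$species, params)
  h <- handling_time(state$species$m, params)
  x <- metabolic_loss(state$species$m, params)
  m <- state$species$m
  B <- state$B

  P <- as.vector(crossprod(A, y))              # sum_k a_ik B_k per consumer
  w <- B / (m * (1 + h * P))                   # B_i / (m_i denom_i)
  flux <- A * rep(w, each = S + 1L) * y        # (k, i): g_ik B_i B_k
  gains <- params$e * colSums(flux)
  losses <- rowSums(flux)                      # biomass removed from prey k
  comp <- as.vector(C %*% B) * B

  out <- list(dB0 = params$n0 - losses[1L] - params$l * state$B0,
              dB = gains - losses[-1L] - comp - x * B)
  if (fluxes) out$flux <- flux
  out
}

#' Advance a community through time
#'
#' Integrates the biomass dynamics over `t_span` time units with an adaptive
#' embedded Runge-Kutta-Fehlberg 4(5) scheme (compiled). The species set is
#' fixed during integration; extinction culling happens between segments via
#' [cull_extinct()]. Biomasses are clamped non-negative (negative excursions
#' are below the absolute tolerance).
#'
#' @param state an [fw_state()] object.
#' @param t_span duration to integrate (non-negative; 0 returns the state
#'   unchanged).
#' @param params an [fw_params()] object (supplies `rtol`, `atol`).
#' @return The advanced [fw_state()].
#' @examples
#' st <- fw_state(t = 0, B0 = 0.5)         # consumer-free resource
#' integrate_community(st, 50)$B0          # -> n0/l = 2
#' @export
integrate_community <- function(state, t_span, params = fw_params()) {
  if (t_span < 0) stop("t_span must be non-negative")
  if (t_span == 0) return(state)
  S <- nrow(state$species)
  A <- if (S > 0) .attack_matrix(state$species, params) else matrix(0, 1, 0)
  C <- if (S > 0) .competition_matrix(state$species, params) else matrix(0, 0, 0)
  h <- if (S > 0) handling_time(state$species$m, params) else numeric(0)
  x <- if (S > 0) metabolic_loss(state$species$m, params) else numeric(0)
  res <- fw_integrate_cpp(state$B0, state$B, state$species$m, A, C, h, x,
                          params$n0, params$l, params$e,
                          t_span, params$rtol, params$atol)
  if (!identical(res$status, "ok"))
    stop(simpleError(paste0("integration failed: ", res$status)),
         call. = FALSE)
  fw_state(t = state$t + t_span, B0 = res$B0, species = state$species,
           B = res$B)
}

#' Remove extinct species
#'
#' Drops every species whose biomass has fallen strictly below the extinction
#' threshold `eps` and stamps its death time. A population sitting exactly at
#' the threshold (e.g. one just introduced) is retained. The basal resource
#' is never removed.
#'
#' @param state an [fw_state()] object.
#' @param params an [fw_params()] object (supplies `eps`).
#' @param t_now time to record as `death_time` on removed species.
#' @return A list with the culled `state` and a `removed` data.frame (the
#'   dropped species rows plus a `death_time` column).
#' @export
cull_extinct <- function(state, params = fw_params(), t_now = state$t) {
  dead <- state$B < params$eps
  removed <- state$species[dead, , drop = FALSE]
  if (nrow(removed)) removed$death_time <- t_now
  else removed$death_time <- numeric(0)
  st <- fw_state(t = state$t, B0 = state$B0,
                 species = state$species[!dead, , drop = FALSE],
                 B = state$B[!dead])
  list(state = st, removed = removed)
}

#' Two-node equilibrium (basal resource + one consumer)
#'
#' Solves the coexistence equilibrium of a single consumer on the basal
#' resource by root-finding on the closed-form conditions
#' `e * g(B0*) * B0* = x` (consumer zero growth) and
#' `n0 - g(B0*) * B1* * B0* - l * B0* = 0` (resource balance). Used as an
#' independent oracle for the integrator.
#'
#' @param consumer a species (traits `m`, `f`, `s`).
#' @param params an [fw_params()] object.
#' @return A list with `B0` and `B1`, or an error if no coexistence
#'   equilibrium exists in `(0, n0/l)`.
#' @export
two_node_equilibrium <- function(consumer, params = fw_params()) {
  m <- .trait(consumer, "m")
  a <- attack_rate(consumer, params$m0, params)
  a_self <- if (params$cannibalism) attack_rate(consumer, m, params) else 0
  h <- handling_time(m, params)
  x <- metabolic_loss(m, params)
  # consumer growth zero: e*a*B0/(m*(1+h*(a*B0 + a_self*B1))) = x, with the
  # (tiny) self-link treated at equilibrium B1(B0) from the resource balance.
  resource_B1 <- function(B0) {
    # n0 - g0*B1*B0 - l*B0 = 0 with denom depending on B1: solve linearly.
    # g0 = a/(m*(1+h*(a*B0+a_self*B1))); flux = g0*B1*B0.
    # => (n0 - l*B0)*(1 + h*a*B0 + h*a_self*B1) = a*B0*B1/m
    cst <- params$n0 - params$l * B0
    B1 <- cst * (1 + h * a * B0) / (a * B0 / m - cst * h * a_self)
    B1
  }
  # per-unit net growth at (B0, B1(B0)), including assimilated self-link gain
  # and the matching self-predation loss
  net <- function(B0) {
    B1 <- resource_B1(B0)
    denom <- 1 + h * (a * B0 + a_self * B1)
    params$e * (a * B0 + a_self * B1) / (m * denom) -
      (a_self * B1) / (m * denom) - x
  }
  upper <- params$n0 / params$l
  root <- stats::uniroot(net, lower = 1e-10, upper = upper * (1 - 1e-9),
                         tol = 1e-14)
  B0 <- root$root
  list(B0 = B0, B1 = resource_B1(B0))
}
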