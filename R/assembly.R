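#' Initial community
#'
#' The system starts from two nodes: the basal resource at its consumer-free
#' equilibrium biomass `n0/l` and a single ancestor species (default traits
#' `m = 100`, `f = 1`, `s = 0.4`) at the extinction-threshold biomass `eps`.
#'
#' @param params an [fw_params()] object.
#' @return An [fw_state()] at `t = 0`.
#' @export
init_community <- function(params = fw_params()) {
  anc <- fw_species(m = params$ancestor[["m"]], f = params$ancestor[["f"]],
                    s = params$ancestor[["s"]], id = 1L, origin = "ancestor",
                    parent_id = NA_integer_, birth_time = 0, params = params)
  fw_state(t = 0, B0 = params$n0 / params$l, species = anc, B = params$eps)
}

#' Mutant or invader?
#'
#' Each scheduled introduction is an invader with probability `p` and a
#' mutant otherwise. Draws from the current R random-number stream.
#'
#' @param params an [fw_params()] object.
#' @return `"mutant"` or `"invader"`.
#' @export
choose_kind <- function(params = fw_params()) {
  if (stats::runif(1) < params$p) "invader" else "mutant"
}

#' Select the parent of a new species
#'
#' Mutant parents are chosen with probability proportional to individual
#' density `B_i / m_i` (abundant, small-bodied populations mutate most
#' often); invader parents are chosen uniformly among extant species. The
#' basal resource is never a parent.
#'
#' @param state an [fw_state()] with at least one extant species.
#' @param kind `"mutant"` or `"invader"`.
#' @return The row index of the chosen parent in `state$species`.
#' @export
select_parent <- function(state, kind = c("mutant", "invader")) {
  kind <- match.arg(kind)
  S <- nrow(state$species)
  if (S == 0)
    stop(structure(class = c("fw_collapse", "error", "condition"),
                   list(message = "community is empty", call = NULL)))
  if (S == 1L) return(1L)
  if (kind == "mutant") {
    w <- state$B / state$species$m
    if (sum(w) <= 0) w <- rep(1, S)
    sample.int(S, 1L, prob = w)
  } else {
    sample.int(S, 1L)
  }
}

#' Draw offspring traits around a parent
#'
#' Body mass and feeding center are mutated on the log10 scale
#' (`log10(m_child) ~ N(log10(m_parent), z)`, likewise `f`), the feeding
#' range linearly (`s_child ~ N(s_parent, z)`); the three traits are drawn
#' independently. Values below the floors (`m >= m0`, `s >= s_floor`) are
#' redrawn (rejection sampling, the default) or clamped, depending on
#' `params$floor_mode`.
#'
#' @param parent a species (traits `m`, `f`, `s`).
#' @param z trait standard deviation (`z_mutant` for mutants, `z_invader`
#'   for invaders).
#' @param params an [fw_params()] object.
#' @return A named list `list(m, f, s)`.
#' @export
draw_traits <- function(parent, z, params = fw_params()) {
  if (!is.finite(z) || z <= 0) stop("trait SD z must be positive")
  draw_floor <- function(center, floor, log_scale) {
    for (k in seq_len(params$max_redraws)) {
      v <- if (log_scale) 10^stats::rnorm(1, log10(center), z)
           else stats::rnorm(1, center, z)
      if (v >= floor) return(v)
      if (params$floor_mode == "clamp") return(floor)
    }
    stop("trait redraw budget exhausted (floor unreachable at this z)")
  }
  log_scale <- params$trait_scale == "log10"
  m <- draw_floor(.trait(parent, "m"), params$m0, log_scale)
  f <- if (log_scale) 10^stats::rnorm(1, log10(.trait(parent, "f")), z)
       else draw_floor(.trait(parent, "f"), .Machine$double.xmin, FALSE)
  s <- draw_floor(.trait(parent, "s"), params$s_floor, FALSE)
  list(m = m, f = f, s = s)
}

#' Introduce a new species
#'
#' Adds a mutant or invader at the extinction-threshold biomass `eps`. For a
#' mutant the introduction biomass is transferred from the parent population
#' (total biomass unchanged); for an invader it is injected from outside
#' (total biomass rises by `eps`). Mutant traits use `z = z_mutant`; invader
#' traits use `z = z_invader`.
#'
#' @param state an [fw_state()] with at least one extant species.
#' @param kind `"mutant"` or `"invader"`.
#' @param params an [fw_params()] object.
#' @param t introduction time stamped on the child.
#' @param next_id integer id to assign to the child.
#' @return A list with the updated `state` and an `event` record
#'   (`t`, `kind`, `parent_id`, `child` row, `z_used`).
#' @export
introduce <- function(state, kind = c("mutant", "invader"),
                      params = fw_params(), t = state$t,
                      next_id = max(state$species$id) + 1L) {
  kind <- match.arg(kind)
  pi <- select_parent(state, kind)
  parent <- state$species[pi, ]
  z <- if (kind == "mutant") params$z_mutant else params$z_invader
  tr <- draw_traits(parent, z, params)
  child <- fw_species(m = tr$m, f = tr$f, s = tr$s, id = next_id,
                      origin = kind, parent_id = parent$id, birth_time = t,
                      params = params)
  B <- state$B
  if (kind == "mutant") B[pi] <- B[pi] - params$eps
  st <- fw_state(t = state$t, B0 = state$B0,
                 species = rbind(state$species, child),
                 B = c(pmax(B, 0), params$eps))
  list(state = st,
       event = list(t = t, kind = kind, parent_id = parent$id, child = child,
                    z_used = z))
}
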