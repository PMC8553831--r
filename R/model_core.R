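#' Construct a species
#'
#' A species is defined by three heritable traits: body mass `m` (its position
#' on the body-size axis), feeding center `f` (the body mass it attacks most
#' efficiently) and feeding range `s` (the SD of its Gaussian feeding kernel,
#' in log10 body-mass units). Traits are fixed for the species' lifetime.
#'
#' @param m body mass; must be at least the resource mass floor.
#' @param f feeding center, on the body-mass scale; positive.
#' @param s feeding range; at least the configured floor.
#' @param id integer identifier, unique within a run.
#' @param origin one of `"ancestor"`, `"mutant"`, `"invader"`.
#' @param parent_id id of the parent species, or `NA` for the ancestor.
#' @param birth_time simulation time of introduction.
#' @param params an [fw_params()] object used to validate the trait floors.
#' @return A one-row `data.frame` with columns
#'   `id, m, f, s, origin, parent_id, birth_time`.
#' @examples
#' fw_species(m = 100, f = 1, s = 0.4)
#' @export
fw_species <- function(m, f, s, id = 1L, origin = "ancestor",
                       parent_id = NA_integer_, birth_time = 0,
                       params = fw_params()) {
  if (!is.finite(m) || m < params$m0) stop("body mass must be >= m0")
  if (!is.finite(f) || f <= 0) stop("feeding center must be positive")
  if (!is.finite(s) || s < params$s_floor) stop("feeding range must be >= s_floor")
  origin <- match.arg(origin, c("ancestor", "mutant", "invader"))
  data.frame(id = as.integer(id), m = m, f = f, s = s, origin = origin,
             parent_id = as.integer(parent_id), birth_time = birth_time,
             stringsAsFactors = FALSE)
}

#' Construct a community state
#'
#' Snapshot of the system at one time point: the basal resource biomass plus
#' the extant species and their biomass densities.
#'
#' @param t simulation time.
#' @param B0 basal resource biomass density (non-negative).
#' @param species a `data.frame` of extant species (rows as from
#'   [fw_species()]).
#' @param B numeric vector of biomass densities, one per species row.
#' @return An object of class `fw_state`.
#' @export
fw_state <- function(t = 0, B0 = 2, species = fw_species(100, 1, 0.4)[0, ],
                     B = numeric(0)) {
  if (!is.finite(B0) || B0 < 0) stop("B0 must be finite and non-negative")
  if (nrow(species) != length(B))
    stop("species table and biomass vector lengths differ")
  if (length(B) && (any(!is.finite(B)) || any(B < 0)))
    stop("species biomasses must be finite and non-negative")
  structure(list(t = t, B0 = B0, species = species, B = as.numeric(B)),
            class = "fw_state")
}

#' @export
print.fw_state <- function(x, ...) {
  cat(sprintf("<fw_state> t=%g  B0=%.6g  S=%d  community biomass=%.6g\n",
              x$t, x$B0, nrow(x$species), sum(x$B)))
  invisible(x)
}

# accept either a list/one-row data.frame with $m, $f, $s
.trait <- function(sp, what) {
  v <- sp[[what]]
  if (is.null(v) || length(v) != 1L) stop("species must carry traits m, f, s")
  v
}

#' Gaussian feeding kernel
#'
#' The feeding kernel is a normal density over log10 body mass: a consumer
#' with feeding center `f` and feeding range `s` attacks a resource of body
#' mass `m_j` in proportion to
#' `N = 1/(s * sqrt(2*pi)) * exp(-(log10(f) - log10(m_j))^2 / (2 s^2))`.
#' It integrates to 1 over log10 mass and peaks at `m_j = f`.
#'
#' @param f feeding center (body-mass scale, positive).
#' @param s feeding range (log10-mass SD, positive).
#' @param m_j resource body mass (vectorised, positive).
#' @return Kernel value(s), strictly positive.
#' @examples
#' feeding_kernel(1, 0.4, 1)   # peak: 1 / (0.4 * sqrt(2*pi))
#' @export
feeding_kernel <- function(f, s, m_j) {
  if (!is.finite(f) || f <= 0) stop("feeding center must be positive")
  if (!is.finite(s) || s <= 0) stop("feeding range must be positive")
  if (any(!is.finite(m_j)) || any(m_j <= 0)) stop("resource mass must be positive")
  stats::dnorm(log10(f) - log10(m_j), mean = 0, sd = s)
}

#' Mass-specific attack rate
#'
#' `a_ij = m_i^0.75 * N_ij`: the allometric capture capacity of consumer `i`
#' times its feeding kernel evaluated at the resource's body mass. Because
#' the kernel is a normalised density, narrower feeding ranges (specialists)
#' buy higher peak attack rates - the model's efficiency/generalism trade-off.
#'
#' @param consumer a species (list or one-row data.frame with `m`, `f`, `s`).
#' @param m_j resource body mass (vectorised).
#' @param params an [fw_params()] object (supplies the allometric exponent).
#' @return Attack rate(s).
#' @examples
#' anc <- fw_species(100, 1, 0.4)
#' attack_rate(anc, 1)          # ~31.54
#' @export
attack_rate <- function(consumer, m_j, params = fw_params()) {
  .trait(consumer, "m")^params$a_exp *
    feeding_kernel(.trait(consumer, "f"), .trait(consumer, "s"), m_j)
}

#' Maximum attack rate
#'
#' The attack rate on an ideal prey sitting exactly at the consumer's feeding
#' center: `m_i^0.75 / (s_i * sqrt(2*pi))`. Used to normalise realized
#' feeding-range calculations.
#'
#' @inheritParams attack_rate
#' @return A single attack rate.
#' @export
max_attack_rate <- function(consumer, params = fw_params()) {
  .trait(consumer, "m")^params$a_exp /
    (.trait(consumer, "s") * sqrt(2 * pi))
}

#' Mass-specific consumption rate (type-II functional response)
#'
#' `g_ij = (1/m_i) * a_ij / (1 + sum_k h_i a_ik B_k)`, where the saturating
#' sum runs over every potential prey `k` of consumer `i`: the basal resource
#' and all extant species (including the consumer itself when cannibalistic
#' self-links are enabled).
#'
#' @param consumer a species with traits `m`, `f`, `s`.
#' @param j prey index: `0` for the basal resource, otherwise the row number
#'   of the prey in `state$species`.
#' @param state an [fw_state()] snapshot supplying prey masses and biomasses.
#' @param params an [fw_params()] object.
#' @return The mass-specific consumption rate of `consumer` on prey `j`.
#' @export
consumption_rate <- function(consumer, j, state, params = fw_params()) {
  prey_m <- c(params$m0, state$species$m)
  prey_B <- c(state$B0, state$B)
  if (j < 0 || j > nrow(state$species)) stop("prey index out of range")
  if (!params$cannibalism) {
    self <- which(state$species$id == consumer$id)
    if (length(self)) prey_B[self + 1L] <- 0
  }
  a <- attack_rate(consumer, prey_m, params)
  h <- handling_time(.trait(consumer, "m"), params)
  denom <- 1 + h * sum(a * prey_B)
  (a[j + 1L] / .trait(consumer, "m")) / denom
}

#' Feeding-kernel overlap between two consumers
#'
#' The integral of the product of two feeding kernels over the log10
#' body-mass axis, `I_ij = integral N_ik N_jk d(log10 m_k)`. For two normal
#' densities this has the closed form
#' `1/sqrt(2*pi*(s_i^2+s_j^2)) * exp(-(log10 f_i - log10 f_j)^2 / (2*(s_i^2+s_j^2)))`,
#' i.e. a normal density in the distance between the feeding centers. The
#' self-overlap is `I_ii = 1/(2 s_i sqrt(pi))`.
#'
#' @param i,j species (lists or one-row data.frames with `f`, `s`).
#' @return The overlap integral (symmetric in its arguments).
#' @examples
#' a <- fw_species(100, 1, 0.4)
#' competition_overlap(a, a)    # 1/(2*0.4*sqrt(pi)) ~ 0.7052
#' @export
competition_overlap <- function(i, j) {
  s2 <- .trait(i, "s")^2 + .trait(j, "s")^2
  d <- log10(.trait(i, "f")) - log10(.trait(j, "f"))
  exp(-d^2 / (2 * s2)) / sqrt(2 * pi * s2)
}

#' Interference-competition coefficient
#'
#' `c_ij = c0 * I_ij / I_ii` for `i != j`: the competitive pressure exerted on
#' focal consumer `i` by consumer `j`, proportional to their kernel overlap
#' normalised by the focal species' self-overlap. The normalisation makes the
#' coefficient asymmetric in general and equal to `c0` for identical kernels.
#' No intraspecific interference term exists (`i == j` is an error).
#'
#' @param i focal species; @param j competitor species.
#' @param params an [fw_params()] object (supplies `c0`).
#' @return The competition coefficient acting on `i` from `j`.
#' @export
competition_coefficient <- function(i, j, params = fw_params()) {
  if (!is.na(i[["id"]] %||% NA) && !is.na(j[["id"]] %||% NA) &&
      identical(i[["id"]], j[["id"]]))
    stop("interference competition is defined for distinct consumers only")
  I_ii <- 1 / (2 * .trait(i, "s") * sqrt(pi))
  params$c0 * competition_overlap(i, j) / I_ii
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Attack matrix: (S+1) prey rows (basal resource first) by S consumer columns.
.attack_matrix <- function(species, params) {
  S <- nrow(species)
  prey_m <- c(params$m0, species$m)
  lg <- log10(prey_m)
  A <- matrix(0, nrow = S + 1L, ncol = S)
  for (i in seq_len(S)) {
    A[, i] <- species$m[i]^params$a_exp *
      stats::dnorm(log10(species$f[i]) - lg, sd = species$s[i])
  }
  if (!params$cannibalism && S > 0) A[cbind(seq_len(S) + 1L, seq_len(S))] <- 0
  A
}

# Competition matrix: entry (i, j) is c_ij acting on focal i from j; zero diagonal.
.competition_matrix <- function(species, params) {
  S <- nrow(species)
  if (S == 0) return(matrix(0, 0, 0))
  lgf <- log10(species$f)
  s2 <- outer(species$s^2, species$s^2, `+`)
  d2 <- outer(lgf, lgf, `-`)^2
  I <- exp(-d2 / (2 * s2)) / sqrt(2 * pi * s2)
  C <- params$c0 * I / (1 / (2 * species$s * sqrt(pi)))  # rows: focal i
  diag(C) <- 0
  C
}
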