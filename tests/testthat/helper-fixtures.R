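# Shared fixtures: random trait sets, random community states, and one
# memoised scaled-down assembly run reused by several structural tests.

rand_species_df <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(id = seq_len(n),
             m = 10^runif(n, 0, 3),
             f = 10^runif(n, -0.5, 2.5),
             s = runif(n, 0.3, 1.5),
             origin = "mutant", parent_id = NA_integer_, birth_time = 0,
             stringsAsFactors = FALSE)
}

rand_state <- function(n = 5, seed = 1, B0 = 1.5) {
  sp <- rand_species_df(n, seed)
  set.seed(seed + 1000)
  fw_state(t = 0, B0 = B0, species = sp, B = runif(n, 0.01, 2))
}

# naive per-pair evaluation of the biomass equations built from the public
# scalar rate functions; independent of the vectorised/compiled path
naive_rhs <- function(state, params) {
  S <- nrow(state$species)
  dB <- numeric(S)
  for (i in seq_len(S)) {
    ci <- state$species[i, ]
    gain <- 0
    for (j in 0:S) {
      Bj <- if (j == 0) state$B0 else state$B[j]
      gain <- gain + params$e * consumption_rate(ci, j, state, params) *
        state$B[i] * Bj
    }
    pred <- 0
    for (j in seq_len(S)) {
      cj <- state$species[j, ]
      pred <- pred + consumption_rate(cj, i, state, params) *
        state$B[j] * state$B[i]
    }
    comp <- 0
    for (j in seq_len(S)) if (j != i)
      comp <- comp + competition_coefficient(ci, state$species[j, ], params) *
        state$B[i] * state$B[j]
    dB[i] <- gain - pred - comp -
      metabolic_loss(ci$m, params) * state$B[i]
  }
  dB0 <- params$n0 - params$l * state$B0
  for (j in seq_len(S))
    dB0 <- dB0 - consumption_rate(state$species[j, ], 0, state, params) *
      state$B[j] * state$B0
  list(dB0 = dB0, dB = dB)
}

# one scaled-down assembly run (horizon 1e5, maximally strange invaders),
# computed once per test session
scaled_run_cache <- new.env(parent = emptyenv())
scaled_run <- function() {
  if (is.null(scaled_run_cache$rec)) {
    p <- fw_params(horizon = 1e5, z_invader = 5,
                   community_interval = 500, turnover_interval = 1000)
    scaled_run_cache$rec <- run_simulation(p, seed = 42)
  }
  scaled_run_cache$rec
}
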