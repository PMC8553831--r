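#' Scheduled introduction times
#'
#' New species arrive at `t = intro_interval, 2*intro_interval, ...` up to
#' and including the horizon: `floor(horizon / intro_interval)` events.
#'
#' @param horizon total simulated time.
#' @param intro_interval time between introductions.
#' @return Numeric vector of event times.
#' @examples
#' length(introduction_times(25e6, 100))  # 250000
#' @export
introduction_times <- function(horizon, intro_interval = 100) {
  if (horizon < intro_interval) return(numeric(0))
  seq(intro_interval, by = intro_interval,
      length.out = floor(horizon / intro_interval))
}

.derive_seed <- function(seed, attempt) {
  as.integer((as.numeric(seed) + 104729 * attempt) %% .Machine$integer.max)
}

.run_once <- function(params, seed) {
  set.seed(seed)
  state <- init_community(params)
  times <- introduction_times(params$horizon, params$intro_interval)
  n_intro <- length(times)

  # append-only ledger, preallocated; species id doubles as the row index
  n_max <- n_intro + 1L
  led <- new.env(parent = emptyenv())
  led$m <- led$f <- led$s <- led$birth <- led$death <- rep(NA_real_, n_max)
  led$origin <- rep(NA_character_, n_max)
  led$parent <- rep(NA_integer_, n_max)
  anc <- state$species
  led$m[1] <- anc$m; led$f[1] <- anc$f; led$s[1] <- anc$s
  led$birth[1] <- 0; led$origin[1] <- "ancestor"

  n_comm <- sum(times %% params$community_interval == 0)
  res_t <- res_B0 <- comm_B <- comm_minB <- comm_S <- rep(NA_real_, n_comm)
  snapshots <- list()        # composition at turnover interval
  comm_snapshots <- list()   # composition at community interval (for realized range)
  ic <- 0L

  for (k in seq_len(n_intro)) {
    t_now <- times[k]
    state <- integrate_community(state, params$intro_interval, params)

    culled <- cull_extinct(state, params, t_now = t_now)
    state <- culled$state
    if (nrow(culled$removed))
      led$death[culled$removed$id] <- t_now
    if (nrow(state$species) == 0L)
      stop(structure(class = c("fw_collapse", "error", "condition"),
                     list(message = "community-level extinction",
                          call = NULL)))

    kind <- choose_kind(params)
    intro <- introduce(state, kind, params, t = t_now, next_id = k + 1L)
    state <- intro$state
    ch <- intro$event$child
    led$m[ch$id] <- ch$m; led$f[ch$id] <- ch$f; led$s[ch$id] <- ch$s
    led$birth[ch$id] <- t_now
    led$origin[ch$id] <- kind
    led$parent[ch$id] <- intro$event$parent_id

    resident <- state$species$birth_time < t_now
    if (t_now %% params$community_interval == 0) {
      ic <- ic + 1L
      res_t[ic] <- t_now
      res_B0[ic] <- state$B0
      comm_B[ic] <- sum(state$B[resident])
      comm_minB[ic] <- min(state$B)
      comm_S[ic] <- sum(resident)
      comm_snapshots[[as.character(t_now)]] <- state$species$id[resident]
    }
    if (t_now %% params$turnover_interval == 0)
      snapshots[[as.character(t_now)]] <- state$species$id[resident]
  }

  used <- !is.na(led$birth)
  ledger <- data.frame(id = which(used), origin = led$origin[used],
                       parent_id = led$parent[used], m = led$m[used],
                       f = led$f[used], s = led$s[used],
                       birth_time = led$birth[used],
                       death_time = led$death[used],
                       stringsAsFactors = FALSE)
  ledger$censored <- is.na(ledger$death_time)
  ledger$lifespan <- ifelse(ledger$censored, params$horizon - ledger$birth_time,
                            ledger$death_time - ledger$birth_time)

  list(ledger = ledger,
       resource_series = data.frame(t = res_t[seq_len(ic)],
                                    B0 = res_B0[seq_len(ic)]),
       community_series = data.frame(t = res_t[seq_len(ic)],
                                     biomass = comm_B[seq_len(ic)],
                                     richness = comm_S[seq_len(ic)],
                                     min_B = comm_minB[seq_len(ic)]),
       snapshots = snapshots, community_snapshots = comm_snapshots,
       final_state = state)
}

#' Run one full assembly simulation
#'
#' Runs the introduction/integration/culling cycle from the two-node initial
#' system to the horizon. Each cycle integrates the biomass dynamics for one
#' introduction interval, removes populations below the extinction threshold,
#' introduces one new species (mutant or invader), and then records any
#' outputs due at that time: resource and community biomass (and the
#' composition used for realized feeding range) every `community_interval`,
#' composition snapshots every `turnover_interval`. Species introduced at a
#' recording time are excluded from that record. Deterministic given
#' `(params, seed)`.
#'
#' If the community goes extinct or the integrator fails, the run restarts
#' with a derived fresh seed (up to `params$max_restarts` times) and the
#' restart count is reported.
#'
#' @param params an [fw_params()] object.
#' @param seed integer random seed.
#' @return An object of class `fw_record`: list with `params`, `seed`,
#'   `seed_used`, `restarts`, `status`, `ledger`, `resource_series`,
#'   `community_series`, `snapshots`, `community_snapshots`, `final_state`.
#' @examples
#' rec <- run_simulation(fw_params(horizon = 2000, community_interval = 500,
#'                                 turnover_interval = 500), seed = 1)
#' nrow(rec$ledger)  # 21 species ever introduced (ancestor + 20)
#' @export
run_simulation <- function(params = fw_params(), seed = 1L) {
  for (attempt in 0:params$max_restarts) {
    seed_k <- .derive_seed(seed, attempt)
    res <- tryCatch(.run_once(params, seed_k),
                    fw_collapse = function(e) e,
                    error = function(e) {
                      if (grepl("integration failed", conditionMessage(e)))
                        e
                      else
                        stop(e)
                    })
    if (!inherits(res, "condition")) {
      out <- c(list(params = params, seed = seed, seed_used = seed_k,
                    restarts = attempt,
                    status = if (attempt == 0) "completed"
                             else sprintf("restarted(%d)", attempt)),
               res)
      class(out) <- "fw_record"
      return(out)
    }
  }
  stop(sprintf("simulation failed after %d restarts (last: %s)",
               params$max_restarts, conditionMessage(res)))
}

#' @export
print.fw_record <- function(x, ...) {
  cat(sprintf(paste0("<fw_record> z=%g seed=%d status=%s  species ever=%d  ",
                     "extant at horizon=%d\n"),
              x$params$z_invader, x$seed, x$status, nrow(x$ledger),
              sum(x$ledger$censored)))
  invisible(x)
}

#' Sweep the invader strangeness parameter
#'
#' Runs one simulation per (z, replicate) cell with invasion probability and
#' all other parameters held fixed. At production scale the design is 50
#' evenly spaced z values from 0.1 to 5 with 100 replicate seed sets (5000
#' runs); desk-scale analyses use fewer values, fewer replicates and a
#' shorter horizon.
#'
#' @param z_values numeric vector of invader strangeness values.
#' @param replicates replicates per z value.
#' @param params base [fw_params()]; `z_invader` is overwritten per run.
#' @param seed base seed; run `r` uses `seed + r`.
#' @return A list of `fw_record` objects with attributes `z` and `replicate`.
#' @export
run_sweep <- function(z_values = seq(0.1, 5, length.out = 50),
                      replicates = 1L, params = fw_params(), seed = 1L) {
  if (!length(z_values)) stop("z_values must be non-empty")
  grid <- expand.grid(replicate = seq_len(replicates), z = z_values,
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    p <- params
    p$z_invader <- grid$z[r]
    rec <- run_simulation(p, seed = .derive_seed(seed, 0) + r)
    rec$z <- grid$z[r]
    rec$replicate <- grid$replicate[r]
    out[[r]] <- rec
  }
  out
}

#' Export a composition snapshot as a feeding edge list
#'
#' Builds the (complete) consumer-resource interaction list for one recorded
#' snapshot: one row per consumer/resource pair with the attack rate, the
#' basal resource carrying id 0. An optional threshold on
#' `attack_rate / max_attack_rate` trims negligible tail links.
#'
#' @param ids integer vector of extant species ids (one entry of
#'   `record$snapshots`).
#' @param ledger the record's species ledger (supplies traits by id).
#' @param params an [fw_params()] object.
#' @param threshold drop links with relative attack rate below this (0 keeps
#'   the complete graph).
#' @return A data.frame with `consumer_id`, `resource_id`, `attack_rate`.
#' @export
snapshot_edgelist <- function(ids, ledger, params = fw_params(),
                              threshold = 0) {
  sp <- ledger[match(ids, ledger$id), , drop = FALSE]
  prey_id <- c(0L, sp$id)
  prey_m <- c(params$m0, sp$m)
  rows <- lapply(seq_len(nrow(sp)), function(i) {
    a <- attack_rate(sp[i, ], prey_m, params)
    rel <- a / max_attack_rate(sp[i, ], params)
    keep <- rel >= threshold
    data.frame(consumer_id = sp$id[i], resource_id = prey_id[keep],
               attack_rate = a[keep])
  })
  do.call(rbind, rows)
}

#' Write a simulation record to disk
#'
#' Writes tab-separated tables (`ledger.tsv`, `resource_series.tsv`,
#' `community_series.tsv`, `composition/<t>.tsv`) and a JSON manifest with
#' the configuration, seed and status.
#'
#' @param record an `fw_record`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_record <- function(record, dir) {
  dir.create(file.path(dir, "composition"), recursive = TRUE,
             showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(record$ledger, "ledger.tsv")
  wt(record$resource_series, "resource_series.tsv")
  wt(record$community_series, "community_series.tsv")
  for (tm in names(record$snapshots))
    wt(data.frame(id = record$snapshots[[tm]]),
       file.path("composition", paste0(tm, ".tsv")))
  manifest <- list(seed = record$seed, seed_used = record$seed_used,
                   status = record$status, restarts = record$restarts,
                   params = record$params[setdiff(names(record$params),
                                                  "ancestor")],
                   ancestor = as.list(record$params$ancestor))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
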