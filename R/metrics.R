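#' Temporal variability of resource and community biomass
#'
#' Sample standard deviation of the recorded basal-resource biomass series
#' (`sd_resource`) or of the summed community biomass series
#' (`sd_community`), the study's disturbance indicators. The series exclude
#' time 0 and species introduced at each recording time by construction.
#'
#' @param record an `fw_record` from [run_simulation()].
#' @param burn_in drop recorded points before this time. The default matches
#'   the study's sampling design, under which community data are first
#'   recorded at t = 50,000 and species data from the first 50,000 time
#'   units are discarded as assembly transient; set to 0 to keep everything.
#' @return A single non-negative number.
#' @export
sd_resource <- function(record, burn_in = 50000) {
  d <- record$resource_series
  x <- d$B0[d$t >= burn_in]
  if (length(x) < 2) stop("need at least 2 recorded points for an SD")
  stats::sd(x)
}

#' @rdname sd_resource
#' @export
sd_community <- function(record, burn_in = 50000) {
  d <- record$community_series
  x <- d$biomass[d$t >= burn_in]
  if (length(x) < 2) stop("need at least 2 recorded points for an SD")
  stats::sd(x)
}

#' Species turnover between composition snapshots
#'
#' Compositional change between each pair of consecutive snapshots. The
#' default (`"jaccard"`) is the Jaccard dissimilarity
#' `(|A \ B| + |B \ A|) / |A U B|`: 0 when the extant sets are identical, 1
#' when disjoint. The alternative `"relative"` formula `(gained + lost)/|A|`
#' expresses change relative to the earlier community and is unbounded.
#' An empty union yields 0.
#'
#' @param record an `fw_record`.
#' @param method `"jaccard"` or `"relative"`; defaults to the record's
#'   configured `turnover_method`.
#' @param burn_in drop snapshots before this time (see [sd_resource()]).
#' @return `turnover_series()`: one value per consecutive snapshot pair;
#'   `mean_turnover()`: their mean.
#' @export
turnover_series <- function(record, method = record$params$turnover_method,
                            burn_in = 50000) {
  snaps <- record$snapshots[as.numeric(names(record$snapshots)) >= burn_in]
  if (length(snaps) < 2) stop("need at least 2 composition snapshots")
  vapply(seq_len(length(snaps) - 1L), function(i) {
    set_turnover(snaps[[i]], snaps[[i + 1L]], method)
  }, numeric(1))
}

#' @rdname turnover_series
#' @export
mean_turnover <- function(record, method = record$params$turnover_method,
                          burn_in = 50000) {
  mean(turnover_series(record, method, burn_in = burn_in))
}

#' @rdname turnover_series
#' @param a,b id sets (integer vectors) of two consecutive snapshots.
#' @export
set_turnover <- function(a, b, method = c("jaccard", "relative")) {
  method <- match.arg(method)
  changed <- length(setdiff(a, b)) + length(setdiff(b, a))
  if (method == "jaccard") {
    u <- length(union(a, b))
    if (u == 0) 0 else changed / u
  } else {
    if (length(a) == 0) 0 else changed / length(a)
  }
}

#' Fundamental feeding range of viable mutants
#'
#' Mean and median feeding range `s` over ledger species that (i) are
#' mutants (invader traits are directly manipulated by the experiment and
#' would bias the metric), (ii) survived at least `min_survival` time units
#' after introduction, and (iii) were born after the burn-in period that
#' removes transient assembly dynamics.
#'
#' @param ledger a species ledger (from an `fw_record`).
#' @param burn_in exclude species born before this time.
#' @param min_survival minimum observed lifespan to count as viable.
#' @return `list(mean, median, n)`.
#' @export
mutant_range_summary <- function(ledger, burn_in = 50000, min_survival = 100) {
  keep <- ledger$origin == "mutant" & ledger$birth_time >= burn_in &
    ledger$lifespan >= min_survival
  if (!any(keep)) stop("no qualifying mutant species in ledger")
  s <- ledger$s[keep]
  list(mean = mean(s), median = stats::median(s), n = length(s))
}

#' Realized feeding range of one consumer
#'
#' The fraction of the community a consumer actually feeds on: entities
#' (basal resource plus every extant species, including the focal consumer)
#' whose relative attack rate `a_ij / a_max` is at least `threshold`,
#' divided by the total entity count. Since
#' `a_ij / a_max = exp(-(log10 f - log10 m_j)^2 / (2 s^2))`, a prey passes
#' the default 0.1 threshold exactly when
#' `|log10 f - log10 m_j| <= s * sqrt(2 * ln 10)`.
#'
#' @param consumer a species (traits `m`, `f`, `s`).
#' @param community data.frame of extant species (must include the focal
#'   consumer's row).
#' @param params an [fw_params()] object.
#' @param threshold minimum relative attack rate for a link to count.
#' @return Proportion in `[0, 1]`.
#' @export
realized_range <- function(consumer, community, params = fw_params(),
                           threshold = 0.1) {
  prey_m <- c(params$m0, community$m)
  rel <- attack_rate(consumer, prey_m, params) /
    max_attack_rate(consumer, params)
  sum(rel >= threshold) / length(prey_m)
}

#' Mean realized feeding range of a simulation
#'
#' Averages [realized_range()] over every consumer in every recorded
#' community-interval snapshot of a run (species introduced at the snapshot
#' time are excluded by construction of the snapshots).
#'
#' @param record an `fw_record`.
#' @param threshold minimum relative attack rate for a link to count.
#' @param burn_in drop snapshots before this time (see [sd_resource()]).
#' @return Mean proportion in `[0, 1]`.
#' @export
mean_realized_range <- function(record, threshold = 0.1, burn_in = 50000) {
  snaps <- record$community_snapshots[
    as.numeric(names(record$community_snapshots)) >= burn_in]
  if (!length(snaps)) stop("no community snapshots recorded")
  vals <- unlist(lapply(snaps, function(ids) {
    comm <- record$ledger[match(ids, record$ledger$id), , drop = FALSE]
    vapply(seq_len(nrow(comm)), function(i)
      realized_range(comm[i, ], comm, record$params, threshold), numeric(1))
  }))
  mean(vals)
}

#' Lifespan slope: persistence versus feeding range
#'
#' Regression coefficient of species lifespan on log10 feeding range from a
#' gamma GLM with log link, fit to all uncensored species of one run.
#' Positive slopes mean generalists outlive specialists. With
#' `log_response = TRUE` the response is log10-transformed as well (both
#' readings of "log10-scaled data" are available; the predictor-only
#' transform is the default).
#'
#' @param ledger a species ledger.
#' @param log_response also log10-transform the lifespan response.
#' @return The slope coefficient (a single number), or an error for
#'   degenerate designs.
#' @export
lifespan_slope <- function(ledger, log_response = FALSE) {
  d <- ledger[!ledger$censored & ledger$lifespan > 0, , drop = FALSE]
  if (nrow(d) < 10) stop("need at least 10 uncensored species")
  if (stats::sd(d$s) == 0) stop("feeding range is constant: slope undefined")
  y <- if (log_response) log10(d$lifespan) else d$lifespan
  fit <- glm_fit(y, cbind(1, log10(d$s)), family = "gamma", link = "log")
  if (!fit$converged) stop("lifespan regression did not converge")
  unname(fit$coefficients[2])
}

#' Mean lifespan of specialist and generalist species
#'
#' Bins uncensored species by feeding range (`s <= specialist_max` are
#' specialists, `s >= generalist_min` generalists, intermediates excluded)
#' and returns each bin's mean lifespan. Empty bins are flagged `NA`.
#'
#' @param ledger a species ledger.
#' @param specialist_max,generalist_min bin cutoffs on `s`.
#' @return `list(specialist, generalist, n_specialist, n_generalist)`.
#' @export
binned_persistence <- function(ledger, specialist_max = 0.32,
                               generalist_min = 0.39) {
  d <- ledger[!ledger$censored, , drop = FALSE]
  spec <- d$lifespan[d$s <= specialist_max]
  gen <- d$lifespan[d$s >= generalist_min]
  list(specialist = if (length(spec)) mean(spec) else NA_real_,
       generalist = if (length(gen)) mean(gen) else NA_real_,
       n_specialist = length(spec), n_generalist = length(gen))
}

#' All per-simulation metrics
#'
#' One row of summary statistics for a run: invader strangeness, the
#' disturbance metrics (resource/community biomass SD, mean turnover), the
#' generalism metrics (mean/median viable-mutant feeding range, mean
#' realized feeding range) and the persistence metrics (lifespan slope,
#' binned mean lifespans). Metrics whose preconditions fail (e.g. no
#' qualifying mutants) are `NA`.
#'
#' @param record an `fw_record`.
#' @param burn_in burn-in applied to every metric (see [sd_resource()]).
#' @return A one-row `data.frame`.
#' @export
sim_metrics <- function(record, burn_in = 50000) {
  tryna <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  mrs <- tryCatch(mutant_range_summary(record$ledger, burn_in = burn_in),
                  error = function(e) list(mean = NA_real_, median = NA_real_))
  bp <- binned_persistence(record$ledger)
  data.frame(z = record$params$z_invader,
             replicate = record$replicate %||% NA_integer_,
             seed = record$seed,
             sd_resource = tryna(sd_resource(record, burn_in = burn_in)),
             sd_community = tryna(sd_community(record, burn_in = burn_in)),
             mean_turnover = tryna(mean_turnover(record, burn_in = burn_in)),
             mean_mutant_s = mrs$mean,
             median_mutant_s = mrs$median,
             mean_realized_range = tryna(mean_realized_range(
               record, burn_in = burn_in)),
             lifespan_slope = tryna(lifespan_slope(record$ledger)),
             mean_lifespan_specialist = bp$specialist,
             mean_lifespan_generalist = bp$generalist)
}

#' Metrics table for a sweep
#'
#' @param records a list of `fw_record`s from [run_sweep()].
#' @param burn_in burn-in for [mutant_range_summary()].
#' @return A `data.frame` with one row per run.
#' @export
metrics_table <- function(records, burn_in = 50000) {
  do.call(rbind, lapply(records, sim_metrics, burn_in = burn_in))
}
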