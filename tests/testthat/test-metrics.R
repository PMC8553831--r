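make_record <- function(ledger = NULL, resource = NULL, community = NULL,
                        snapshots = NULL, params = fw_params()) {
  structure(list(params = params, seed = 1L, ledger = ledger,
                 resource_series = resource, community_series = community,
                 snapshots = snapshots, community_snapshots = snapshots),
            class = "fw_record")
}

make_ledger <- function(s, lifespan, origin = "mutant", birth = 60000,
                        censored = FALSE) {
  n <- length(s)
  data.frame(id = seq_len(n), origin = rep_len(origin, n),
             parent_id = NA_integer_, m = 10, f = 1, s = s,
             birth_time = rep_len(birth, n),
             death_time = ifelse(rep_len(censored, n), NA,
                                 rep_len(birth, n) + lifespan),
             censored = rep_len(censored, n), lifespan = lifespan)
}

test_that("biomass variability is the sample SD of the recorded series", {
  rec <- make_record(
    resource = data.frame(t = c(50000, 100000), B0 = c(1, 3)),
    community = data.frame(t = c(50000, 100000, 150000),
                           biomass = c(2, 2, 2)))
  expect_equal(sd_resource(rec), sqrt(2))
  expect_equal(sd_community(rec), 0)
  # brute-force two-pass SD on a longer fixture
  set.seed(1)
  x <- runif(40)
  rec2 <- make_record(resource = data.frame(t = 50000 + 500 * (0:39), B0 = x))
  expect_equal(sd_resource(rec2), sqrt(sum((x - mean(x))^2) / 39))
  # fewer than 2 usable points is an error
  rec3 <- make_record(resource = data.frame(t = 100, B0 = 1))
  expect_error(sd_resource(rec3), "at least 2")
})

test_that("burn-in filtering drops early transient records", {
  rec <- make_record(resource = data.frame(t = c(500, 50000, 100000),
                                           B0 = c(100, 1, 3)))
  expect_equal(sd_resource(rec), sqrt(2))            # t = 500 excluded
  expect_gt(sd_resource(rec, burn_in = 0), 10)       # included on request
})

test_that("turnover is the Jaccard dissimilarity of consecutive snapshots", {
  expect_equal(set_turnover(1:3, 1:3), 0)
  expect_equal(set_turnover(1:3, 4:6), 1)
  expect_equal(set_turnover(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(set_turnover(integer(0), integer(0)), 0)
  # symmetry and the alternative normalisation
  expect_equal(set_turnover(1:4, 3:8), set_turnover(3:8, 1:4))
  expect_equal(set_turnover(c(1, 2, 3), c(2, 3, 4), method = "relative"), 2 / 3)
  # record-level mean over consecutive pairs
  snaps <- list(`50000` = 1:3, `60000` = c(2, 3, 4), `70000` = c(2, 3, 4))
  rec <- make_record(snapshots = snaps)
  expect_equal(turnover_series(rec), c(0.5, 0))
  expect_equal(mean_turnover(rec), 0.25)
})

test_that("viable-mutant feeding range summary applies all three filters", {
  led <- rbind(
    make_ledger(s = c(0.4, 0.4), lifespan = c(500, 500)),            # kept
    make_ledger(s = 0.9, lifespan = 500, origin = "invader"),        # origin
    make_ledger(s = 0.9, lifespan = 50),                             # lifespan
    make_ledger(s = 0.9, lifespan = 500, birth = 1000))              # burn-in
  led$id <- seq_len(nrow(led))
  out <- mutant_range_summary(led)
  expect_equal(out$mean, 0.4)
  expect_equal(out$median, 0.4)
  expect_equal(out$n, 2L)
  # invader-only ledgers have no qualifying rows
  inv <- make_ledger(s = c(0.4, 0.5), lifespan = c(500, 600),
                     origin = "invader")
  expect_error(mutant_range_summary(inv), "no qualifying")
  # mixed fixture equals a brute-force row scan
  set.seed(2)
  big <- make_ledger(s = runif(200, 0.3, 1), lifespan = sample(0:1000, 200, TRUE),
                     origin = sample(c("mutant", "invader"), 200, TRUE),
                     birth = sample(c(1000, 80000), 200, TRUE))
  big$id <- seq_len(nrow(big))
  keep <- big$origin == "mutant" & big$lifespan >= 100 & big$birth_time >= 50000
  if (any(keep)) {
    out2 <- mutant_range_summary(big)
    expect_equal(out2$mean, mean(big$s[keep]))
    expect_equal(out2$median, stats::median(big$s[keep]))
  }
})

test_that("realized feeding range counts prey at or above the relative threshold", {
  p <- fw_params()
  # focal consumer centered on one prey; second prey far away
  comm <- data.frame(id = 1:3, m = c(10, 100, 1e6), f = c(100, 1, 1),
                     s = c(0.4, 0.4, 0.4))
  focal <- comm[1, ]
  # prey at the center passes; basal (d=2) and the far species fail;
  # the focal's own mass sits at d=1 (ratio exp(-1/0.32) ~ 0.044): fails
  expect_equal(realized_range(focal, comm, p), 1 / 4)

  # a prey on the 0.1 locus is counted (threshold comparison is >=);
  # the locus prey sits a hair inside to keep the floating-point count exact
  d_star <- 0.4 * sqrt(2 * log(10))
  comm2 <- data.frame(id = 1:2, m = c(10^(2 + d_star * (1 - 1e-9)), 100),
                      f = c(1, 100), s = c(0.4, 0.4))
  focal2 <- comm2[2, ]   # f = 100, s = 0.4, feeding on its own mass class
  r <- attack_rate(focal2, comm2$m[1], p) / max_attack_rate(focal2, p)
  expect_equal(r, 0.1)
  expect_equal(realized_range(focal2, comm2, p), 2 / 3)  # locus prey + itself

  # random community: brute-force per-pair evaluation
  set.seed(3)
  sp <- rand_species_df(12, seed = 3)
  for (i in c(1, 5, 12)) {
    got <- realized_range(sp[i, ], sp, p)
    rel <- vapply(c(p$m0, sp$m), function(mj)
      attack_rate(sp[i, ], mj, p) / max_attack_rate(sp[i, ], p), numeric(1))
    expect_equal(got, mean(rel >= 0.1))
    # closed-form locus gives the same count
    d <- abs(log10(sp$f[i]) - log10(c(p$m0, sp$m)))
    expect_equal(got, mean(d <= sp$s[i] * sqrt(2 * log(10)) + 1e-12))
  }
})

test_that("lifespan slope recovers a noise-free generating coefficient", {
  set.seed(4)
  s <- runif(60, 0.3, 1.2)
  b <- 1.7
  lifespan <- exp(2 + b * log10(s))
  led <- make_ledger(s = s, lifespan = lifespan)
  expect_equal(lifespan_slope(led), b, tolerance = 1e-6)
  # constant feeding range is a degenerate design
  expect_error(lifespan_slope(make_ledger(s = rep(0.4, 20),
                                          lifespan = runif(20, 1, 2))),
               "constant")
  # censored species are excluded
  led_cen <- make_ledger(s = s, lifespan = lifespan, censored = TRUE)
  expect_error(lifespan_slope(led_cen), "at least 10")
})

test_that("lifespan slope is within 3 SE of truth under gamma noise", {
  set.seed(5)
  n <- 500
  s <- runif(n, 0.3, 1.2)
  b <- -0.8
  mu <- exp(5 + b * log10(s))
  shape <- 4
  lifespan <- stats::rgamma(n, shape = shape, rate = shape / mu)
  led <- make_ledger(s = s, lifespan = lifespan)
  fit <- glm_fit(lifespan, cbind(1, log10(s)), family = "gamma", link = "log")
  expect_lt(abs(lifespan_slope(led) - b), 3 * fit$se[2])
})

test_that("persistence bins split on the feeding-range cutoffs", {
  led <- make_ledger(s = c(0.30, 0.32, 0.35, 0.39, 0.50),
                     lifespan = c(100, 200, 999, 400, 600))
  out <- binned_persistence(led)
  expect_equal(out$specialist, 150)       # 0.30, 0.32; 0.35 excluded
  expect_equal(out$generalist, 500)       # 0.39, 0.50
  expect_equal(out$n_specialist, 2L)
  expect_equal(out$n_generalist, 2L)
  # empty bin is flagged
  led2 <- make_ledger(s = c(0.3, 0.31), lifespan = c(1, 2))
  expect_true(is.na(binned_persistence(led2)$generalist))
})

test_that("per-simulation metrics assemble into one labelled row", {
  rec <- scaled_run()
  m <- sim_metrics(rec)
  expect_equal(nrow(m), 1L)
  expect_equal(m$z, 5)
  expect_true(m$sd_resource >= 0)
  expect_true(m$mean_turnover >= 0 && m$mean_turnover <= 1)
  expect_true(m$mean_realized_range >= 0 && m$mean_realized_range <= 1)
})
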