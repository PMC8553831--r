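test_that("feeding kernel peaks at the feeding center with the normal-density height", {
  peak <- feeding_kernel(1, 0.4, 1)
  expect_equal(peak, 1 / (0.4 * sqrt(2 * pi)))
  expect_equal(peak, 0.99736, tolerance = 5e-6 / peak)

  # symmetric in log10 distance around the center
  for (d in c(0.1, 0.7, 2)) {
    expect_equal(feeding_kernel(100, 0.5, 10^(2 + d)),
                 feeding_kernel(100, 0.5, 10^(2 - d)))
  }
  # strictly positive, maximal at the center
  mj <- 10^seq(-2, 4, by = 0.25)
  v <- feeding_kernel(10, 0.6, mj)
  expect_true(all(v > 0))
  expect_equal(mj[which.max(v)], 10)
})

test_that("feeding kernel integrates to one over log10 mass", {
  sp <- rand_species_df(20, seed = 5)
  for (i in seq_len(nrow(sp))) {
    c0 <- log10(sp$f[i]); w <- 12 * sp$s[i]
    q <- stats::integrate(function(lg) feeding_kernel(sp$f[i], sp$s[i], 10^lg),
                          c0 - w, c0 + w, rel.tol = 1e-10)
    expect_equal(q$value, 1, tolerance = 1e-8)
  }
})

test_that("kernel and attack rate reject non-positive inputs", {
  expect_error(feeding_kernel(-1, 0.4, 1), "positive")
  expect_error(feeding_kernel(1, 0, 1), "positive")
  expect_error(feeding_kernel(1, 0.4, c(1, -2)), "positive")
  expect_error(handling_time(0), "positive")
})

test_that("attack rate is the allometric factor times the kernel", {
  anc <- fw_species(100, 1, 0.4)
  expect_equal(attack_rate(anc, 1), 100^0.75 * feeding_kernel(1, 0.4, 1))
  expect_equal(attack_rate(anc, 1), 31.54, tolerance = 2e-4)

  # unit body mass removes the allometric factor
  sp1 <- list(m = 1, f = 5, s = 0.5)
  expect_equal(attack_rate(sp1, 5), 1 / (0.5 * sqrt(2 * pi)))

  # doubling body mass at fixed kernel scales attack by 2^0.75
  sp2 <- list(m = 2, f = 5, s = 0.5)
  expect_equal(attack_rate(sp2, 3) / attack_rate(sp1, 3), 2^0.75)
})

test_that("maximum attack rate is the attack rate on an ideal central prey", {
  sp <- rand_species_df(10, seed = 9)
  for (i in seq_len(nrow(sp))) {
    expect_equal(max_attack_rate(sp[i, ]), attack_rate(sp[i, ], sp$f[i]))
  }
  anc <- fw_species(100, 1, 0.4)
  expect_equal(max_attack_rate(anc), 100^0.75 / (0.4 * sqrt(2 * pi)))
  # wider kernels have strictly lower peaks at fixed mass
  peaks <- vapply(c(0.3, 0.5, 1, 2), function(s)
    max_attack_rate(list(m = 10, f = 2, s = s)), numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("relative attack rate crosses 0.1 exactly at the closed-form locus", {
  for (s in c(0.3, 0.4, 1.1)) {
    sp <- list(m = 7, f = 10, s = s)
    d_star <- s * sqrt(2 * log(10))
    ratio <- attack_rate(sp, 10^(1 + d_star)) / max_attack_rate(sp)
    expect_equal(ratio, 0.1)
    expect_lt(attack_rate(sp, 10^(1 + d_star * 1.001)) / max_attack_rate(sp), 0.1)
    expect_gt(attack_rate(sp, 10^(1 + d_star * 0.999)) / max_attack_rate(sp), 0.1)
  }
})

test_that("allometric handling time and metabolic loss match their power laws", {
  p25 <- fw_params(h_exp = -0.25)
  expect_equal(handling_time(1, p25), 0.4)
  expect_equal(handling_time(16, p25), 0.2)   # 16^-0.25 = 0.5
  expect_equal(metabolic_loss(1), 0.3)
  expect_equal(metabolic_loss(16), 0.15)
  m <- c(1, 2, 8, 100, 1e4)
  expect_true(all(diff(handling_time(m)) < 0))
  expect_true(all(diff(metabolic_loss(m)) < 0))
})

test_that("consumption rate reduces correctly in limiting cases", {
  sp <- rand_species_df(3, seed = 2)
  st0 <- fw_state(t = 0, B0 = 0, species = sp, B = rep(0, 3))
  p <- fw_params()
  # empty prey field: denominator collapses to 1
  for (i in 1:3) {
    expect_equal(consumption_rate(sp[i, ], 0, st0, p),
                 attack_rate(sp[i, ], p$m0, p) / sp$m[i])
  }
  # saturation: one huge prey pool drives g toward 1/(m h)
  stBig <- fw_state(t = 0, B0 = 1e12, species = sp[1, , drop = FALSE], B = 0)
  g <- consumption_rate(sp[1, ], 0, stBig, p)
  expect_equal(g * 1e12, 1 / (sp$m[1] * handling_time(sp$m[1], p)),
               tolerance = 1e-6)
})

test_that("consumption rate matches independent scalar arithmetic", {
  # ancestor feeding on the basal resource at B0 = 2, evaluated with the
  # tabulated coefficient set (handling exponent -0.25)
  p <- fw_params(h_exp = -0.25)
  anc <- fw_species(100, 1, 0.4)
  st <- fw_state(t = 0, B0 = 2, species = anc, B = 0)
  a <- 100^0.75 * exp(0) / (0.4 * sqrt(2 * pi))
  a_self <- 100^0.75 * exp(-(log10(100))^2 / (2 * 0.16)) / (0.4 * sqrt(2 * pi))
  expected <- (1 / 100) * a / (1 + 0.4 * 100^-0.25 * (a * 2 + a_self * 0))
  expect_equal(consumption_rate(anc, 0, st, p), expected)

  # and with the default mass-independent ingestion/metabolism scaling
  pd <- fw_params()
  expected_d <- (1 / 100) * a / (1 + 0.4 * 100^-0.75 * a * 2)
  expect_equal(consumption_rate(anc, 0, st, pd), expected_d)
})

test_that("competition overlap closed form agrees with adaptive quadrature", {
  sp <- rand_species_df(20, seed = 11)
  set.seed(99)
  pairs <- cbind(sample(20, 100, TRUE), sample(20, 100, TRUE))
  for (k in seq_len(nrow(pairs))) {
    i <- sp[pairs[k, 1], ]; j <- sp[pairs[k, 2], ]
    closed <- competition_overlap(i, j)
    lo <- min(log10(i$f) - 12 * i$s, log10(j$f) - 12 * j$s)
    hi <- max(log10(i$f) + 12 * i$s, log10(j$f) + 12 * j$s)
    quad <- stats::integrate(function(lg)
      feeding_kernel(i$f, i$s, 10^lg) * feeding_kernel(j$f, j$s, 10^lg),
      lo, hi, rel.tol = 1e-12)$value
    expect_equal(closed, quad, tolerance = 1e-8)
  }
})

test_that("competition overlap has the correct self-value, symmetry and tails", {
  a <- fw_species(100, 1, 0.4)
  expect_equal(competition_overlap(a, a), 1 / (2 * 0.4 * sqrt(pi)))
  expect_equal(competition_overlap(a, a), 0.7052, tolerance = 1e-4)
  b <- list(m = 5, f = 30, s = 0.7)
  expect_equal(competition_overlap(a, b), competition_overlap(b, a))
  far <- list(m = 5, f = 1e12, s = 0.7)
  expect_lt(competition_overlap(a, far), 1e-40)
})

test_that("competition coefficient normalises overlap by the focal self-overlap", {
  p <- fw_params()
  a <- fw_species(10, 2, 0.5, id = 1)
  twin <- fw_species(99, 2, 0.5, id = 2)  # identical kernel, different mass
  expect_equal(competition_coefficient(a, twin, p), p$c0)

  i <- fw_species(10, 2, 0.3, id = 1)
  j <- fw_species(10, 2, 0.6, id = 2)
  expected <- 0.05 * (1 / sqrt(2 * pi * (0.09 + 0.36))) / (1 / (2 * 0.3 * sqrt(pi)))
  expect_equal(competition_coefficient(i, j, p), expected)
  # asymmetric: each focal species normalises by its own self-overlap
  expect_false(isTRUE(all.equal(competition_coefficient(i, j, p),
                                competition_coefficient(j, i, p))))
  # no intraspecific interference term
  expect_error(competition_coefficient(i, i, p), "distinct")
})

test_that("species and state constructors enforce their invariants", {
  expect_error(fw_species(0.5, 1, 0.4), "m0")
  expect_error(fw_species(10, -1, 0.4), "positive")
  expect_error(fw_species(10, 1, 0.2), "s_floor")
  expect_error(fw_state(B0 = -1), "non-negative")
  sp <- rand_species_df(3)
  expect_error(fw_state(B0 = 1, species = sp, B = c(1, 2)), "lengths")
  expect_error(fw_state(B0 = 1, species = sp, B = c(1, 2, -1)), "non-negative")
})
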