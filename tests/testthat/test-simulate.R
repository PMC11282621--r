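test_that("configuration rejects invalid parameter combinations", {
  expect_error(dispersal_config(bottleneck_size = 0), "bottleneck_size")
  expect_error(dispersal_config(missing_rate = 1), "missing_rate")
  expect_error(dispersal_config(n_populations = 3,
                                founder_steps = c(2L, 1L, 3L)),
               "is.unsorted")
  expect_error(dispersal_config(origin_freq = c(0.9, 0.1)), "frequency law")
})

test_that("the same seed reproduces the simulation exactly", {
  cfg <- dispersal_config(n_populations = 4, n_loci = 100, sample_n = 10,
                          seed = 5)
  s1 <- simulate_dispersal(cfg)
  s2 <- simulate_dispersal(cfg)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$freqs, s2$freqs)
  expect_identical(s1$breeds, s2$breeds)
})

test_that("zero founder steps leave all populations at origin frequencies", {
  cfg <- dispersal_config(n_populations = 4, founder_steps = rep(0L, 4),
                          n_loci = 600, sample_n = 40, missing_rate = 0,
                          seed = 8)
  sim <- simulate_dispersal(cfg)
  expect_true(all(sim$freqs == sim$freqs[, 1]))
  g <- sim$genotypes
  th <- pairwise_fst(g$calls[g$ind$breed_id == "POP01", ],
                     g$calls[g$ind$breed_id == "POP04", ])$theta
  expect_lt(abs(th), 0.02)
})

test_that("a single founder step through Nb = 1 lands on {0, 1/2, 1}", {
  cfg <- dispersal_config(n_populations = 2, founder_steps = c(0L, 1L),
                          bottleneck_size = 1, n_loci = 200, sample_n = 2,
                          seed = 10)
  sim <- simulate_dispersal(cfg)
  expect_true(all(sim$freqs[, 2] %in% c(0, 0.5, 1)))
})

test_that("route coordinates recede from the origin with route position", {
  cfg <- dispersal_config(n_populations = 6, n_loci = 10, sample_n = 2,
                          seed = 12)
  sim <- simulate_dispersal(cfg)
  b <- distances_to_origin(sim$breeds, cfg$origin)
  expect_true(all(diff(b$distance_km) > 0))
  expect_equal(b$distance_km[1], 0)
  expect_equal(diff(b$distance_km), rep(500, 5), tolerance = 1e-6)
})

test_that("closed-form heterozygosity decay matches its pieces", {
  # steps = 0: just the origin-law expectation, checked against quadrature
  e0 <- expected_he_decay(c(0.05, 0.95), 25, 0)
  quad <- integrate(function(p) 2 * p * (1 - p) / 0.9, 0.05, 0.95)$value
  expect_equal(e0, quad, tolerance = 1e-8)
  # one step through Nb = 1 halves heterozygosity
  expect_equal(expected_he_decay(c(0.05, 0.95), 1, 1), e0 / 2)
  expect_equal(expected_he_decay(c(0.2, 0.2), 10, 0), 2 * 0.2 * 0.8)
  expect_equal(expected_he_decay(c(0.05, 0.95), 25, 0:3),
               e0 * (1 - 1 / 50)^(0:3))
})

test_that("measured He tracks the closed-form decay within Monte Carlo error", {
  n_rep <- 30
  cfg0 <- dispersal_config(n_populations = 6, founder_steps = c(0L, 2L, 4L,
                                                                6L, 8L, 10L),
                           n_loci = 500, sample_n = 30, seed = 1)
  he <- matrix(NA_real_, n_rep, 6)
  for (r in seq_len(n_rep)) {
    cfg <- cfg0; cfg$seed <- 1000L + r
    sim <- simulate_dispersal(cfg)
    g <- sim$genotypes
    he[r, ] <- vapply(sprintf("POP%02d", 1:6), function(b)
      expected_heterozygosity(g$calls[g$ind$breed_id == b, ]), numeric(1))
  }
  expect_he <- expected_he_decay(cfg0$origin_freq, cfg0$bottleneck_size,
                                 cfg0$founder_steps)
  se <- apply(he, 2, sd) / sqrt(n_rep)
  expect_true(all(abs(colMeans(he) - expect_he) < 3 * se),
              label = "per-step He within 3 MC standard errors")
})

test_that("He decreases along the route in nearly all replicates", {
  neg <- 0
  for (r in 1:100) {
    cfg <- dispersal_config(n_populations = 10,
                            founder_steps = 0:9, n_loci = 300,
                            sample_n = 20, seed = 4000L + r)
    sim <- simulate_dispersal(cfg)
    g <- sim$genotypes
    he <- vapply(sprintf("POP%02d", 1:10), function(b)
      expected_heterozygosity(g$calls[g$ind$breed_id == b, ]), numeric(1))
    rho <- cor(he, 1:10, method = "spearman")
    neg <- neg + (rho < 0)
  }
  expect_gte(neg, 95)
})

test_that("differentiation from the origin grows with founder steps", {
  ths <- matrix(NA_real_, 15, 3)
  for (r in 1:15) {
    cfg <- dispersal_config(n_populations = 4, founder_steps = c(0L, 1L, 5L,
                                                                 11L),
                            n_loci = 500, sample_n = 25, missing_rate = 0,
                            seed = 7000L + r)
    sim <- simulate_dispersal(cfg)
    g <- sim$genotypes
    origin <- g$calls[g$ind$breed_id == "POP01", ]
    ths[r, ] <- vapply(sprintf("POP%02d", 2:4), function(b)
      pairwise_fst(g$calls[g$ind$breed_id == b, ], origin)$theta, numeric(1))
  }
  expect_true(all(diff(colMeans(ths)) > 0))
})

test_that("migration between neighbours weakens the cline", {
  base <- run_dispersal_pipeline(
    dispersal_config(n_loci = 600, seed = 42), qc = NULL)
  mixed <- run_dispersal_pipeline(
    dispersal_config(n_loci = 600, migration_rate = 0.5, seed = 42),
    qc = NULL)
  expect_lt(base$he_cline$r, -0.9)
  # neighbour gene flow replenishes downstream diversity: shallower decay
  expect_lt(abs(mixed$he_cline$slope), abs(base$he_cline$slope))
})
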