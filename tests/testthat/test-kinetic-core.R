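test_that("initial state partitions chain pools by the distribution", {
  spec <- model_spec("DAR8", "detailed")
  cond <- run_condition(1.5, 3, mab_molar_mass = 148000)
  dist <- adc2_distribution()
  st <- initial_state(cond, dist, spec)
  cm <- 1.5 / 148000 * 1000  # 0.010135 mmol/L
  expect_equal(unname(st$species["L0.0c"]), 0.04 * 2 * cm, tolerance = 1e-12)
  expect_equal(unname(st$species["L0.1c"]), 0.96 * 2 * cm, tolerance = 1e-12)
  expect_equal(sum(st$species[startsWith(names(st$species), "H")]), 2 * cm)
  # batch: payload present at t = 0 at the molar excess
  expect_equal(st$free_drug, 3 * cm)
  expect_equal(st$volume, cond$initial_volume)
  # degenerate distribution: the whole heavy pool sits in one species
  st2 <- initial_state(cond, single_site_dar2(), model_spec("DAR2", "simple"))
  expect_equal(unname(st2$species["H0.1c"]), 2 * cm)
  expect_equal(sum(st2$species[startsWith(names(st2$species), "H")]), 2 * cm)
  # fed-batch: no payload at t = 0
  condf <- run_condition(1.5, 3, "fedbatch", feed_duration = 600)
  expect_equal(initial_state(condf, dist, spec)$free_drug, 0)
  # modality mismatch is an error
  expect_error(initial_state(cond, adc1_distribution(), spec), "match")
})

test_that("the RHS reproduces the detailed DAR2 rate equations", {
  spec <- model_spec("DAR2", "detailed")
  cond <- run_condition(3, 3)
  rates <- rate_set(c(0.3, 1.7), k_drug = 0.002)
  st <- initial_state(cond, adc1_distribution(), spec)
  # put mass into intermediate species to exercise every term
  st$species["H1.1c"] <- 0.004
  st$species["H1.2c"] <- 0.003
  st$species["H2.2c"] <- 0.001
  d <- conjugation_rhs(st, 0, rates, cond, spec)
  k1 <- 0.3; k2 <- 1.7; cd <- st$free_drug
  s <- st$species
  expect_equal(unname(d$species["H0.2c"]), -k1 * s[["H0.2c"]] * cd)
  expect_equal(unname(d$species["H0.1c"]), -k1 * s[["H0.1c"]] * cd)
  expect_equal(unname(d$species["H0.0c"]), 0)
  expect_equal(unname(d$species["H1.2c"]),
               k1 * s[["H0.2c"]] * cd - k2 * s[["H1.2c"]] * cd)
  # H1 from single-site chains is formation-only
  expect_equal(unname(d$species["H1.1c"]), k1 * s[["H0.1c"]] * cd)
  expect_equal(unname(d$species["H2.2c"]), k2 * s[["H1.2c"]] * cd)
  expect_equal(d$free_drug,
               -cd * (k1 * s[["H0.2c"]] + k1 * s[["H0.1c"]] +
                      k2 * s[["H1.2c"]]) - 0.002 * cd)
  expect_equal(d$volume, 0)
  # no payload, no fluxes
  st$free_drug <- 0
  d0 <- conjugation_rhs(st, 0, rates, cond, spec)
  expect_true(all(d0$species == 0))
  expect_equal(d0$free_drug, 0)
})

test_that("single-step kinetics match the closed-form second-order solution", {
  spec <- model_spec("DAR2", "simple")
  cond <- run_condition(3, 3, sample_times = c(30, 60, 120, 300, 600, 1800),
                        t_end = 1800, sample_volume = 0)
  k <- 0.251
  sim <- simulate_conjugation(spec, rate_set(k, 0), cond, single_site_dar2())
  cm <- mab_molar_conc(cond)
  expected <- analytic_second_order(A0 = 2 * cm, B0 = 3 * cm, k = k,
                                    t = sim$times)
  expect_equal(sim$observed[, "H0"], expected,
               tolerance = 1e-3, ignore_attr = TRUE)
  # < 0.1% relative where the pool is not yet exhausted
  idx <- expected > 1e-5
  expect_lt(max(abs(sim$observed[idx, "H0"] / expected[idx] - 1)), 1e-3)
})

test_that("batch trajectories conserve chains and payload", {
  spec <- model_spec("DAR8", "detailed")
  cond <- run_condition(1.5, 9, sample_times = numeric(0), t_end = 1800)
  sim <- simulate_conjugation(spec, rate_set(table2_dar8_rates, 0), cond,
                              adc2_distribution(), dense_n = 400)
  # every (chain, nc) group is closed under conjugation
  gt <- group_totals(sim)
  rel_drift <- apply(gt, 2, function(col) {
    if (max(col) < 1e-12) return(0)
    diff(range(col)) / max(col)
  })
  expect_lt(max(rel_drift), 1e-6)
  # payload: free + bound constant when k_drug = 0
  total <- sim$free_drug + bound_drug(sim)
  expect_lt(diff(range(total)) / total[1], 1e-6)
})

test_that("payload depletion deficit equals the integrated first-order loss", {
  spec <- model_spec("DAR2", "simple")
  cond <- run_condition(3, 3, sample_times = numeric(0), t_end = 1800)
  kd <- 0.002
  sim <- simulate_conjugation(spec, rate_set(0.251, kd), cond,
                              adc1_distribution(), dense_n = 2000)
  total <- sim$free_drug + bound_drug(sim)
  deficit <- total[1] - total
  # quadrature of k_drug * c_drug on the dense grid
  integ <- cumsum(c(0, diff(sim$times) *
                      (utils::head(sim$free_drug, -1) +
                       utils::tail(sim$free_drug, -1)) / 2)) * kd
  expect_equal(deficit, integ, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("the detailed model with equal rates reproduces the simple model", {
  cond <- run_condition(1.5, 11, sample_times = c(60, 300, 900), t_end = 900)
  dist <- adc2_distribution()
  k <- 1.7
  simS <- simulate_conjugation(model_spec("DAR8", "simple"), rate_set(k, 0.001),
                               cond, dist, dense_n = 50)
  simD <- simulate_conjugation(model_spec("DAR8", "detailed"),
                               rate_set(rep(k, 4), 0.001), cond, dist,
                               dense_n = 50)
  expect_equal(simD$observed, simS$observed, tolerance = 1e-8)
})

test_that("a near-instant feed converges to the instant-addition batch run", {
  dist <- adc1_distribution()
  spec <- model_spec("DAR2", "simple")
  rates <- rate_set(0.251, 0)
  ts <- c(300, 900, 1800)
  fed <- run_condition(1.5, 3, "fedbatch", feed_duration = 1,
                       initial_volume = 1, feed_volume = 0.1,
                       sample_times = ts, t_end = 1800, sample_volume = 0)
  # batch comparator: same mixture after instantaneous addition
  bat <- run_condition(1.5 / 1.1, 3, "batch", initial_volume = 1.1,
                       sample_times = ts, t_end = 1800, sample_volume = 0)
  simF <- simulate_conjugation(spec, rates, fed, dist, dense_n = 0)
  simB <- simulate_conjugation(spec, rates, bat, dist, dense_n = 0)
  scale <- max(simB$observation$observed)
  expect_lt(max(abs(simF$observation$observed - simB$observation$observed)) /
              scale, 1e-3)
})

test_that("total payload fed equals the molar-excess target", {
  cond <- run_condition(1.5, 11, "fedbatch", feed_duration = 600,
                        initial_volume = 4, feed_volume = 0.4,
                        sample_times = numeric(0), t_end = 1200)
  feed_moles <- cond$drug_excess * mab_molar_conc(cond) * cond$initial_volume
  sim <- simulate_conjugation(model_spec("DAR8", "detailed"),
                              rate_set(table2_dar8_rates, 0), cond,
                              adc2_distribution(), dense_n = 200)
  # with no depletion, free + bound payload moles equal the fed amount
  n_end <- length(sim$times)
  in_reactor <- (sim$free_drug[n_end] + bound_drug(sim)[n_end]) *
    sim$volume[n_end]
  expect_equal(in_reactor, feed_moles, tolerance = 1e-6)
  # and the feed composition hits the target exactly by construction
  expect_equal(adckinetics:::.feed_params(cond)$c_in * cond$feed_volume,
               feed_moles, tolerance = 1e-12)
})

test_that("with large payload excess H0 decays pseudo-first-order", {
  cond <- run_condition(1.5, 400, sample_times = c(0.5, 1, 2), t_end = 2,
                        sample_volume = 0)
  k <- 0.251
  sim <- simulate_conjugation(model_spec("DAR2", "simple"), rate_set(k, 0),
                              cond, single_site_dar2(), dense_n = 0)
  cm <- mab_molar_conc(cond)
  expected <- 2 * cm * exp(-k * 400 * cm * sim$observation$times)
  expect_lt(max(abs(sim$observation$observed[, "H0"] / expected - 1)), 0.01)
})

test_that("DAR and conjugation tails are monotone; zero excess is inert", {
  cond <- run_condition(1.5, 11, sample_times = numeric(0), t_end = 600)
  sim <- simulate_conjugation(model_spec("DAR8", "detailed"),
                              rate_set(table2_dar8_rates, 0.041 / 60), cond,
                              adc2_distribution(), dense_n = 300)
  dar <- dar_trajectory(sim)
  expect_true(all(diff(dar) > -1e-9))
  # cumulative tails sum_{d' >= d} obs(chain, d') never decrease
  for (d in 1:4) {
    tail_h <- rowSums(sim$observed[, paste0("H", d:4), drop = FALSE])
    expect_true(all(diff(tail_h) > -1e-9), info = paste("tail H", d))
  }
  # no payload, no change
  cond0 <- run_condition(1.5, 0, sample_times = c(60, 600), t_end = 600)
  sim0 <- simulate_conjugation(model_spec("DAR8", "detailed"),
                               rate_set(table2_dar8_rates, 0), cond0,
                               adc2_distribution(), dense_n = 20)
  expect_lt(max(abs(sweep(sim0$observed, 2, sim0$observed[1, ]))), 1e-12)
})

test_that("observable collapse sums hidden species and preserves chain totals", {
  spec <- model_spec("DAR2", "detailed")
  struct <- adckinetics:::model_structure(spec)
  hidden <- matrix(0, nrow = 1, ncol = struct$n_species,
                   dimnames = list(NULL, struct$tab$name))
  hidden[, "H1.1c"] <- 0.2
  hidden[, "H1.2c"] <- 0.1
  obs <- collapse_observables(hidden, spec)
  expect_equal(obs[1, "H1"], 0.3, ignore_attr = TRUE)
  expect_equal(collapse_observables(hidden * 0, spec)[1, ],
               stats::setNames(rep(0, 5), c("H0", "H1", "H2", "L0", "L1")))
  # random state: chain totals preserved
  set.seed(11)
  hidden[1, ] <- stats::runif(struct$n_species)
  obs <- collapse_observables(hidden, spec)
  expect_equal(sum(obs[1, startsWith(colnames(obs), "H")]),
               sum(hidden[1, startsWith(colnames(hidden), "H")]))
})

test_that("DAR evaluates stoichiometry of observations", {
  # fully unconjugated
  cond <- run_condition(1.5, 0)
  cm <- mab_molar_conc(cond)
  obs0 <- matrix(c(2 * cm, 0, 0, 0, 0, 2 * cm, 0), nrow = 1,
                 dimnames = list(NULL, c(paste0("H", 0:4), "L0", "L1")))
  expect_equal(compute_dar(kinetic_observation(0, obs0, cond), 0), 0)
  # both light chains singly conjugated, heavy untouched
  obs1 <- obs0; obs1[, "L0"] <- 0; obs1[, "L1"] <- 2 * cm
  expect_equal(compute_dar(kinetic_observation(0, obs1, cond), 0), 2)
  # saturating conjugation of the DAR8 distribution reaches the
  # stoichiometric DAR (~7.8 payloads per mAb)
  dist <- adc2_distribution()
  cond <- run_condition(1.5, 12, sample_times = numeric(0), t_end = 3600)
  sim <- simulate_conjugation(model_spec("DAR8", "detailed"),
                              rate_set(table2_dar8_rates, 0), cond, dist,
                              dense_n = 100)
  expect_equal(compute_dar(sim), sites_per_mab(dist), tolerance = 1e-4)
  # zero mAb is an error
  zero <- obs0 * 0
  expect_error(compute_dar(kinetic_observation(0, zero, cond), 0), "zero mAb")
})
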