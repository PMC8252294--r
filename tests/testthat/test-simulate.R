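test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_planted = 90, n_features = 80), "n_planted")
  expect_error(sim_config(presence_resistant = 1.2), "Probabilities")
  expect_error(sim_config(presence_resistant = 0.1,
                          presence_susceptible = 0.5), "exceed")
  expect_error(sim_config(baseline_daily_hazard = -0.1), "non-negative")
})

test_that("degenerate presence probabilities pin planted features to resistant accessions", {
  cfg <- sim_config(presence_resistant = 1, presence_susceptible = 0,
                    presence_background = 0, n_features = 10, n_planted = 3,
                    seed = 5)
  sim <- simulate_feature_table(cfg)
  truth <- sim$truth
  long <- sim$table$long
  resistant <- truth$accessions$accession[truth$accessions$class == "resistant"]
  planted <- long$feature_id %in% truth$planted_features
  in_resistant <- long$accession %in% resistant
  expect_true(all(long$abundance[planted & in_resistant] > 0))
  expect_true(all(long$abundance[!(planted & in_resistant)] == 0))
})

test_that("a fixed seed reproduces every generator bit-identically", {
  cfg <- sim_config(seed = 7)
  expect_identical(simulate_feature_table(cfg), simulate_feature_table(cfg))
  expect_identical(simulate_whitefly_assay(cfg), simulate_whitefly_assay(cfg))
  expect_identical(simulate_thrips_assay(cfg), simulate_thrips_assay(cfg))
})

test_that("presence fractions match the configured probabilities within binomial error", {
  # background features only; presence decided per accession x feature
  cfg <- sim_config(n_accessions = 20, n_resistant = 8, n_features = 200,
                    n_planted = 0, presence_background = 0.5,
                    n_replicates = 3, seed = 13)
  sim <- simulate_feature_table(cfg)
  present <- feature_matrix(sim$table) > 0
  frac <- mean(present)
  se <- sqrt(0.5 * 0.5 / length(present))
  expect_lt(abs(frac - 0.5), 3 * se)

  # planted features follow the class-specific probabilities
  cfg2 <- sim_config(n_accessions = 60, n_resistant = 30, n_features = 40,
                     n_planted = 40, presence_resistant = 0.9,
                     presence_susceptible = 0.1, n_replicates = 2, seed = 17)
  sim2 <- simulate_feature_table(cfg2)
  m <- feature_matrix(sim2$table) > 0
  cls <- sim2$truth$accessions$class[match(rownames(m),
                                           sim2$truth$accessions$accession)]
  fr_r <- mean(m[cls == "resistant", ])
  fr_s <- mean(m[cls == "susceptible", ])
  expect_lt(abs(fr_r - 0.9), 3 * sqrt(0.9 * 0.1 / sum(cls == "resistant") / 40))
  expect_lt(abs(fr_s - 0.1), 3 * sqrt(0.9 * 0.1 / sum(cls == "susceptible") / 40))
})

test_that("whitefly cage counts follow the true survival probabilities", {
  # the most resistant accession is generated with zero survival
  cfg <- sim_config(seed = 3)
  wf <- simulate_whitefly_assay(cfg)
  truth <- accession_truth(cfg)
  zero_acc <- truth$accession[truth$surv_prob == 0]
  expect_gt(length(zero_acc), 0)
  expect_true(all(wf$n_alive[wf$accession %in% zero_acc] == 0))
  expect_true(all(wf$n_alive + wf$n_dead == cfg$cage_size))

  # p = 1: every insect survives
  cfg1 <- sim_config(n_accessions = 2, n_resistant = 1,
                     surv_susceptible = 1, seed = 4)
  wf1 <- simulate_whitefly_assay(cfg1)
  base <- baseline_accession(cfg1)
  expect_true(all(wf1$n_dead[wf1$accession == base] == 0))

  # p = 0.5 over 1000 cages of 15: binomial oracle
  cfg5 <- sim_config(n_accessions = 2, n_resistant = 1,
                     surv_susceptible = 0.5, plants_per_accession = 500,
                     seed = 9)
  wf5 <- simulate_whitefly_assay(cfg5)
  base5 <- baseline_accession(cfg5)
  alive <- wf5$n_alive[wf5$accession == base5]
  frac <- sum(alive) / (length(alive) * cfg5$cage_size)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / (length(alive) * cfg5$cage_size)))
})

test_that("thrips event times are daily-rounded exponentials with censoring", {
  # extreme hazard: everyone dies on day one
  cfg_hi <- sim_config(baseline_daily_hazard = 50, log_hr_resistant = 0.1,
                       seed = 2)
  th_hi <- simulate_thrips_assay(cfg_hi)
  expect_true(all(th_hi$day == 1 & th_hi$status == 1))

  # zero hazard: fully censored at the horizon
  cfg0 <- sim_config(baseline_daily_hazard = 0, seed = 2)
  th0 <- simulate_thrips_assay(cfg0)
  expect_true(all(th0$day == cfg0$followup_days & th0$status == 0))

  # rate 0.2/day: empirical median day equals ceil(ln 2 / 0.2) = 4
  cfg <- sim_config(n_accessions = 2, n_resistant = 1,
                    baseline_daily_hazard = 0.2,
                    larvae_per_accession = 5000, seed = 21)
  th <- simulate_thrips_assay(cfg)
  base <- baseline_accession(cfg)
  expect_equal(median(th$day[th$accession == base]), 4)

  # structural invariants
  expect_true(all(th$day >= 1 & th$day <= cfg$followup_days))
  expect_true(all(th$day == as.integer(th$day)))
  expect_true(all(th$status[th$day < cfg$followup_days] == 1))
  censored <- th[th$status == 0, ]
  expect_true(all(censored$day == cfg$followup_days))
})

test_that("abundances are non-negative and truth is internally consistent", {
  cfg <- sim_config(seed = 31)
  sim <- simulate_feature_table(cfg)
  expect_true(all(sim$table$long$abundance >= 0))
  expect_true(all(sim$truth$planted_features %in%
                    sim$table$long$feature_id))
  expect_equal(sum(sim$truth$accessions$class == "resistant"),
               cfg$n_resistant)
})
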