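test_that("relative survival rescales to the maximum and is scale-invariant", {
  d <- tibble::tibble(accession = c("a", "b", "c"),
                      score = c(0.22, 0.44, 0.88))
  rs <- relative_survival(d, score)
  expect_equal(rs$relative_survival, c(25, 50, 100))

  d10 <- dplyr::mutate(d, score = score * 10)
  expect_equal(relative_survival(d10, score)$relative_survival,
               rs$relative_survival)

  expect_error(relative_survival(dplyr::mutate(d, score = 0), score),
               "undefined")
})

test_that("trichome densities aggregate disc -> plant -> surface rule -> accession", {
  rec <- tibble::tibble(
    accession = "a", plant_id = "p1",
    leaf_disc_id = c("d1", "d2", "d3", "d4"),
    surface = rep(c("abaxial", "adaxial"), each = 2),
    trichome_type = "I/IV",
    density = c(10, 10, 2, 2)
  )
  expect_equal(aggregate_density(rec, "whitefly")$density, 6)
  expect_equal(aggregate_density(rec, "thrips")$density, 2)

  # disc means within a surface: discs 4 and 6 -> 5
  rec2 <- rec
  rec2$density <- c(4, 6, 4, 6)
  expect_equal(aggregate_density(rec2, "thrips")$density, 5)

  # nested two plants x two discs, hand-computed accession mean
  rec3 <- tibble::tibble(
    accession = "a",
    plant_id = rep(c("p1", "p2"), each = 4),
    leaf_disc_id = paste0("d", 1:8),
    surface = rep(rep(c("abaxial", "adaxial"), each = 2), 2),
    trichome_type = "VI",
    density = c(2, 4, 6, 8, 10, 12, 14, 16)
  )
  # p1: ab 3, ad 7 -> 5; p2: ab 11, ad 15 -> 13; accession: 9
  expect_equal(aggregate_density(rec3, "whitefly")$density, 9)
  # thrips: p1 ad 7, p2 ad 15 -> 11
  expect_equal(aggregate_density(rec3, "thrips")$density, 11)

  missing_surface <- dplyr::filter(rec, surface == "adaxial")
  expect_error(aggregate_density(missing_surface, "whitefly"),
               "both leaf surfaces")
})

test_that("linear fits agree with the closed-form normal equations", {
  exact <- tibble::tibble(x = 1:5, y = 2 * (1:5))
  f <- linear_fit(exact, x, y)
  expect_equal(f$r_squared, 1)
  expect_equal(f$slope, 2)

  set.seed(19)
  for (i in 1:5) {
    d <- tibble::tibble(x = rnorm(8), y = rnorm(8))
    f <- linear_fit(d, x, y)
    slope_o <- cov(d$x, d$y) / var(d$x)
    inter_o <- mean(d$y) - slope_o * mean(d$x)
    r2_o <- cor(d$x, d$y)^2
    expect_equal(f$slope, slope_o, tolerance = 1e-10)
    expect_equal(f$intercept, inter_o, tolerance = 1e-10)
    expect_equal(f$r_squared, r2_o, tolerance = 1e-10)
    expect_equal(f$n, 8)
  }

  set.seed(20)
  big <- tibble::tibble(x = rnorm(500), y = rnorm(500))
  expect_lt(linear_fit(big, x, y)$r_squared, 0.05)

  expect_error(linear_fit(tibble::tibble(x = c(1, 1, 1), y = 1:3), x, y),
               "zero variance")
  expect_error(linear_fit(exact[1:2, ], x, y), "three")
})

test_that("complete-linkage clustering merges by maximal distance, deterministically", {
  # identical features merge first at height 0
  m <- tibble::tibble(accession = c("a1", "a2"),
                      f1 = c(1, 5), f2 = c(1, 5), f3 = c(9, 0))
  cl <- cluster_features(m, transform = "raw")
  expect_equal(min(cl$heights), 0)

  # pairwise distances 1, 2, 3 -> complete-linkage merge heights (1, 3)
  # points on a line: A = 0, B = 1, C = 3 (one accession dimension)
  m2 <- tibble::tibble(accession = "a1", A = 0, B = 1, C = 3)
  # need >= 2 accessions for a meaningful matrix; pad with zeros
  m2 <- dplyr::bind_rows(m2, tibble::tibble(accession = "a2",
                                            A = 0, B = 0, C = 0))
  # use distances from the first accession only by making row 2 constant;
  # pairwise distances: AB = 1, AC = 3, BC = 2 -> heights (1, 3)
  cl2 <- cluster_features(m2, transform = "raw")
  expect_equal(cl2$heights, c(1, 3))

  # merge heights never decrease
  set.seed(77)
  m3 <- matrix(rlnorm(6 * 15, 4, 2), 6, 15,
               dimnames = list(sprintf("a%d", 1:6), sprintf("f%02d", 1:15)))
  cl3 <- cluster_features(m3)
  expect_true(all(diff(cl3$heights) >= 0))

  # identical inputs produce identical orderings
  expect_identical(tidy(cluster_features(m3)), tidy(cluster_features(m3)))
})

test_that("reports list selected features with log10-scale summaries", {
  cfg <- sim_config(n_features = 12, seed = 91)
  sim <- simulate_feature_table(cfg)
  labels <- sim$truth$accessions
  sel <- rf_select(sim$table, labels,
                   selection_config(n_trees = 150, n_repeats = 2,
                                    n_permutations = 60, alpha = 0.05,
                                    seed = 91))
  rep <- render_reports(sel, sim$table, labels)
  expect_true(all(sim$truth$planted_features %in% rep$selected$feature))
  panel <- rep$abundance_panel
  expect_true(all(c("log10_mean", "log10_se", "class") %in% names(panel)))
  one <- panel[panel$mean_abundance > 0, ][1, ]
  expect_equal(one$log10_mean, log10(one$mean_abundance))
  expect_equal(one$log10_se,
               one$se_abundance / (one$mean_abundance * log(10)))
  expect_equal(nrow(rep$heatmap), 12 * cfg$n_accessions)

  # empty selection: explicit message, no panel
  null_sel <- sel
  null_sel$result$selected <- FALSE
  expect_message(rep0 <- render_reports(null_sel, sim$table),
                 "No significant features")
  expect_null(rep0$abundance_panel)
  expect_equal(nrow(rep0$selected), 0)
})

test_that("the full synthetic pipeline recovers planted features as top hits", {
  out <- run_pipeline(sim_config(n_features = 15, seed = 14),
                      selection_config(n_trees = 150, n_repeats = 2,
                                       n_permutations = 60, alpha = 0.05,
                                       seed = 14))
  expect_s3_class(out$selection, "rf_selection")
  planted <- out$truth$planted_features
  td <- tidy(out$selection)
  top2 <- td$feature[order(-td$mean_importance)][1:2]
  expect_setequal(top2, planted)
  expect_true(all(out$recovery$selected[out$recovery$planted]))
})
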