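test_that("abundance normalisation applies IS, dilution and weight corrections", {
  expect_equal(normalize_abundance(500, 500), 1)
  expect_equal(normalize_abundance(0, 500, 2, 0.1), 0)
  expect_equal(normalize_abundance(2000, 500, 2, 0.1), 80)
  expect_equal(normalize_abundance(2000, 500, 2, 0.1,
                                   dilution_action = "divide"), 20)
  expect_error(normalize_abundance(10, 0), "positive")
  expect_error(normalize_abundance(10, 5, fresh_weight = 0), "positive")
})

test_that("acylsugar labels map to CHO formulas by ester stoichiometry", {
  f <- label_to_formula("S3:15")
  expect_equal(c(f$n_c, f$n_h, f$n_o, f$dbe), c(27, 46, 14, 5))
  g <- label_to_formula("G0:0")
  expect_equal(c(g$n_c, g$n_h, g$n_o), c(6, 12, 6))
  g2 <- label_to_formula("G2:10")
  expect_equal(c(g2$n_c, g2$n_h, g2$n_o, g2$dbe), c(16, 28, 8, 3))
  expect_error(label_to_formula("S3:5"), "N >= 2k")
  expect_error(label_to_formula("X3:15"), "valid acylsugar")
  expect_equal(parse_acylsugar("S3:21-2")$isomer, 2L)
})

test_that("formulas invert to labels, rejecting non-acylsugar stoichiometry", {
  expect_equal(formula_to_label(27, 46, 14)$label, "S3:15")
  expect_equal(formula_to_label(6, 12, 6, dbe_range = c(0, 10))$label, "G0:0")
  rej <- formula_to_label(10, 16, 0) # a monoterpene
  expect_true(is.na(rej$label))
  expect_match(rej$reason, "not a saturated acylsugar")
})

test_that("label -> formula -> label round-trips exhaustively with no S/G ambiguity", {
  grid <- expand.grid(backbone = c("S", "G"), k = 0:6, N = 0:40,
                      stringsAsFactors = FALSE)
  grid <- grid[(grid$k == 0 & grid$N == 0) |
                 (grid$k > 0 & grid$N >= 2 * grid$k), ]
  labels <- sprintf("%s%d:%d", grid$backbone, grid$k, grid$N)
  f <- label_to_formula(labels)
  back <- formula_to_label(f$n_c, f$n_h, f$n_o, dbe_range = c(0, 20))
  expect_identical(back$label, labels)

  # no CHO formula is claimed by both backbones
  key <- paste(f$n_c, f$n_h, f$n_o)
  split_bb <- split(key, grid$backbone)
  expect_length(intersect(split_bb$S, split_bb$G), 0)
})

test_that("adduct m/z values reproduce printed masses", {
  expect_equal(round(adduct_mz("S3:15", adduct = "[M+Na]+")), 617)
  expect_equal(round(monoisotopic_mass(15, 24), 1), 204.2)  # alpha-humulene
  expect_equal(round(monoisotopic_mass(10, 16), 1), 136.1)  # alpha-phellandrene
  # sodium vs proton adduct separation is a constant mass difference
  set.seed(1)
  for (i in 1:5) {
    nc <- sample(5:40, 1); nh <- sample(5:60, 1); no <- sample(0:20, 1)
    expect_equal(adduct_mz(nc, nh, no, "[M+Na]+") -
                   adduct_mz(nc, nh, no, "[M+H]+"),
                 21.981945, tolerance = 1e-6)
  }
})

test_that("retention indices interpolate linearly between calibration alkanes", {
  cal <- tibble::tibble(carbon = 8:20, rt = 2 + 1.7 * (8:20) + 0.01 * (8:20)^2)
  # every calibration alkane lands exactly on 100 x its carbon number
  expect_equal(kovats_index(cal$rt, cal), 100 * cal$carbon)
  # midpoint between C10 and C11 -> 1050
  mid <- (cal$rt[cal$carbon == 10] + cal$rt[cal$carbon == 11]) / 2
  expect_equal(kovats_index(mid, cal), 1050)
  # worked two-alkane example
  expect_equal(kovats_index(21.4, tibble::tibble(carbon = 14:15,
                                                 rt = c(20, 22))), 1470)
  # strict monotonicity across the calibrated range
  rts <- sort(runif(200, min(cal$rt), max(cal$rt)))
  expect_true(all(diff(kovats_index(rts, cal)) > 0))
  # out-of-range handling
  expect_error(kovats_index(min(cal$rt) - 1, cal), "extrapolate")
  expect_lt(kovats_index(min(cal$rt) - 0.5, cal, extrapolate = TRUE), 800)
  expect_error(kovats_index(5, tibble::tibble(carbon = 8:9, rt = c(3, 2))),
               "strictly increasing")
})

test_that("feature tables merge co-eluting peaks, zero-fill and average replicates", {
  m <- tibble::tibble(
    accession = rep(c("a1", "a2"), each = 2),
    replicate = rep(1L, 4),
    feature_id = rep(c("bphell", "dlim"), 2),
    abundance = c(3, 4, 5, 6)
  )
  ft <- build_feature_table(m, merge_rules = list(`bphell/dlim` =
                                                    c("bphell", "dlim")))
  expect_equal(sort(ft$wide$`bphell/dlim`), c(7, 11))

  # absent feature is an explicit zero
  m2 <- tibble::tibble(accession = c("a1", "a2"), replicate = 1L,
                       feature_id = c("x", "y"), abundance = c(2, 5))
  ft2 <- build_feature_table(m2)
  expect_equal(ft2$wide$y[ft2$wide$accession == "a1"], 0)
  expect_equal(ft2$wide$x[ft2$wide$accession == "a2"], 0)

  # replicates 1..6 average to 3.5
  m3 <- tibble::tibble(accession = "a1", replicate = 1:6,
                       feature_id = "f", abundance = 1:6)
  expect_equal(build_feature_table(m3)$wide$f, 3.5)

  dup <- dplyr::bind_rows(m2, m2[1, ])
  expect_error(build_feature_table(dup), "Duplicate")
  neg <- m2; neg$abundance[1] <- -1
  expect_error(build_feature_table(neg), "non-negative")
})

test_that("label/mass disagreements are surfaced, not silently corrected", {
  chk <- annotation_consistency(c("S3:15", "S3:21"), c(617, 715))
  expect_true(chk$consistent[1])
  expect_false(chk$consistent[2])
  # saturated S3:21 sodium adduct sits near 701.4, ~13.6 u below the
  # reported 715; the check reports the gap on the reported side
  expect_equal(chk$expected_mz[2], 701.4, tolerance = 0.05)
  expect_gt(chk$delta[2], 13)
})
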