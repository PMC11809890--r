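test_that("weighted frequencies normalise to 100%", {
  tab <- survey_joint_fixture()
  wf <- weighted_frequency(tab, "anc4")
  expect_equal(sum(wf$pct), 100)
  expect_equal(wf$count[wf$level == "0"], 2238)
  expect_equal(wf$pct[wf$level == "0"], 57.0, tolerance = 1e-3)

  # all weights 1: weighted counts equal raw counts
  tab1 <- small_table()
  wf1 <- weighted_frequency(tab1, "y2")
  expect_equal(sum(wf1$count), nrow(tab1))
})

test_that("chi-square cross-tab matches the hand computation", {
  # 2x2 weighted counts [[10,20],[20,10]]: X2 = sum (O-E)^2/E = 20/3
  df <- data.frame(y1 = c(1, 1, 0, 0), y2 = c(1, 0, 1, 0),
                   cluster = "z", grp = c("r1", "r1", "r2", "r2"),
                   weight = c(10, 20, 20, 10))
  tab <- analysis_table(df, weight = "weight",
                        schema = list(categorical_spec("grp",
                                                       c("r1", "r2"))))
  ct <- crosstab_chisq(tab, "grp", "y2")
  expect_equal(ct$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(ct$df, 1)
  expect_equal(ct$p_value, pchisq(20 / 3, 1, lower.tail = FALSE))
  expect_equal(rowSums(ct$row_pct), c(r1 = 100, r2 = 100))

  # identical rows: no association
  df0 <- df; df0$weight <- c(10, 20, 10, 20)
  ct0 <- crosstab_chisq(analysis_table(df0, weight = "weight"),
                        "grp", "y2")
  expect_equal(ct0$statistic, 0, tolerance = 1e-12)
  expect_equal(ct0$p_value, 1)

  # df formula for a 3x2 table; invariance under row permutation
  tab3 <- small_table(n = 60, seed = 7)
  ct3 <- crosstab_chisq(tab3, "grp", "y1")
  expect_equal(ct3$df, 2)
  perm <- withr::with_seed(3, sample(nrow(tab3)))
  tab3p <- analysis_table(as.data.frame(tab3)[perm, ], "y1", "y2",
                          "cluster", "weight", schema = grp_schema)
  expect_equal(crosstab_chisq(tab3p, "grp", "y1")$statistic,
               ct3$statistic)
})

test_that("joint table reproduces the published worked example", {
  jt <- joint_outcome_table(survey_joint_fixture())
  expect_equal(unname(jt$counts),
               c(1266, 422, 796, 1442))          # y11, y10, y01, y00
  expect_equal(jt$total, 3926)
  expect_lt(max(abs(jt$proportions - c(0.322, 0.108, 0.203, 0.367))),
            1e-3)
  expect_equal(sum(jt$proportions), 1)
  expect_equal(unname(jt$margins$y1), c(1688, 2238))
  expect_equal(unname(jt$margins$y2), c(2062, 1864))

  or <- contingency_odds_ratio(jt)
  expect_equal(or$or_hat, 5.435, tolerance = 1e-4)
  expect_equal(or$ci_low, 4.724, tolerance = 1e-3)
  expect_equal(or$ci_high, 6.252, tolerance = 1e-3)
})

test_that("odds ratio obeys symmetry, round-trip and zero-cell rules", {
  jt <- joint_outcome_table(survey_joint_fixture())
  # swapping the second outcome's columns inverts the OR
  swapped <- jt
  swapped$counts <- jt$counts[c("y10", "y11", "y00", "y01")]
  names(swapped$counts) <- c("y11", "y10", "y01", "y00")
  expect_equal(contingency_odds_ratio(swapped)$or_hat,
               1 / contingency_odds_ratio(jt)$or_hat)

  # cells built from plackett_cells scaled by N return psi
  cells <- plackett_cells(0.4, 0.6, 3.7)
  fake <- list(counts = c(y11 = cells$p11, y10 = cells$p10,
                          y01 = cells$p01, y00 = cells$p00) * 5000)
  expect_equal(contingency_odds_ratio(fake)$or_hat, 3.7,
               tolerance = 1e-10)

  # equal cells: OR 1, CI symmetric about 1 on the log scale
  eq <- list(counts = c(y11 = 25, y10 = 25, y01 = 25, y00 = 25))
  oreq <- contingency_odds_ratio(eq)
  expect_equal(oreq$or_hat, 1)
  expect_equal(log(oreq$ci_low), -log(oreq$ci_high))

  zero <- list(counts = c(y11 = 5, y10 = 0, y01 = 3, y00 = 2))
  expect_error(contingency_odds_ratio(zero), "y10")
  expect_gt(contingency_odds_ratio(zero, continuity = TRUE)$or_hat, 0)
})

test_that("risk profiles add up to the grand joint table", {
  cfg <- default_emdhs_config(n_clusters = 10, cluster_size_mean = 30)
  tab <- simulate_bivml(cfg, seed = 5)
  prof <- joint_risk_profile(tab, "education")
  jt <- joint_outcome_table(tab)
  expect_equal(sum(prof$n11), unname(jt$counts["y11"]))
  expect_equal(sum(prof$n00), unname(jt$counts["y00"]))
  # within-stratum percentage pairs normalise to 100
  expect_equal(prof$pct00 + prof$pct01, rep(100, nrow(prof)))
  expect_equal(prof$pct10 + prof$pct11, rep(100, nrow(prof)))
  # a single-level covariate reproduces the grand table
  df <- as.data.frame(tab); df$all <- "x"
  tab2 <- analysis_table(df, "anc4", "facility", "zone", "weight",
                         schema = list(categorical_spec("all", "x")))
  p1 <- joint_risk_profile(tab2, "all")
  expect_equal(c(p1$n00, p1$n01, p1$n10, p1$n11),
               unname(jt$counts[c("y00", "y01", "y10", "y11")]))
})
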