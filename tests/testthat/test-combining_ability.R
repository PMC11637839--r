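# Line x tester ANOVA, effects and variance components.

test_that("reference design yields the reference df column", {
  sim <- simulate_trial(sim_config(seed = 1, conditions = "drought"))
  an <- fit_linetester_anova(sim$obs, "drought", "GY")
  df <- setNames(an$df, an$source)
  expect_equal(df[["GENOTYPES"]], 179)
  expect_equal(df[["LINE (GCA Line)"]], 35)
  expect_equal(df[["TESTER (GCA Tester)"]], 4)
  expect_equal(df[["LINE x TESTER (SCA)"]], 140)
  expect_equal(df[["GENOTYPES x E"]], 179)
  expect_equal(df[["BLOCK(E:REP)"]], 52)
  expect_equal(df[["Residuals"]], 306)
})

test_that("sums of squares match the brute-force decomposition on small designs", {
  set.seed(42)
  for (l in 2:3) for (t in 2:3) for (e in 1:2) for (r in 1:2) {
    if (e == 1 && r == 1) next   # no residual df; decomposition is exact 0
    cells <- matrix(rnorm(l * t, 100, 20), l, t)
    d <- toy_testcross(cells, n_env = e, n_rep = r,
                       env_eff = rnorm(e, 0, 5), rep_eff = rnorm(r, 0, 2),
                       noise = rnorm(l * t * e * r, 0, 3))
    an <- if (e < 2)
      suppressWarnings(fit_linetester_anova(d, "drought", "GY"))
    else fit_linetester_anova(d, "drought", "GY")
    bf <- brute_force_lt_anova(d, "GY")
    map <- c("LINE (GCA Line)" = "L", "TESTER (GCA Tester)" = "T",
             "LINE x TESTER (SCA)" = "LT", "Residuals" = "RES")
    if (e >= 2)
      map <- c(map, E = "E", "REP(E)" = "REP", "GCA LINE x E" = "LE",
               "GCA TESTER x E" = "TE", "LINE x TESTER x E" = "LTE")
    for (src in names(map)) {
      i <- match(src, an$source)
      expect_equal(an$sum_sq[i], bf$ss[[map[[src]]]], tolerance = 1e-9,
                   label = sprintf("SS[%s] l=%d t=%d e=%d r=%d",
                                   src, l, t, e, r))
      expect_equal(an$df[i], bf$df[[map[[src]]]])
    }
    # exact genotype partition
    expect_equal(an$sum_sq[an$source == "GENOTYPES"],
                 sum(an$sum_sq[an$source %in%
                   c("LINE (GCA Line)", "TESTER (GCA Tester)",
                     "LINE x TESTER (SCA)")]), tolerance = 1e-12)
  }
})

test_that("constant data gives zero SS and NA F ratios", {
  d <- toy_testcross(matrix(5, 2, 2), n_env = 2, n_rep = 2)
  an <- fit_linetester_anova(d, "drought", "GY")
  expect_true(all(an$sum_sq < 1e-20))
  expect_true(all(is.na(an$F)))
})

test_that("unbalanced cells are rejected with the missing cell named", {
  d <- toy_testcross(matrix(1:4 * 1.0, 2, 2), n_rep = 2)
  d <- d[-1, ]
  expect_error(fit_linetester_anova(d, "drought", "GY"), "unbalanced")
  expect_error(fit_linetester_anova(d, "drought", "GY"), "L1")
})

test_that("an additive 2x2 cell-mean table decomposes by hand", {
  d <- toy_testcross(matrix(c(10, 30, 20, 40), 2, 2), n_rep = 2)
  eff <- suppressWarnings(estimate_effects(d, "drought", "GY"))  # 1 season
  expect_equal(setNames(eff$gca_line$effect, eff$gca_line$parent),
               c(L1 = -10, L2 = 10))
  expect_equal(setNames(eff$gca_tester$effect, eff$gca_tester$parent),
               c(T1 = -5, T2 = 5))
  expect_true(all(abs(eff$sca$effect) < 1e-12))
  # all cell means equal -> every effect zero
  eff0 <- suppressWarnings(
    estimate_effects(toy_testcross(matrix(7, 2, 2), n_rep = 2),
                     "drought", "GY"))
  expect_true(all(abs(c(eff0$gca_line$effect, eff0$gca_tester$effect,
                        eff0$sca$effect)) < 1e-12))
})

test_that("estimated effects satisfy zero sums and track the truth", {
  sim <- simulate_trial(sim_config(seed = 8, conditions = "drought"))
  eff <- estimate_effects(sim$obs, "drought", "GY")
  expect_lt(abs(sum(eff$gca_line$effect)), 1e-9)
  expect_lt(abs(sum(eff$gca_tester$effect)), 1e-9)
  s <- matrix(eff$sca$effect, 36, 5)
  expect_lt(max(abs(rowSums(s))), 1e-9)
  expect_lt(max(abs(colSums(s))), 1e-9)
  tru <- sim$truth
  g_true <- setNames(tru$value[tru$term == "gca_line" & tru$trait == "GY" &
                                 tru$condition == "drought"],
                     tru$parent[tru$term == "gca_line" & tru$trait == "GY" &
                                  tru$condition == "drought"])
  # at the calibrated drought signal/noise (line variance ~110000 against a
  # plot error of ~823000 over 20 observations per line plus SCA and GxE
  # leakage) the attainable estimate-truth correlation is ~0.8
  expect_gt(cor(eff$gca_line$effect, g_true[eff$gca_line$parent]), 0.65)
  cors <- vapply(2:5, function(s) {
    sm <- simulate_trial(sim_config(seed = s, conditions = "drought",
                                    traits = default_trait_specs()["GY"]))
    ef <- estimate_effects(sm$obs, "drought", "GY")
    tt <- sm$truth
    gt <- setNames(tt$value[tt$term == "gca_line"],
                   tt$parent[tt$term == "gca_line"])
    cor(ef$gca_line$effect, gt[ef$gca_line$parent])
  }, 0)
  expect_gt(mean(cors), 0.7)
})

test_that("EMS divisors turn mean squares into variance components", {
  an <- reference_mean_squares("drought")
  comp <- estimate_components(an)
  expect_equal(comp$sigma2_sca, (1042447.91 - 823214.9) / 4,
               tolerance = 1e-12)
  expect_equal(comp$sigma2_gca_line, (3246398.69 - 1042447.91) / 20,
               tolerance = 1e-12)
  expect_equal(comp$sigma2_gca_tester, (3662333.70 - 1042447.91) / 144,
               tolerance = 1e-12)
  # MS_SCA == MS_err -> null SCA component, flagged truncation when below
  an2 <- an
  an2$mean_square[an2$source == "LINE x TESTER (SCA)"] <-
    an2$mean_square[an2$source == "Residuals"]
  expect_equal(estimate_components(an2)$sigma2_sca, 0)
  an3 <- an
  an3$mean_square[an3$source == "LINE x TESTER (SCA)"] <- 0
  c3 <- estimate_components(an3)
  expect_equal(c3$sigma2_sca, 0)
  expect_true("sigma2_sca" %in% c3$truncated)
  expect_error(estimate_components(an[an$source != "Residuals", ]),
               "Residuals")
})

test_that("GCA/SCA contributions and Baker's ratio behave as defined", {
  an <- reference_mean_squares("drought")
  contrib <- gca_sca_contribution(an)
  expect_equal(contrib[["pct_gca_ms"]],
               100 * (3246398.69 + 3662333.70) /
                 (3246398.69 + 3662333.70 + 1042447.91), tolerance = 1e-9)
  expect_equal(contrib[["pct_gca_ms"]] + contrib[["pct_sca_ms"]], 100)
  # pure additivity: no SCA mean square -> 100% GCA, Baker = 1
  an0 <- an
  an0$mean_square[an0$source == "LINE x TESTER (SCA)"] <-
    an0$mean_square[an0$source == "Residuals"]
  an0$sum_sq <- an0$mean_square * an0$df
  c0 <- gca_sca_contribution(an0)
  expect_equal(c0[["baker_ratio"]], 1)
})

test_that("equal GCA and SCA variances give Baker's ratio near 0.8", {
  # closed form 2(v+v) / (2(v+v)+v) = 0.8; check the estimate on simulations
  br <- vapply(1:25, function(s) {
    cfg <- small_gy_config(s, n_lines = 36, n_testers = 5,
                           var_gca_line = 1e5, var_gca_tester = 1e5,
                           var_sca = 1e5, var_error = 5e4)
    gca_sca_contribution(
      fit_linetester_anova(simulate_trial(cfg)$obs, "drought",
                           "GY"))[["baker_ratio"]]
  }, 0)
  expect_equal(mean(br), 0.8, tolerance = 0.08)
})
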