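# Mid-parent, better-parent and economic heterosis.

mk_blues <- function(g, v, trait = "GY") {
  d <- data.frame(genotype = g, stringsAsFactors = FALSE)
  d[[trait]] <- v
  d
}

ped1 <- data.frame(genotype = "H1", line_parent = "P1", tester_parent = "P2",
                   stringsAsFactors = FALSE)

test_that("heterosis percentages follow the mid/better-parent arithmetic", {
  hy <- mk_blues("H1", 3000)
  pa <- mk_blues(c("P1", "P2"), c(1000, 2000))
  ht <- heterosis_table(hy, pa, ped1, "GY")
  expect_equal(ht$MP, 1500)
  expect_equal(ht$MPH, 100)
  expect_equal(ht$BP, 2000)
  expect_equal(ht$BPH, 50)
  # F1 equal to both parents: zero heterosis
  ht0 <- heterosis_table(mk_blues("H1", 1500), mk_blues(c("P1", "P2"),
                                                        c(1500, 1500)),
                         ped1, "GY")
  expect_equal(c(ht0$MPH, ht0$BPH), c(0, 0))
  # zero mid-parent -> NA, not Inf
  htz <- heterosis_table(mk_blues("H1", 10),
                         mk_blues(c("P1", "P2"), c(-5, 5)), ped1, "GY")
  expect_true(is.na(htz$MPH))
  expect_warning(
    heterosis_table(mk_blues(c("H1", "H2"), c(1, 2)),
                    mk_blues(c("P1", "P2"), c(1, 1)),
                    rbind(ped1, data.frame(genotype = "H2",
                                           line_parent = "P9",
                                           tester_parent = "P2")), "GY"),
    "missing parent")
})

test_that("direction-aware better parent mirrors the negated-trait computation", {
  hy <- mk_blues("H1", 4, "PASP")
  pa <- mk_blues(c("P1", "P2"), c(3, 6), "PASP")
  ht <- heterosis_table(hy, pa, ped1, "PASP", direction_aware = TRUE)
  expect_equal(ht$BP, 3)   # lower-better: smaller score is the better parent
  # default convention keeps the numerically larger parent
  ht_def <- heterosis_table(hy, pa, ped1, "PASP")
  expect_equal(ht_def$BP, 6)
})

test_that("MPH is at least BPH whenever the hybrid beats the better parent", {
  set.seed(3)
  for (i in 1:40) {
    p <- sort(stats::runif(2, 100, 1000)); f1 <- p[2] * stats::runif(1, 1, 2)
    ht <- heterosis_table(mk_blues("H1", f1), mk_blues(c("P1", "P2"), p),
                          ped1, "GY")
    expect_gte(ht$MPH, ht$BPH)
  }
})

test_that("economic heterosis ranks hybrids against the best check", {
  b <- mk_blues(c("H1", "H2", "H3", "C1", "C2"),
                c(4044.2, 3500, 2000, 3015.2, 2500))
  eh <- economic_heterosis(b, c("C1", "C2"), "GY")
  expect_equal(eh$bcc, 3015.2)
  expect_equal(eh$table$EH_pct[1], 100 * (4044.2 - 3015.2) / 3015.2)
  expect_equal(eh$n_above_check, 2)
  # adding a weaker check changes nothing
  b2 <- rbind(b, mk_blues("C3", 1000))
  eh2 <- economic_heterosis(b2, c("C1", "C2", "C3"), "GY")
  expect_equal(eh2$table$EH_pct, eh$table$EH_pct)
  # hybrid equal to the check is not counted as beating it
  b3 <- mk_blues(c("H1", "C1"), c(3015.2, 3015.2))
  expect_equal(economic_heterosis(b3, "C1", "GY")$n_above_check, 0)
  expect_error(economic_heterosis(mk_blues(c("H1", "C1"), c(5, -2)),
                                  "C1", "GY"), "not positive")
})

test_that("summary averages per-hybrid percentages per trait", {
  recs <- data.frame(hybrid = c("A", "B"), trait = "GY",
                     F1 = 1, P1 = 1, P2 = 1, MP = 1, BP = 1,
                     MPH = c(100, 300), BPH = c(50, 150))
  s <- heterosis_summary(recs)
  expect_equal(s$mean_MPH, 200)
  expect_equal(s$mean_BPH, 100)
})

test_that("pure additivity gives zero mean mid-parent heterosis", {
  # inbred per-se value = mu + 2*gca and hybrid mean mu equal to inbred mu:
  # the mid-parent equals the expected F1, so MPH averages to ~0
  cfg <- small_gy_config(21, n_lines = 12, n_testers = 4, var_sca = 0,
                         var_error = 3e4)
  cfg$parent_mu$GY <- cfg$mu$GY <- 2139
  cfg$var_rep$GY <- 0; cfg$var_block$GY <- 0
  sim <- simulate_trial(cfg)
  hb <- compute_blues(sim$obs, "drought", roles = "testcross")
  pb <- compute_blues(sim$obs, "drought", roles = c("line", "tester"))
  ped <- unique(sim$obs[sim$obs$role == "testcross",
                        c("genotype", "line_parent", "tester_parent")])
  ht <- heterosis_table(hb, pb, ped, "GY")
  expect_lt(abs(mean(ht$MPH)), 2.5)
})

test_that("low parent means with dominance give MPH >> BPH > 0", {
  # inbreeding depression (parents well below the hybrids) with moderate
  # parental spread, so the percentage denominators stay away from zero
  cfg <- small_gy_config(31, n_lines = 12, n_testers = 4,
                         var_gca_line = 5e4, var_gca_tester = 2e4,
                         var_sca = 4e5, var_error = 5e4)
  cfg$parent_mu$GY <- 1200
  sim <- simulate_trial(cfg)
  hb <- compute_blues(sim$obs, "drought", roles = "testcross")
  pb <- compute_blues(sim$obs, "drought", roles = c("line", "tester"))
  ped <- unique(sim$obs[sim$obs$role == "testcross",
                        c("genotype", "line_parent", "tester_parent")])
  s <- heterosis_summary(heterosis_table(hb, pb, ped, "GY"))
  expect_gt(s$mean_MPH, s$mean_BPH)
  expect_gt(s$mean_BPH, 0)
})
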