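# Data model, CSV round trips and adjusted means.

test_that("a small testcross file parses with roles and values intact", {
  cells <- matrix(c(10, 20, 30, 40), 2, 2)
  d <- toy_testcross(cells, n_rep = 2)
  f <- tempfile(fileext = ".csv")
  write_trial(d, f)
  got <- read_trial(f)
  expect_equal(nrow(got), 8L)
  expect_true(all(got$role == "testcross"))
  expect_equal(sort(got$GY), sort(d$GY))
})

test_that("out-of-range ordinal scores are rejected with trait and row named", {
  d <- toy_testcross(matrix(c(10, 20, 30, 40), 2, 2))
  d$PASP <- c(5, 12, 4, 3)
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE, na = "")
  expect_error(read_trial(f), "PASP.*\\[1,9\\]")
  expect_error(read_trial(f), "row 2")
})

test_that("role/parent cross-validation and design columns are enforced", {
  d <- toy_testcross(matrix(1:4, 2, 2))
  f <- tempfile(fileext = ".csv")
  d2 <- d; d2$role[1] <- "hybridx"
  write.csv(d2, f, row.names = FALSE, na = "")
  expect_error(read_trial(f), "unknown role")
  d3 <- d; d3$line_parent[2] <- NA
  write.csv(d3, f, row.names = FALSE, na = "")
  expect_error(read_trial(f), "both parents")
  d4 <- d[, setdiff(names(d), "block")]
  write.csv(d4, f, row.names = FALSE, na = "")
  expect_error(read_trial(f), "missing design column")
  # condition-restricted trait: stay-green only exists under drought
  d5 <- d; d5$condition <- "rainfed"; d5$STGC <- 5
  write.csv(d5, f, row.names = FALSE, na = "")
  expect_error(read_trial(f), "STGC")
})

test_that("simulated 180-testcross trial round-trips write -> read losslessly", {
  sim <- simulate_trial(sim_config(seed = 11, conditions = "drought"))
  f <- tempfile(fileext = ".csv")
  write_trial(sim$obs, f)
  got <- read_trial(f)
  for (tr in attr(sim$obs, "traits"))
    expect_equal(got[[tr]], sim$obs[[tr]], tolerance = 1e-12)
  expect_equal(got$genotype, sim$obs$genotype)
})

test_that("BLUEs equal raw genotype means on balanced block-free data", {
  cells <- matrix(c(10, 20, 30, 40, 50, 60), 3, 2)
  d <- toy_testcross(cells, n_env = 2, n_rep = 2, env_eff = c(0, 0))
  b <- compute_blues(d, "drought")
  raw <- tapply(d$GY, d$genotype, mean)
  expect_equal(b$GY, as.numeric(raw[b$genotype]), tolerance = 1e-10)
})

test_that("single-environment single-replicate BLUEs are the plot values", {
  d <- toy_testcross(matrix(c(7, 13, 21, 34), 2, 2))
  b <- compute_blues(d, "drought")
  expect_equal(sort(b$GY), sort(d$GY))
})

test_that("block-adjusted BLUEs beat raw means when block effects are real", {
  cfg <- small_gy_config(3, n_lines = 8, n_testers = 3, var_block = 4e5,
                         var_error = 5e4)
  sim <- simulate_trial(cfg)
  # lattice-like: re-blocked per replicate with 6-plot blocks
  obs <- sim$obs[sim$obs$role == "testcross", ]
  set.seed(99)
  for (ek in unique(obs$environment)) for (r in 1:2) {
    ix <- which(obs$environment == ek & obs$replicate == r)
    blk <- ceiling(seq_along(ix) / 6)[sample(length(ix))]
    obs$block[ix] <- blk
    obs$GY[ix] <- obs$GY[ix] + 2000 * blk   # strong additive block effects
  }
  attr(obs, "traits") <- "GY"
  tru <- sim$truth
  true_val <- with(
    expand.grid(line = unique(obs$line_parent),
                tester = unique(obs$tester_parent),
                stringsAsFactors = FALSE), {
    gl <- setNames(tru$value[tru$term == "gca_line"],
                   tru$parent[tru$term == "gca_line"])
    gt <- setNames(tru$value[tru$term == "gca_tester"],
                   tru$parent[tru$term == "gca_tester"])
    sc <- tru[tru$term == "sca", ]
    s <- setNames(sc$value, paste(sc$line, sc$tester))
    setNames(gl[line] + gt[tester] + s[paste(line, tester)],
             paste(line, "x", tester))
  })
  b <- compute_blues(obs, "drought")
  raw <- tapply(obs$GY, obs$genotype, mean)
  est <- setNames(b$GY, b$genotype)
  rmse <- function(e) {
    d <- e[names(true_val)] - true_val
    sqrt(mean((d - mean(d))^2))
  }
  expect_lt(rmse(est), rmse(raw))
})

test_that("stress penalty arithmetic, zero-denominator handling and summary", {
  bs <- data.frame(genotype = c("A", "B", "C"), GY = c(400, 500, 10))
  bo <- data.frame(genotype = c("A", "B", "C"), GY = c(1000, 500, 0))
  expect_warning(sp <- stress_penalty(bs, bo, "GY"), "zero")
  expect_equal(sp$per_genotype$penalty_pct,
               c(60, 0))                      # C excluded
  expect_equal(sp$summary[["mean"]], 30)
  # identical tables -> all zero
  sp0 <- stress_penalty(bo[1:2, ], bo[1:2, ], "GY")
  expect_equal(unname(sp0$summary), c(0, 0, 0))
  # lower-better trait reports an increase under stress
  bs2 <- data.frame(genotype = "A", PASP = 6)
  bo2 <- data.frame(genotype = "A", PASP = 4)
  expect_equal(stress_penalty(bs2, bo2, "PASP")$summary[["mean"]], 50)
})

test_that("swapping the tables flips the penalty sign with rescaled base", {
  bs <- data.frame(genotype = c("A", "B"), GY = c(400, 900))
  bo <- data.frame(genotype = c("A", "B"), GY = c(1000, 600))
  fwd <- stress_penalty(bs, bo, "GY")$per_genotype
  rev <- stress_penalty(bo, bs, "GY")$per_genotype
  expect_equal(sign(rev$penalty_pct), -sign(fwd$penalty_pct))
  expect_equal(rev$penalty_pct,
               -fwd$penalty_pct * bo$GY / bs$GY)
})

test_that("a drought scenario scaling true yields by 0.4 gives ~60% mean loss", {
  cfg <- sim_config(
    conditions = c("drought", "rainfed"),
    traits = default_trait_specs()["GY"],
    mu = list(GY = c(drought = 0.4 * 5568, rainfed = 5568)),
    parent_mu = list(GY = c(drought = 0.4 * 2026, rainfed = 2026)),
    var_gca_line = list(GY = c(drought = 0.16 * 222427, rainfed = 222427)),
    var_gca_tester = list(GY = c(drought = 0.16 * 216691, rainfed = 216691)),
    var_sca = list(GY = c(drought = 0.16 * 386696, rainfed = 386696)),
    var_gca_line_x_env = list(GY = 0), var_gca_tester_x_env = list(GY = 0),
    var_sca_x_env = list(GY = 0), var_env = list(GY = 0),
    var_rep = list(GY = 0), var_block = list(GY = 0),
    var_error = list(GY = c(drought = 2e4, rainfed = 2e4)),
    seed = 5)
  sim <- simulate_trial(cfg)
  bs <- compute_blues(sim$obs, "drought", roles = "testcross")
  bo <- compute_blues(sim$obs, "rainfed", roles = "testcross")
  sp <- stress_penalty(bs, bo, "GY")
  expect_equal(sp$summary[["mean"]], 60, tolerance = 0.05)
  expect_equal(nrow(sp$per_genotype), 180L)
})
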