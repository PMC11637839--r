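# Independent oracles used across the test files.

# Brute-force full-factorial mean decomposition of a balanced line x tester
# data set: every sum of squares is accumulated plot by plot from plain
# mean lookups (no cell-total shortcuts), independent of the package's
# implementation.
brute_force_lt_anova <- function(d, trait) {
  d <- d[d$role == "testcross" & !is.na(d[[trait]]), ]
  y <- d[[trait]]
  m <- mean(y)
  key <- function(...) paste(..., sep = "\r")
  avg <- function(keys) {
    s <- tapply(y, keys, mean)
    unname(s[keys])
  }
  li <- d$line_parent; tj <- d$tester_parent; ek <- d$environment
  l <- length(unique(li)); t <- length(unique(tj))
  e <- length(unique(ek)); r <- length(unique(d$replicate))
  m_i <- avg(li); m_j <- avg(tj); m_k <- avg(ek)
  m_ij <- avg(key(li, tj)); m_ik <- avg(key(li, ek)); m_jk <- avg(key(tj, ek))
  m_ijk <- avg(key(li, tj, ek)); m_kr <- avg(key(ek, d$replicate))
  ss <- list(
    L = sum((m_i - m)^2), T = sum((m_j - m)^2),
    LT = sum((m_ij - m_i - m_j + m)^2))
  dfs <- list(L = l - 1, T = t - 1, LT = (l - 1) * (t - 1))
  if (e >= 2) {
    ss$E <- sum((m_k - m)^2)
    ss$REP <- sum((m_kr - m_k)^2)
    ss$LE <- sum((m_ik - m_i - m_k + m)^2)
    ss$TE <- sum((m_jk - m_j - m_k + m)^2)
    ss$LTE <- sum((m_ijk - m_ij - m_ik - m_jk + m_i + m_j + m_k - m)^2)
    dfs <- c(dfs, list(E = e - 1, REP = e * (r - 1), LE = (l - 1) * (e - 1),
                       TE = (t - 1) * (e - 1),
                       LTE = (l - 1) * (t - 1) * (e - 1)))
  } else if (r >= 2) {
    ss$REP <- sum((m_kr - m_k)^2)
    dfs$REP <- e * (r - 1)
  }
  res <- y - m_ijk
  if (e < 2) res <- y - m_ij  # single season: residual within cells
  ss <- lapply(ss, sum)
  tot <- sum((y - m)^2)
  ss$RES <- tot - sum(unlist(ss))
  dfs$RES <- length(y) - 1 - sum(unlist(dfs))
  list(ss = ss, df = dfs, total = tot)
}

# Exhaustive Ward.D2 agglomeration: at every step recompute the Ward
# criterion sqrt(2 |A||B| / (|A|+|B|) * ||centroid_A - centroid_B||^2) over
# all cluster pairs and merge the minimum.  Returns merge heights and the
# partition after each merge.
brute_force_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (b <= a) next
      A <- clusters[[a]]; B <- clusters[[b]]
      mu_a <- colMeans(x[A, , drop = FALSE])
      mu_b <- colMeans(x[B, , drop = FALSE])
      h <- sqrt(2 * length(A) * length(B) / (length(A) + length(B)) *
                  sum((mu_a - mu_b)^2))
      if (h < best[1]) best <- c(h, a, b)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1L]] <- merged
    part <- integer(n)
    for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1L]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# Canonical encoding of a partition (cluster labels renumbered by first
# appearance) so partitions can be compared irrespective of label choice.
canon_partition <- function(p) as.integer(factor(p, levels = unique(p)))

# Hand-built balanced testcross data frame from a matrix of cell values
# (lines x testers), replicated over environments/reps with optional
# additive offsets.
toy_testcross <- function(cells, n_env = 1, n_rep = 1, env_eff = NULL,
                          rep_eff = NULL, noise = NULL) {
  l <- nrow(cells); t <- ncol(cells)
  lines <- sprintf("L%d", seq_len(l)); testers <- sprintf("T%d", seq_len(t))
  rows <- expand.grid(line = seq_len(l), tester = seq_len(t),
                      env = seq_len(n_env), rep = seq_len(n_rep))
  y <- cells[cbind(rows$line, rows$tester)]
  if (!is.null(env_eff)) y <- y + env_eff[rows$env]
  if (!is.null(rep_eff)) y <- y + rep_eff[rows$rep]
  if (!is.null(noise)) y <- y + noise
  data.frame(condition = "drought", environment = paste0("E", rows$env),
             replicate = rows$rep, block = 1L,
             genotype = paste(lines[rows$line], testers[rows$tester],
                              sep = " x "),
             role = "testcross", line_parent = lines[rows$line],
             tester_parent = testers[rows$tester], GY = y,
             stringsAsFactors = FALSE)
}

# A small, fast simulator configuration (grain yield only, one condition)
# used where full-size trials would be wasteful.
small_gy_config <- function(seed, n_lines = 6, n_testers = 3, n_envs = 2,
                            n_reps = 2, var_gca_line = 110000,
                            var_gca_tester = 18000, var_sca = 55000,
                            var_error = 823215, gxe = 0, n_checks = 0,
                            var_block = 0) {
  sim_config(
    n_lines = n_lines, n_testers = n_testers, n_checks = n_checks,
    n_envs = n_envs, n_reps = n_reps, block_size = 1000,
    conditions = "drought", traits = default_trait_specs()["GY"],
    var_gca_line = list(GY = var_gca_line),
    var_gca_tester = list(GY = var_gca_tester),
    var_sca = list(GY = var_sca),
    var_gca_line_x_env = list(GY = gxe),
    var_gca_tester_x_env = list(GY = gxe),
    var_sca_x_env = list(GY = gxe),
    var_env = list(GY = 20000), var_rep = list(GY = 10000),
    var_block = list(GY = var_block),
    var_error = list(GY = var_error), seed = seed)
}
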