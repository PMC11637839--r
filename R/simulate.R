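# Synthetic line x tester trial generator. The generator mirrors the
# observation model the analysis assumes:
#   y = mu + env + rep(env) + block(rep) + g_i + t_j + s_ij
#       + (gE)_ik + (tE)_jk + (sE)_ijk + error
# with every random term Gaussian with a configurable variance, and with the
# genetic terms re-centered to exact zero sums so that downstream estimates
# can be compared against an unambiguous truth.

# Internal: a per-trait parameter may be a scalar (same under both growing
# conditions) or a named vector c(drought = , rainfed = ).
cond_val <- function(x, condition) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (!condition %in% names(x))
    stop("no value for condition '", condition, "'")
  unname(x[[condition]])
}

# Default per-trait magnitudes.  Means reproduce the reference trial's
# testcross, inbred and check performance levels under managed drought and
# rain-fed conditions; genetic variances (line GCA, tester GCA, line x
# tester SCA) and plot error variances are calibrated to the reference
# trial's variance-component and residual mean-square estimates.  GxE
# variance components default to the grain-yield estimates (other traits: 0,
# where the reference interactions were mostly non-significant).
default_trait_params <- function() {
  p <- list(
    #        mu_d,   mu_r, pmu_d,  pmu_r, cmu_d, cmu_r,  vl_d,     vl_r,     vt_d,    vt_r,     vs_d,    vs_r,     ve_d,    ve_r
    GY   = c(2139,   5568,  577,   2026,  2700,  5500,   110197.54, 222427.66, 18193.65, 216691.81, 54808.25, 386696.39, 823214.9, 1095273.8),
    DP   = c(50,     51,    54,    54.47, 50,    51,     0.54,     0.25,     0.77,    0.23,     0.39,    0.38,     2.45,    1.03),
    DS   = c(51,     51,    55,    54.67, 51,    51,     1.55,     0.75,     1.11,    0.28,     0.92,    0.78,     5.66,    1.74),
    ASI  = c(1.5,    0.61,  1.5,   0.94,  1.5,   0.6,    0.23,     0.01,     0.03,    0.03,     0.11,    0.06,     1.66,    0.39),
    PHT  = c(147.86, 179.28, 85.47, 117.3, 150,  180,    42.81,    27.52,    24.88,   54.32,    17.54,   14.92,    192.69,  71.65),
    EHT  = c(76.36,  83.56, 41.67, 47.71, 77,    84,     13.76,    11.35,    13.84,   18.53,    11.15,   10.85,    69.55,   51.07),
    EPP  = c(0.71,   0.92,  0.55,  0.88,  0.72,  0.93,   0.002,    0.002,    0.002,   0.002,    0.002,   0.002,    0.03,    0.01),
    PASP = c(5.42,   4.43,  5.47,  3.82,  5.2,   4.2,    0.05,     0.04,     0.06,    0.21,     0.08,    0.17,     0.94,    0.86),
    EASP = c(5.12,   4.78,  5.65,  4.26,  5.0,   4.5,    0.11,     0.01,     0.03,    0.02,     0.04,    0.02,     0.98,    0.74),
    HCV  = c(5.0,    4.7,   5.5,   5.0,   5.0,   4.7,    0.24,     0.26,     0.57,    1.41,     0.09,    0.18,     0.77,    0.81),
    STGC = c(5.0,    5.0,   5.5,   5.5,   5.0,   5.0,    0.04,     0.04,     0.14,    0.14,     0.11,    0.11,     0.98,    0.98)
  )
  cols <- c("mu_d", "mu_r", "parent_mu_d", "parent_mu_r", "check_mu_d",
            "check_mu_r", "var_gca_line_d", "var_gca_line_r",
            "var_gca_tester_d", "var_gca_tester_r", "var_sca_d", "var_sca_r",
            "var_error_d", "var_error_r")
  out <- as.data.frame(do.call(rbind, p))
  names(out) <- cols
  out$trait <- rownames(out)
  out
}

#' Configuration for the synthetic line x tester trial
#'
#' The default configuration emulates the reference extra-early orange maize
#' study design: 36 lines crossed to 5 testers (180 testcrosses) plus 6
#' commercial checks, 2 replicates and 2 seasons per growing condition,
#' incomplete blocks of 14 entries, and per-trait means and variance
#' magnitudes calibrated to the reference trial's estimates.  Drought is
#' emulated through condition-specific means and variances: yield drops by
#' about 61\%, the anthesis-silking interval lengthens, and the visual
#' scores inflate.
#'
#' Per-trait parameters (\code{mu}, variances, ...) accept either a scalar
#' (both conditions) or \code{c(drought = , rainfed = )}.
#'
#' @param n_lines,n_testers,n_checks Entry counts.
#' @param n_envs Seasons per growing condition.
#' @param n_reps Replicates per season.
#' @param block_size Entries per incomplete block.
#' @param conditions Growing conditions to generate.
#' @param traits Named list of \code{\link{trait_spec}}.
#' @param mu,parent_mu,check_mu Named lists (per trait) of testcross, inbred
#'   per-se and check means.
#' @param var_gca_line,var_gca_tester,var_sca Genetic variances per trait.
#' @param var_gca_line_x_env,var_gca_tester_x_env,var_sca_x_env GxE
#'   variances per trait.
#' @param var_env,var_rep,var_block,var_error,var_check Design and error
#'   variances per trait.
#' @param seed RNG seed; identical configuration and seed give
#'   byte-identical output.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_lines = 36, n_testers = 5, n_checks = 6,
                       n_envs = 2, n_reps = 2, block_size = 14,
                       conditions = c("drought", "rainfed"),
                       traits = default_trait_specs(),
                       mu = NULL, parent_mu = NULL, check_mu = NULL,
                       var_gca_line = NULL, var_gca_tester = NULL,
                       var_sca = NULL,
                       var_gca_line_x_env = NULL,
                       var_gca_tester_x_env = NULL,
                       var_sca_x_env = NULL,
                       var_env = NULL, var_rep = NULL, var_block = NULL,
                       var_error = NULL, var_check = NULL,
                       seed = 1L) {
  tp <- default_trait_params()
  tnames <- names(traits)
  pick <- function(user, d_col, r_col, fallback = NULL) {
    out <- setNames(vector("list", length(tnames)), tnames)
    for (tr in tnames) {
      if (!is.null(user) && !is.null(user[[tr]])) out[[tr]] <- user[[tr]]
      else if (tr %in% tp$trait && !is.null(d_col))
        out[[tr]] <- c(drought = tp[tr, d_col], rainfed = tp[tr, r_col])
      else out[[tr]] <- fallback
    }
    out
  }
  gy_only <- function(user, d_val, r_val) {
    out <- setNames(rep(list(0), length(tnames)), tnames)
    if ("GY" %in% tnames) out$GY <- c(drought = d_val, rainfed = r_val)
    for (tr in tnames)
      if (!is.null(user) && !is.null(user[[tr]])) out[[tr]] <- user[[tr]]
    out
  }
  cfg <- list(
    n_lines = n_lines, n_testers = n_testers, n_checks = n_checks,
    n_envs = n_envs, n_reps = n_reps, block_size = block_size,
    conditions = conditions, traits = traits,
    mu = pick(mu, "mu_d", "mu_r", 0),
    parent_mu = pick(parent_mu, "parent_mu_d", "parent_mu_r", 0),
    check_mu = pick(check_mu, "check_mu_d", "check_mu_r", 0),
    var_gca_line = pick(var_gca_line, "var_gca_line_d", "var_gca_line_r", 0),
    var_gca_tester = pick(var_gca_tester, "var_gca_tester_d",
                          "var_gca_tester_r", 0),
    var_sca = pick(var_sca, "var_sca_d", "var_sca_r", 0),
    var_gca_line_x_env = gy_only(var_gca_line_x_env, 22437.47, 62647.88),
    var_gca_tester_x_env = gy_only(var_gca_tester_x_env, 16786.49, 26605.24),
    var_sca_x_env = gy_only(var_sca_x_env, 13012.88, 0),
    var_env = gy_only(var_env, 23000, 158000),
    var_rep = gy_only(var_rep, 46000, 10000),
    var_block = gy_only(var_block, 20000, 30000),
    var_error = pick(var_error, "var_error_d", "var_error_r", 1),
    var_check = gy_only(var_check, 90000, 90000),
    seed = as.integer(seed)
  )
  for (nm in grep("^var", names(cfg), value = TRUE))
    for (tr in tnames)
      if (any(unlist(cfg[[nm]][[tr]]) < 0))
        stop("config error: negative variance for ", nm, " / ", tr)
  if (block_size < 2)
    stop("config error: block_size must be at least 2")
  class(cfg) <- "sim_config"
  cfg
}

# Internal: centered draws -- exact zero sum.  Used for main (GCA) effects:
# subtracting the mean leaves their sample variance untouched.
centered_norm <- function(n) { z <- rnorm(n); z - mean(z) }
# Internal: SCA draws are iid with only the grand mean removed.  Removing
# row/column means as well (exact per-parent zero sums) would delete the
# SCA contribution from every parent's marginal mean and bias the standard
# expected-mean-square estimators by -sigma2_sca/t (lines) and
# -sigma2_sca/l (testers); the iid draw matches the estimators' sampling
# model, at the price of per-parent truth sums that are only zero in
# expectation.
grand_centered_norm_mat <- function(nr, nc) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  z - mean(z)
}

#' Simulate a multi-environment line x tester trial with known truth
#'
#' Draws GCA scores with exact zero sums per parent group and iid SCA
#' scores (grand mean removed) once per parent/cross, and scales
#' them by the per-condition genetic standard deviations, so genetic values
#' are perfectly correlated across growing conditions; adds season,
#' replicate, incomplete-block, GxE and plot-error effects; and assembles
#' plot observations for the testcross + check hybrid trial and the parent
#' (line/tester per-se) trial.  Inbred per-se genetic values are modelled as
#' twice the parent's GCA effect (pure additivity), so with equal hybrid and
#' inbred means mid-parent heterosis is zero in expectation.  Ordinal-score
#' traits are simulated on a latent continuous scale, clipped to [1, 9] and
#' rounded to 0.1 as the last step; count-ratio traits (ears per plant) are
#' clipped at 0.  Continuous traits are left on the Gaussian scale, so a
#' weak inbred can show a (near-)zero or slightly negative drought yield.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{obs} (plot observations, see
#'   \code{\link{read_trial}}) and \code{truth} (true GCA/SCA effects per
#'   condition and trait, plus the configuration).
#' @export
simulate_trial <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  l <- config$n_lines; t <- config$n_testers
  lines <- sprintf("L%02d", seq_len(l))
  testers <- sprintf("T%d", seq_len(t))
  checks <- if (config$n_checks > 0) sprintf("CHK%d", seq_len(config$n_checks))
            else character(0)
  tnames <- names(config$traits)

  # shared standard-normal genetic scores (drawn once, fixed order)
  z_line <- sapply(tnames, function(tr) centered_norm(l))
  z_tester <- sapply(tnames, function(tr) centered_norm(t))
  z_sca <- lapply(setNames(tnames, tnames),
                  function(tr) grand_centered_norm_mat(l, t))
  z_check <- sapply(tnames, function(tr) rnorm(config$n_checks))
  if (config$n_checks == 0) z_check <- matrix(0, 0, length(tnames))

  obs_list <- list(); truth_list <- list()
  for (cond in config$conditions) {
    traits_cond <- tnames[vapply(tnames, function(tr)
      cond %in% config$traits[[tr]]$conditions, TRUE)]
    envs <- paste0(toupper(substr(cond, 1, 1)), "E", seq_len(config$n_envs))

    eff <- list()
    for (tr in traits_cond) {
      sd_l <- sqrt(cond_val(config$var_gca_line[[tr]], cond))
      sd_t <- sqrt(cond_val(config$var_gca_tester[[tr]], cond))
      sd_s <- sqrt(cond_val(config$var_sca[[tr]], cond))
      g <- z_line[, tr] * sd_l
      tt <- z_tester[, tr] * sd_t
      s <- z_sca[[tr]] * sd_s
      # GxE deviations, centered across parents within each season
      sd_ge <- sqrt(cond_val(config$var_gca_line_x_env[[tr]], cond))
      sd_te <- sqrt(cond_val(config$var_gca_tester_x_env[[tr]], cond))
      sd_se <- sqrt(cond_val(config$var_sca_x_env[[tr]], cond))
      gE <- sapply(envs, function(e) centered_norm(l) * sd_ge)
      tE <- sapply(envs, function(e) centered_norm(t) * sd_te)
      sE <- lapply(setNames(envs, envs),
                   function(e) grand_centered_norm_mat(l, t) * sd_se)
      eff[[tr]] <- list(g = g, t = tt, s = s, gE = gE, tE = tE, sE = sE)
      truth_list[[paste(cond, tr)]] <- rbind(
        data.frame(condition = cond, trait = tr, term = "gca_line",
                   parent = lines, line = NA, tester = NA, value = g),
        data.frame(condition = cond, trait = tr, term = "gca_tester",
                   parent = testers, line = NA, tester = NA, value = tt),
        data.frame(condition = cond, trait = tr, term = "sca",
                   parent = NA,
                   line = rep(lines, t), tester = rep(testers, each = l),
                   value = as.vector(s)))
    }

    # season effects are shared by the hybrid and parent trials grown in the
    # same seasons, so per-se vs testcross comparisons are on a common base
    env_effects <- vapply(traits_cond, function(tr)
      rnorm(config$n_envs, 0, sqrt(cond_val(config$var_env[[tr]], cond))),
      numeric(config$n_envs))
    if (!is.matrix(env_effects))
      env_effects <- matrix(env_effects, nrow = 1,
                            dimnames = list(NULL, traits_cond))

    obs_list[[paste0(cond, "_hyb")]] <- build_trial_plots(
      config, cond, envs, traits_cond, env_effects,
      entries = data.frame(
        genotype = c(paste(rep(lines, t), rep(testers, each = l), sep = " x "),
                     checks),
        role = c(rep("testcross", l * t), rep("check", length(checks))),
        line_parent = c(rep(lines, t), rep(NA, length(checks))),
        tester_parent = c(rep(testers, each = l), rep(NA, length(checks))),
        stringsAsFactors = FALSE),
      genetic_value = function(tr, entries, env_i) {
        e <- eff[[tr]]
        v <- numeric(nrow(entries))
        tc <- entries$role == "testcross"
        i <- match(entries$line_parent[tc], lines)
        j <- match(entries$tester_parent[tc], testers)
        v[tc] <- cond_val(config$mu[[tr]], cond) +
          e$g[i] + e$t[j] + e$s[cbind(i, j)] +
          e$gE[i, env_i] + e$tE[j, env_i] + e$sE[[env_i]][cbind(i, j)]
        ck <- entries$role == "check"
        if (any(ck))
          v[ck] <- cond_val(config$check_mu[[tr]], cond) +
            z_check[, tr] * sqrt(cond_val(config$var_check[[tr]], cond))
        v
      })

    obs_list[[paste0(cond, "_par")]] <- build_trial_plots(
      config, cond, envs, traits_cond, env_effects,
      entries = data.frame(
        genotype = c(lines, testers),
        role = c(rep("line", l), rep("tester", t)),
        line_parent = NA, tester_parent = NA, stringsAsFactors = FALSE),
      genetic_value = function(tr, entries, env_i) {
        e <- eff[[tr]]
        cond_val(config$parent_mu[[tr]], cond) + 2 * c(e$g, e$t)
      })
  }

  obs <- do.call(rbind, c(obs_list, make.row.names = FALSE))
  for (tr in tnames) {
    if (!tr %in% names(obs)) next
    v <- obs[[tr]]
    if (config$traits[[tr]]$kind == "ordinal-score")
      v <- round(pmin(pmax(v, 1), 9) / 0.1) * 0.1
    else if (config$traits[[tr]]$kind == "count-ratio")
      v <- pmax(v, 0)
    obs[[tr]] <- v
  }
  attr(obs, "traits") <- intersect(tnames, names(obs))
  truth <- do.call(rbind, c(truth_list, make.row.names = FALSE))
  list(obs = obs, truth = truth, config = config)
}

# Internal: lay one trial (one condition) out over seasons, replicates and
# incomplete blocks, add design effects and plot error.  `env_effects`
# (season x trait) is drawn by the caller so trials grown in the same
# seasons share them.
build_trial_plots <- function(config, cond, envs, traits_cond, env_effects,
                              entries, genetic_value) {
  n <- nrow(entries)
  b <- ceiling(n / config$block_size)
  out <- list()
  for (env_i in seq_along(envs)) {
    env_eff <- env_effects[env_i, traits_cond]
    gv <- sapply(traits_cond, function(tr)
      genetic_value(tr, entries, env_i))
    if (n == 1L) gv <- matrix(gv, nrow = 1)
    for (r in seq_len(config$n_reps)) {
      rep_eff <- sapply(traits_cond, function(tr)
        rnorm(1, 0, sqrt(cond_val(config$var_rep[[tr]], cond))))
      ord <- sample.int(n)
      blk <- ceiling(seq_len(n) / config$block_size)[order(ord)]
      blk_eff <- sapply(traits_cond, function(tr)
        rnorm(b, 0, sqrt(cond_val(config$var_block[[tr]], cond))))
      if (b == 1L) blk_eff <- matrix(blk_eff, nrow = 1)
      err <- sapply(traits_cond, function(tr)
        rnorm(n, 0, sqrt(cond_val(config$var_error[[tr]], cond))))
      if (n == 1L) err <- matrix(err, nrow = 1)
      d <- data.frame(condition = cond, environment = envs[env_i],
                      replicate = r, block = blk, entries,
                      stringsAsFactors = FALSE)
      for (ti in seq_along(traits_cond))
        d[[traits_cond[ti]]] <- gv[, ti] + env_eff[ti] + rep_eff[ti] +
          blk_eff[blk, ti] + err[, ti]
      out[[length(out) + 1L]] <- d
    }
  }
  res <- do.call(rbind, out)
  # traits not measured in this condition come back as NA columns so that
  # rbind across conditions lines up
  for (tr in setdiff(names(config$traits), traits_cond))
    res[[tr]] <- NA_real_
  res[, c(design_columns(), names(config$traits))]
}

#' Generate a GCA-effect table with planted heterotic groups
#'
#' Parents are assigned to \code{groups} clusters whose centroids form a
#' regular simplex with all pairwise distances equal to \code{separation}
#' within-group standard deviations, rotated by a (seeded) random
#' orthonormal basis so the group signal is spread over all trait columns
#' rather than sitting on single axes; members are the centroid plus
#' unit-variance Gaussian noise per trait.  With \code{separation = 0} the
#' labels are unrecoverable by construction.
#'
#' @param groups Number of planted groups (>= 2).
#' @param parents_per_group Parents in each group (scalar or vector of
#'   length \code{groups}).
#' @param separation Centroid separation in within-group SD units (>= 0).
#' @param traits Trait identifiers (needs at least \code{groups} of them).
#' @param seed RNG seed.
#' @return List with \code{gca} (parent x trait matrix) and \code{labels}
#'   (true group of each parent).
#' @export
make_clustered_gca <- function(groups = 3, parents_per_group = 12,
                               separation = 6,
                               traits = names(default_trait_specs()),
                               seed = 1L) {
  if (groups < 2) stop("config error: need at least 2 groups")
  if (separation < 0) stop("config error: separation must be >= 0")
  if (length(traits) < groups)
    stop("config error: need at least as many traits as groups")
  sizes <- rep_len(parents_per_group, groups)
  set.seed(as.integer(seed))
  n <- sum(sizes)
  d <- length(traits)
  labels <- rep(seq_len(groups), sizes)
  simplex <- diag(groups) * separation / sqrt(2)
  Q <- qr.Q(qr(matrix(rnorm(d * groups), d, groups)))
  centroids <- simplex %*% t(Q)       # groups x d, pairwise dist = separation
  gca <- centroids[labels, , drop = FALSE] +
    matrix(rnorm(n * d), n, d)
  dimnames(gca) <- list(sprintf("P%02d", seq_len(n)), traits)
  list(gca = gca, labels = labels)
}
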