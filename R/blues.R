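#' Adjusted genotype means (BLUEs) for one growing condition
#'
#' Fits, per trait, the fixed-effects model
#' \deqn{y = \mu + genotype + env + rep(env) + block(rep \cdot env) + \epsilon}
#' by least squares with sum-to-zero contrasts on the nuisance factors, and
#' reports each genotype's adjusted mean (intercept + genotype effect) with
#' its standard error.  On balanced data with no block/replicate structure
#' the adjusted means equal the raw genotype means; when the design is
#' singular for a trait the function falls back to raw means with a warning.
#' Missing plot values are dropped for that trait only, never imputed.
#'
#' @param obs Plot-observation data frame (see \code{\link{read_trial}}).
#' @param condition \code{"drought"} or \code{"rainfed"}.
#' @param trait_specs Named list of \code{\link{trait_spec}}.
#' @param roles Optional subset of roles to keep (default: all genotypes
#'   present, checks included).
#' @return A \code{data.frame} with columns \code{condition},
#'   \code{genotype}, \code{role}, then \code{<trait>} and \code{<trait>_se}
#'   per trait measured under the condition.
#' @export
compute_blues <- function(obs, condition,
                          trait_specs = default_trait_specs(),
                          roles = NULL) {
  stopifnot(condition %in% c("drought", "rainfed"))
  d <- obs[obs$condition == condition, , drop = FALSE]
  if (!is.null(roles)) d <- d[d$role %in% roles, , drop = FALSE]
  if (nrow(d) == 0L) stop("no observations for condition ", condition)
  if (length(unique(d$genotype)) < 2L)
    stop("need at least 2 genotypes to compute adjusted means")

  traits <- intersect(attr(obs, "traits") %||% names(trait_specs), names(d))
  traits <- traits[vapply(traits, function(tr)
    condition %in% trait_specs[[tr]]$conditions, TRUE)]

  role_of <- tapply(d$role, d$genotype, function(r) r[[1]])
  out <- data.frame(condition = condition,
                    genotype = names(role_of),
                    role = unname(role_of),
                    stringsAsFactors = FALSE)

  for (tr in traits) {
    di <- d[!is.na(d[[tr]]), , drop = FALSE]
    est <- blue_one_trait(di, tr)
    missing_g <- setdiff(out$genotype, est$genotype)
    if (length(missing_g))
      warning(sprintf("trait %s: no plots for genotype(s) %s; omitted",
                      tr, paste(missing_g, collapse = ", ")))
    idx <- match(out$genotype, est$genotype)
    out[[tr]] <- est$blue[idx]
    out[[paste0(tr, "_se")]] <- est$se[idx]
  }
  rownames(out) <- NULL
  out
}

# Internal: adjusted means for one trait on rows with observed values.
blue_one_trait <- function(di, tr) {
  g <- factor(di$genotype)
  glev <- levels(g)
  y <- di[[tr]]
  raw <- tapply(y, g, mean)
  raw_se <- tapply(y, g, function(v)
    if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_)
  raw_tab <- data.frame(genotype = glev, blue = as.numeric(raw[glev]),
                        se = as.numeric(raw_se[glev]),
                        stringsAsFactors = FALSE)

  env <- factor(di$environment)
  rep_f <- factor(paste(di$environment, di$replicate, sep = ":"))
  blk_f <- factor(paste(di$environment, di$replicate, di$block, sep = ":"))
  # no nuisance structure to adjust for -> raw means are the BLUEs
  if (nlevels(env) <= 1L && nlevels(rep_f) <= 1L && nlevels(blk_f) <= 1L)
    return(raw_tab)
  if (any(table(g) == 0L) || nlevels(g) < 2L) return(raw_tab)

  terms <- list(geno = model.matrix(~ g, contrasts.arg =
                                      list(g = "contr.sum"))[, -1, drop = FALSE])
  if (nlevels(env) > 1L)
    terms$env <- model.matrix(~ env, contrasts.arg =
                                list(env = "contr.sum"))[, -1, drop = FALSE]
  if (nlevels(rep_f) > nlevels(env))
    terms$rep <- model.matrix(~ rep_f, contrasts.arg =
                                list(rep_f = "contr.sum"))[, -1, drop = FALSE]
  if (nlevels(blk_f) > nlevels(rep_f))
    terms$blk <- model.matrix(~ blk_f, contrasts.arg =
                                list(blk_f = "contr.sum"))[, -1, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, do.call(cbind, terms))
  ng <- nlevels(g) - 1L
  fit <- lm(y ~ X - 1)
  cf <- coef(fit)
  geno_cols <- 1L + seq_len(ng)          # after intercept
  if (anyNA(cf[geno_cols]) || fit$df.residual <= 0L) {
    warning(sprintf(
      "trait %s: singular design for genotype effects; using raw means", tr))
    return(raw_tab)
  }
  keep <- !is.na(cf)
  if (!all(keep)) {                      # aliased nuisance columns: drop, refit
    X <- X[, keep, drop = FALSE]
    fit <- lm(y ~ X - 1)
    cf <- coef(fit)
  }
  # adjusted mean for genotype i: intercept + sum-contrast row for level i,
  # nuisance factors at their (zero) average
  Cg <- rbind(stats::contr.sum(nlevels(g)))
  L <- matrix(0, nrow = nlevels(g), ncol = length(cf))
  L[, 1] <- 1
  gidx <- which(startsWith(names(cf), "Xg"))
  L[, gidx] <- Cg
  blue <- drop(L %*% cf)
  # summary.lm warns on numerically perfect fits (noise-free fixtures)
  V <- suppressWarnings(vcov(fit))
  se <- sqrt(pmax(rowSums((L %*% V) * L), 0))
  data.frame(genotype = glev, blue = blue, se = se, stringsAsFactors = FALSE)
}

#' Stress penalty of a trait between growing conditions
#'
#' Per-genotype percent change from the non-stress to the stress condition,
#' computed on adjusted means.  For higher-better traits this is the percent
#' loss \eqn{100 (optimal - stress)/optimal}; for lower-better traits the
#' sign convention is inverted and the value reported as a percent increase
#' under stress.  The summary is the mean of the per-genotype percentages,
#' not the penalty of the mean values.  Genotypes with a zero value under
#' the non-stress condition are excluded with a warning (the ratio is
#' undefined).
#'
#' @param blues_stress,blues_optimal BLUE tables from
#'   \code{\link{compute_blues}} for the stress and non-stress condition.
#' @param trait Trait identifier present in both tables.
#' @param trait_specs Named list of \code{\link{trait_spec}} supplying the
#'   trait's selection direction.
#' @return List with \code{per_genotype} (genotype, stress, optimal,
#'   penalty_pct) and \code{summary} (min, max, mean of the percentages).
#' @export
stress_penalty <- function(blues_stress, blues_optimal, trait,
                           trait_specs = default_trait_specs()) {
  if (!trait %in% names(blues_stress) || !trait %in% names(blues_optimal))
    stop("trait ", trait, " absent from one of the BLUE tables")
  m <- merge(blues_stress[, c("genotype", trait)],
             blues_optimal[, c("genotype", trait)],
             by = "genotype", suffixes = c("_stress", "_optimal"))
  names(m)[2:3] <- c("stress", "optimal")
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) == 0L) stop("no genotype present in both tables with data")
  zero <- m$optimal == 0
  if (any(zero)) {
    warning("excluding genotype(s) with zero non-stress value: ",
            paste(m$genotype[zero], collapse = ", "))
    m <- m[!zero, , drop = FALSE]
  }
  dirn <- trait_specs[[trait]]$direction %||% "higher-better"
  m$penalty_pct <- if (dirn == "higher-better")
    100 * (m$optimal - m$stress) / m$optimal
  else
    100 * (m$stress - m$optimal) / m$optimal
  list(per_genotype = m,
       summary = c(min = min(m$penalty_pct), max = max(m$penalty_pct),
                   mean = mean(m$penalty_pct)))
}
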