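# End-to-end analysis: data -> BLUEs -> line x tester ANOVA -> effects ->
# variance components -> heritability -> heterosis -> heterotic grouping ->
# dendrogram comparison -> correlations, with every table written to disk
# and a manifest that makes the run reproducible.

#' Run the full line x tester analysis
#'
#' Either reads plot data from \code{input} or simulates a trial from
#' \code{config}, then runs every stage per growing condition and trait:
#' adjusted means, ANOVA with GCA/SCA partition, effect estimates,
#' method-of-moments variance components, additive/dominance variances and
#' heritability, mid-parent/better-parent/economic heterosis, HGCAMT
#' heterotic grouping (traits gated on significant genotype mean squares),
#' cross-condition dendrogram comparison, and the mid-parent vs hybrid and
#' yield vs heterosis/SCA correlation matrices.  All tables are written as
#' CSV (dendrograms as Newick) under \code{out_dir} together with a
#' manifest; identical configuration and seed give identical outputs.
#'
#' @param input Optional path to a plot-level CSV (see
#'   \code{\link{read_trial}}).  Exactly one of \code{input} /
#'   \code{config} is used.
#' @param config Optional \code{\link{sim_config}} for simulate mode
#'   (default when \code{input} is \code{NULL}).
#' @param conditions Growing conditions to analyze.
#' @param traits Trait identifiers to analyze (default: all declared).
#' @param trait_specs Named list of \code{\link{trait_spec}}.
#' @param F Parental inbreeding coefficient for
#'   \code{\link{derive_A_D}}.
#' @param k_override Optional fixed number of heterotic groups.
#' @param out_dir Output directory (created if needed); \code{NULL} skips
#'   writing.
#' @param seed Seed for any simulation randomness.
#' @return Invisibly, a list bundle with one entry per stage.
#' @export
run_pipeline <- function(input = NULL, config = NULL,
                         conditions = c("drought", "rainfed"),
                         traits = NULL,
                         trait_specs = default_trait_specs(),
                         F = 0, k_override = NULL,
                         out_dir = NULL, seed = 1L) {
  if (!is.null(input) && !is.null(config))
    stop("supply exactly one of 'input' (CSV path) or 'config' (sim_config)")
  traits <- traits %||% names(trait_specs)
  bad <- setdiff(traits, names(trait_specs))
  if (length(bad)) stop("undeclared trait(s): ", paste(bad, collapse = ", "))
  for (tr in traits)
    if (!any(conditions %in% trait_specs[[tr]]$conditions))
      stop("trait ", tr, " is only measured under ",
           paste(trait_specs[[tr]]$conditions, collapse = "/"),
           ", not under the requested condition(s)")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  obs <- stage("data", {
    if (!is.null(input)) read_trial(input, trait_specs)
    else {
      config <- config %||% sim_config(seed = seed, traits = trait_specs)
      simulate_trial(config)$obs
    }
  })

  bundle <- list(conditions = conditions, traits = traits, seed = seed)
  dends <- list()
  for (cond in conditions) {
    traits_cond <- traits[vapply(traits, function(tr)
      cond %in% trait_specs[[tr]]$conditions, TRUE)]
    res <- list()
    res$blues_hybrids <- stage(paste0("blues/", cond),
      compute_blues(obs, cond, trait_specs, roles = c("testcross", "check")))
    has_parents <- any(obs$role %in% c("line", "tester") &
                         obs$condition == cond)
    if (has_parents)
      res$blues_parents <- stage(paste0("blues-parents/", cond),
        compute_blues(obs, cond, trait_specs, roles = c("line", "tester")))

    res$anova <- res$effects <- res$components <- list()
    genpar <- list()
    for (tr in traits_cond) {
      an <- stage(paste0("anova/", cond, "/", tr),
                  fit_linetester_anova(obs, cond, tr))
      res$anova[[tr]] <- an
      res$effects[[tr]] <- stage(paste0("effects/", cond, "/", tr),
                                 estimate_effects(obs, cond, tr))
      comp <- stage(paste0("components/", cond, "/", tr),
                    estimate_components(an))
      res$components[[tr]] <- comp
      ad <- derive_A_D(comp, F = F)
      s2e <- derive_sigma2_E(an)
      h <- heritability(ad[["sigma2_A"]], ad[["sigma2_D"]], s2e)
      genpar[[tr]] <- data.frame(
        trait = tr, condition = cond,
        sigma2_gca_line = comp$sigma2_gca_line,
        sigma2_gca_tester = comp$sigma2_gca_tester,
        sigma2_sca = comp$sigma2_sca,
        sigma2_A = ad[["sigma2_A"]], sigma2_D = ad[["sigma2_D"]],
        sigma2_E = s2e, H2 = h[["H2"]], h2 = h[["h2"]],
        stringsAsFactors = FALSE)
    }
    res$genetic_parameters <- do.call(rbind, genpar)
    rownames(res$genetic_parameters) <- NULL

    # HGCAMT grouping on traits with significant genotype mean squares
    sig_traits <- names(Filter(function(an) {
      p <- an$p[match("GENOTYPES", an$source)]
      !is.na(p) && p < 0.05
    }, res$anova))
    res$significant_traits <- sig_traits
    if (length(sig_traits) >= 1L) {
      gca_mat <- sapply(sig_traits, function(tr) {
        e <- res$effects[[tr]]
        setNames(c(e$gca_line$effect, e$gca_tester$effect),
                 c(e$gca_line$parent, e$gca_tester$parent))
      })
      grp <- stage(paste0("grouping/", cond), {
        z <- standardize_gca(gca_mat)
        dend <- ward_cluster(z)
        sel <- select_k(dend, z, override = k_override)
        list(z = z, dendrogram = dend, k = sel$k, votes = sel$votes,
             groups = sel$groups)
      })
      res$grouping <- grp
      dends[[cond]] <- grp$dendrogram
    }

    # heterosis needs parent per-se values
    if (has_parents) {
      ped <- unique(obs[obs$role == "testcross",
                        c("genotype", "line_parent", "tester_parent")])
      res$heterosis <- stage(paste0("heterosis/", cond), {
        recs <- do.call(rbind, lapply(traits_cond, function(tr)
          heterosis_table(res$blues_hybrids, res$blues_parents, ped, tr)))
        recs
      })
      res$heterosis_summary <- heterosis_summary(res$heterosis)
      checks <- unique(obs$genotype[obs$role == "check"])
      if (length(checks) && "GY" %in% traits_cond)
        res$economic_heterosis <- stage(paste0("economic-heterosis/", cond),
          economic_heterosis(res$blues_hybrids, checks, "GY"))
      res$midparent_correlations <- stage(paste0("correlations/", cond),
        midparent_hybrid_correlations(res$blues_hybrids, res$blues_parents,
                                      ped, traits_cond))
      if ("GY" %in% traits_cond)
        res$f1_correlations <- stage(paste0("f1-correlations/", cond),
          f1_heterosis_correlations(
            res$heterosis[res$heterosis$trait == "GY", ],
            res$effects[["GY"]], ped))
    }
    bundle[[cond]] <- res
  }

  if (length(dends) == 2L)
    bundle$dendrogram_comparison <- stage("compare-dendrograms",
      compare_dendrograms(dends[[1]], dends[[2]]))

  if (!is.null(out_dir)) write_bundle(bundle, out_dir, obs)
  invisible(bundle)
}

# Internal: write every table of a pipeline bundle as CSV/Newick plus a
# plain-text manifest.
write_bundle <- function(bundle, out_dir, obs) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) write.csv(x, file.path(out_dir, name),
                                    row.names = FALSE, na = "")
  for (cond in bundle$conditions) {
    res <- bundle[[cond]]
    if (is.null(res)) next
    wr(res$blues_hybrids, sprintf("blues_hybrids_%s.csv", cond))
    if (!is.null(res$blues_parents))
      wr(res$blues_parents, sprintf("blues_parents_%s.csv", cond))
    an_all <- do.call(rbind, lapply(names(res$anova), function(tr)
      cbind(trait = tr, as.data.frame(res$anova[[tr]]))))
    wr(an_all, sprintf("anova_%s.csv", cond))
    wr(res$genetic_parameters, sprintf("genetic_parameters_%s.csv", cond))
    eff_all <- do.call(rbind, lapply(names(res$effects), function(tr) {
      e <- res$effects[[tr]]
      rbind(cbind(trait = tr, term = "gca_line", e$gca_line),
            cbind(trait = tr, term = "gca_tester", e$gca_tester))
    }))
    wr(eff_all, sprintf("gca_effects_%s.csv", cond))
    if (!is.null(res$heterosis))
      wr(res$heterosis, sprintf("heterosis_%s.csv", cond))
    if (!is.null(res$heterosis_summary))
      wr(res$heterosis_summary, sprintf("heterosis_summary_%s.csv", cond))
    if (!is.null(res$economic_heterosis))
      wr(res$economic_heterosis$table,
         sprintf("economic_heterosis_%s.csv", cond))
    if (!is.null(res$grouping)) {
      wr(data.frame(parent = names(res$grouping$groups),
                    condition = cond,
                    cluster = as.integer(res$grouping$groups)),
         sprintf("heterotic_groups_%s.csv", cond))
      write_dendrogram_newick(res$grouping$dendrogram,
                              file.path(out_dir,
                                        sprintf("dendrogram_%s.nwk", cond)))
    }
  }
  if (!is.null(bundle$dendrogram_comparison))
    wr(as.data.frame(bundle$dendrogram_comparison[
      c("cophenetic_correlation", "n_matched_leaves", "entanglement",
        "shared_leaves")]), "dendrogram_comparison.csv")
  manifest <- c(
    sprintf("linetester version: %s",
            as.character(utils::packageVersion("linetester"))),
    sprintf("R version: %s", R.version.string),
    sprintf("seed: %s", bundle$seed),
    sprintf("conditions: %s", paste(bundle$conditions, collapse = ", ")),
    sprintf("traits: %s", paste(bundle$traits, collapse = ", ")),
    sprintf("n plots: %d", nrow(obs)),
    sprintf("generated: deterministic given config + seed"))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
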