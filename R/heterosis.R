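# Mid-parent, better-parent and economic heterosis on adjusted means.

#' Per-hybrid heterosis relative to the parents
#'
#' For each hybrid with both parents present:
#' \deqn{MP = (P_1 + P_2)/2, \quad MPH = 100\,(F_1 - MP)/MP, \quad
#'       BPH = 100\,(F_1 - BP)/BP}
#' where by default \eqn{BP = \max(P_1, P_2)} regardless of the trait's
#' selection direction (matching the usual reporting convention); with
#' \code{direction_aware = TRUE} the better parent is the smaller value for
#' lower-better traits.  Percentages are \code{NA} where their denominator
#' is zero.
#'
#' @param hybrid_blues BLUE table (\code{\link{compute_blues}}) holding the
#'   hybrids.
#' @param parent_blues BLUE table holding the parents.
#' @param pedigree Data frame with columns \code{genotype},
#'   \code{line_parent}, \code{tester_parent} (one row per hybrid).
#' @param trait Trait identifier.
#' @param direction_aware Use the trait's declared direction to pick the
#'   better parent.
#' @param trait_specs Trait specifications (used when
#'   \code{direction_aware}).
#' @return Data frame with columns \code{hybrid}, \code{trait}, \code{F1},
#'   \code{P1}, \code{P2}, \code{MP}, \code{BP}, \code{MPH}, \code{BPH}.
#' @export
heterosis_table <- function(hybrid_blues, parent_blues, pedigree, trait,
                            direction_aware = FALSE,
                            trait_specs = default_trait_specs()) {
  pv <- setNames(parent_blues[[trait]], parent_blues$genotype)
  hv <- setNames(hybrid_blues[[trait]], hybrid_blues$genotype)
  recs <- list()
  for (i in seq_len(nrow(pedigree))) {
    hyb <- pedigree$genotype[i]
    p1n <- pedigree$line_parent[i]; p2n <- pedigree$tester_parent[i]
    if (!hyb %in% names(hv)) next
    if (!p1n %in% names(pv) || !p2n %in% names(pv)) {
      warning("missing parent value for hybrid ", hyb, "; skipped")
      next
    }
    f1 <- hv[[hyb]]; p1 <- pv[[p1n]]; p2 <- pv[[p2n]]
    if (anyNA(c(f1, p1, p2))) next
    mp <- (p1 + p2) / 2
    lower_better <- direction_aware &&
      (trait_specs[[trait]]$direction %||% "higher-better") == "lower-better"
    bp <- if (lower_better) min(p1, p2) else max(p1, p2)
    recs[[length(recs) + 1L]] <- data.frame(
      hybrid = hyb, trait = trait, F1 = f1, P1 = p1, P2 = p2,
      MP = mp, BP = bp,
      MPH = if (mp != 0) 100 * (f1 - mp) / mp else NA_real_,
      BPH = if (bp != 0) 100 * (f1 - bp) / bp else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(recs)) stop("no hybrid had both parents present")
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Economic heterosis over the best commercial check
#'
#' \eqn{EH = 100\,(F_1 - BCC)/BCC} with \eqn{BCC} the best (largest) check
#' mean.  Hybrids are returned ranked by EH, together with the subset that
#' beats the best check.
#'
#' @param hybrid_blues BLUE table holding testcross hybrids and checks (or
#'   only hybrids, with checks found via \code{checks}).
#' @param checks Character vector of check genotype identifiers.
#' @param trait Trait identifier.
#' @return List with \code{bcc} (best check value), \code{best_check},
#'   \code{table} (hybrid, value, EH_pct, ranked descending), and
#'   \code{n_above_check}.
#' @export
economic_heterosis <- function(hybrid_blues, checks, trait) {
  v <- setNames(hybrid_blues[[trait]], hybrid_blues$genotype)
  cv <- v[names(v) %in% checks]
  cv <- cv[is.finite(cv)]
  if (!length(cv)) stop("no check with a finite value for ", trait)
  bcc <- max(cv)
  if (bcc <= 0) stop("best check value is not positive; economic heterosis undefined")
  hyb <- v[!names(v) %in% checks]
  hyb <- hyb[is.finite(hyb)]
  tab <- data.frame(hybrid = names(hyb), value = as.numeric(hyb),
                    EH_pct = 100 * (as.numeric(hyb) - bcc) / bcc,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$EH_pct), , drop = FALSE]
  rownames(tab) <- NULL
  list(bcc = bcc, best_check = names(cv)[which.max(cv)], table = tab,
       n_above_check = sum(tab$EH_pct > 0))
}

#' Study-level heterosis summary
#'
#' Arithmetic means of the per-hybrid mid-parent and better-parent
#' heterosis percentages over hybrids with defined values (hybrids whose
#' denominators were zero are excluded and counted).
#'
#' @param records Output of \code{\link{heterosis_table}} (possibly several
#'   traits row-bound).
#' @return Data frame per trait: \code{mean_MPH}, \code{mean_BPH},
#'   \code{n}, \code{n_excluded}.
#' @export
heterosis_summary <- function(records) {
  if (nrow(records) == 0L) stop("no heterosis records")
  out <- lapply(split(records, records$trait), function(d) {
    data.frame(trait = d$trait[1],
               mean_MPH = mean(d$MPH, na.rm = TRUE),
               mean_BPH = mean(d$BPH, na.rm = TRUE),
               n = sum(!is.na(d$MPH)),
               n_excluded = sum(is.na(d$MPH) | is.na(d$BPH)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
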