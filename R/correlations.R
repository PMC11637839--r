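# Inter-trait correlation analyses: mid-parent values vs hybrid means, and
# hybrid grain yield vs parent-derived quantities and SCA effects.

# Internal: Pearson correlation matrix with t-test p-values,
# pairwise-complete observations. x and y are numeric matrices whose rows
# line up.
cor_matrix_tested <- function(x, y) {
  r <- p <- nmat <- matrix(NA_real_, ncol(x), ncol(y),
                           dimnames = list(colnames(x), colnames(y)))
  for (i in seq_len(ncol(x))) for (j in seq_len(ncol(y))) {
    ok <- is.finite(x[, i]) & is.finite(y[, j])
    n <- sum(ok)
    nmat[i, j] <- n
    if (n < 3L) next
    if (sd(x[ok, i]) == 0 || sd(y[ok, j]) == 0) next
    rij <- cor(x[ok, i], y[ok, j])
    r[i, j] <- rij
    tt <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
    p[i, j] <- 2 * pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = nmat, sig = matrix(sig_code_cor(p), nrow(p),
                                            dimnames = dimnames(p)))
}

#' Correlations between mid-parent trait values and hybrid trait means
#'
#' For each hybrid, the mid-parent value \eqn{(P_1 + P_2)/2} of every trait
#' is paired with the hybrid's adjusted means; the full rectangular Pearson
#' matrix (hybrid traits in rows, mid-parent traits in columns) is returned
#' with two-sided t-test p-values over pairwise-complete hybrids.  The
#' diagonal holds the same-trait parent-offspring correlations.  Cells with
#' fewer than 3 complete pairs (or a constant margin) are \code{NA} with a
#' warning.
#'
#' @param hybrid_blues,parent_blues BLUE tables
#'   (\code{\link{compute_blues}}).
#' @param pedigree Data frame with \code{genotype}, \code{line_parent},
#'   \code{tester_parent}.
#' @param traits Trait identifiers to include.
#' @return List of class \code{mp_cor} with matrices \code{r}, \code{p},
#'   \code{n}, \code{sig}.
#' @export
midparent_hybrid_correlations <- function(hybrid_blues, parent_blues,
                                          pedigree, traits) {
  traits <- intersect(traits, intersect(names(hybrid_blues),
                                        names(parent_blues)))
  if (!length(traits)) stop("no shared trait columns")
  hyb <- pedigree$genotype[pedigree$genotype %in% hybrid_blues$genotype]
  hi <- match(hyb, hybrid_blues$genotype)
  p1 <- match(pedigree$line_parent[match(hyb, pedigree$genotype)],
              parent_blues$genotype)
  p2 <- match(pedigree$tester_parent[match(hyb, pedigree$genotype)],
              parent_blues$genotype)
  H <- as.matrix(hybrid_blues[hi, traits, drop = FALSE])
  MP <- (as.matrix(parent_blues[p1, traits, drop = FALSE]) +
           as.matrix(parent_blues[p2, traits, drop = FALSE])) / 2
  colnames(H) <- colnames(MP) <- traits
  out <- cor_matrix_tested(H, MP)
  if (any(out$n < 3))
    warning("some cells have fewer than 3 complete hybrid-midparent pairs")
  structure(out, class = "mp_cor")
}

#' Correlations of hybrid yield with parent values, heterosis and SCA
#'
#' The full pairwise Pearson matrix among the hybrid's trait value
#' (\code{F1}), better-parent value (\code{BP}), mid-parent value
#' (\code{MP}), mid-parent heterosis (\code{MPH}), better-parent heterosis
#' (\code{BPH}) and the hybrid's SCA effect, with significance codes.
#'
#' @param records Heterosis records from \code{\link{heterosis_table}} for
#'   one trait.
#' @param effects An \code{lt_effects} object supplying the SCA effects,
#'   or \code{NULL} to omit the SCA column.
#' @param pedigree Data frame mapping hybrids to parents (needed to look up
#'   SCA effects); defaults to parsing is not attempted — supply it when
#'   \code{effects} is given.
#' @return List of class \code{mp_cor} with matrices \code{r}, \code{p},
#'   \code{n}, \code{sig}.
#' @export
f1_heterosis_correlations <- function(records, effects = NULL,
                                      pedigree = NULL) {
  m <- records[, c("F1", "BP", "MP", "MPH", "BPH")]
  if (!is.null(effects)) {
    if (is.null(pedigree))
      stop("pedigree required to attach SCA effects")
    ped <- pedigree[match(records$hybrid, pedigree$genotype), ]
    key <- paste(effects$sca$line, effects$sca$tester)
    sca <- effects$sca$effect[match(paste(ped$line_parent, ped$tester_parent),
                                    key)]
    if (anyNA(sca))
      stop("hybrid(s) without a defined SCA effect: ",
           paste(records$hybrid[is.na(sca)][1:min(3, sum(is.na(sca)))],
                 collapse = ", "))
    m$SCA <- sca
  }
  m <- as.matrix(m)
  structure(cor_matrix_tested(m, m), class = "mp_cor")
}

#' @export
print.mp_cor <- function(x, digits = 2, ...) {
  out <- matrix(paste0(format(round(x$r, digits)),
                       ifelse(x$sig == "ns", "", x$sig)),
                nrow(x$r), dimnames = dimnames(x$r))
  print(out, quote = FALSE)
  invisible(x)
}
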