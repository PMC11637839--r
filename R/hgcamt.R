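# Heterotic grouping from the GCA of multiple traits (HGCAMT):
# Z-score the GCA effects of the traits with significant genotype mean
# squares, take Euclidean distances over parents, cluster with Ward.D2,
# pick the cluster count, and compare groupings across growing conditions.

#' Z-score a parent x trait GCA-effect table
#'
#' Each retained trait column is standardized to mean 0, sample SD 1
#' (\code{n - 1} denominator) over parents, making traits with different
#' scales comparable.  Only traits named in \code{significant_traits} are
#' kept; constant (zero-SD) columns cannot be standardized and are dropped
#' with a warning.
#'
#' @param gca Numeric matrix or data frame, parents in rows (rownames),
#'   traits in columns.
#' @param significant_traits Traits to retain (default: all columns).
#' @return Matrix of class \code{hgcamt_z} with the retained Z-scored
#'   columns.
#' @export
standardize_gca <- function(gca, significant_traits = colnames(gca)) {
  gca <- as.matrix(gca)
  if (nrow(gca) < 2L) stop("need at least 2 parents")
  keep <- intersect(significant_traits, colnames(gca))
  if (!length(keep)) stop("no retained trait column present in the GCA table")
  gca <- gca[, keep, drop = FALSE]
  sds <- apply(gca, 2, sd)
  if (any(sds == 0 | is.na(sds))) {
    drop <- colnames(gca)[sds == 0 | is.na(sds)]
    warning("dropping constant trait column(s): ",
            paste(drop, collapse = ", "))
    gca <- gca[, !(colnames(gca) %in% drop), drop = FALSE]
    if (!ncol(gca)) stop("no non-constant trait column left to standardize")
  }
  z <- scale(gca)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  class(z) <- c("hgcamt_z", class(z))
  z
}

#' Ward.D2 clustering of standardized GCA profiles
#'
#' Euclidean distances between parents, agglomerated with the Ward.D2
#' criterion (distances squared inside the criterion, merge heights on the
#' unsquared scale, so two singletons at distance d merge at height d).
#' Heights are non-decreasing along the merge sequence.
#'
#' @param z Standardized matrix from \code{\link{standardize_gca}} (any
#'   numeric parent x trait matrix is accepted).
#' @return An object of class \code{hgcamt_dend}: the \code{hclust} tree
#'   plus the cophenetic distance matrix.
#' @export
ward_cluster <- function(z) {
  z <- unclass(as.matrix(z))
  if (!all(is.finite(z))) stop("non-finite values in the standardized matrix")
  if (nrow(z) < 2L) stop("need at least 2 parents")
  hc <- hclust(dist(z, method = "euclidean"), method = "ward.D2")
  structure(list(hclust = hc, labels = hc$labels,
                 cophenetic = as.matrix(cophenetic(hc))),
            class = "hgcamt_dend")
}

#' @export
print.hgcamt_dend <- function(x, ...) {
  cat(sprintf("<hgcamt_dend> Ward.D2 tree on %d parents (max height %.3f)\n",
              length(x$labels), max(x$hclust$height)))
  invisible(x)
}

#' Cut a dendrogram into k groups
#'
#' @param dend An \code{hgcamt_dend}.
#' @param k Number of groups.
#' @return Named integer vector of cluster memberships.
#' @export
cut_groups <- function(dend, k) cutree(dend$hclust, k = k)

# Internal: total within-cluster sum of squares of a partition.
within_ss <- function(z, part) {
  sum(vapply(split(seq_len(nrow(z)), part), function(ix) {
    m <- colMeans(z[ix, , drop = FALSE])
    sum(sweep(z[ix, , drop = FALSE], 2, m)^2)
  }, 0))
}

#' Choose the number of heterotic groups
#'
#' Three internal indices each cast a vote over \code{k_range}: mean
#' silhouette width (maximized), the Calinski-Harabasz pseudo-F
#' (maximized), and the within-SS elbow (largest second difference of the
#' total within-cluster sum of squares).  The majority wins; ties break
#' toward the smaller k.  An explicit \code{override} bypasses the vote
#' (useful to impose a known group count).
#'
#' @param dend An \code{hgcamt_dend}.
#' @param z The matrix the tree was built from.
#' @param k_range Candidate counts (clipped to \code{2..n-1}).
#' @param override Optional fixed k.
#' @return List with \code{k}, \code{votes} (per-index choice) and
#'   \code{groups} (membership at the chosen k).
#' @export
select_k <- function(dend, z, k_range = 2:10, override = NULL) {
  z <- unclass(as.matrix(z))
  n <- nrow(z)
  k_range <- sort(unique(pmin(pmax(k_range, 2L), max(n - 1L, 2L))))
  if (n < 4L) k_range <- 2L
  if (!is.null(override)) {
    k <- as.integer(override)
    return(list(k = k, votes = c(override = k),
                groups = cut_groups(dend, k)))
  }
  dmat <- dist(z)
  ks <- k_range
  sil <- ch <- wss <- setNames(rep(NA_real_, length(ks)), ks)
  for (i in seq_along(ks)) {
    part <- cutree(dend$hclust, k = ks[i])
    if (length(unique(part)) < 2L) next
    sil[i] <- mean(cluster::silhouette(part, dmat)[, "sil_width"])
    w <- within_ss(z, part)
    tot <- within_ss(z, rep(1L, n))
    ch[i] <- ((tot - w) / (ks[i] - 1)) / (w / (n - ks[i]))
    wss[i] <- w
  }
  vote_sil <- ks[which.max(sil)]
  vote_ch <- ks[which.max(ch)]
  # elbow: largest drop-off in the within-SS decrease
  vote_elbow <- if (length(ks) >= 3L) {
    d2 <- diff(diff(wss))
    ks[which.max(d2) + 1L]
  } else ks[1L]
  votes <- c(silhouette = vote_sil, calinski_harabasz = vote_ch,
             elbow = vote_elbow)
  tally <- table(votes)
  winners <- as.integer(names(tally)[tally == max(tally)])
  k <- min(winners)
  list(k = k, votes = votes, groups = cut_groups(dend, k))
}

# Internal: leaf order with the smaller subtree placed first at every
# internal node (ties: the subtree containing the smallest original leaf
# index first). Deterministic, so order-based comparison metrics are
# reproducible.
canonical_leaf_order <- function(dend) {
  hc <- dend$hclust
  n <- length(hc$labels %||% hc$order)
  rec <- function(node) {
    if (node < 0) return(-node)
    left <- rec(hc$merge[node, 1])
    right <- rec(hc$merge[node, 2])
    swap <- length(right) < length(left) ||
      (length(right) == length(left) && min(right) < min(left))
    if (swap) c(right, left) else c(left, right)
  }
  idx <- rec(nrow(hc$merge))
  (hc$labels %||% as.character(seq_len(n)))[idx]
}

#' Compare two dendrograms built on (partly) shared parents
#'
#' Restricted to the shared leaves: the Pearson correlation between the two
#' cophenetic distance matrices; the number of leaves occupying the same
#' position under the two canonical leaf orders (smaller subtree first);
#' and an entanglement score in [0, 1] — the mean absolute displacement of
#' each shared leaf's rank between the two orders, normalized by its
#' maximum (0 for identical orders, 1 for a full reversal).
#'
#' @param d1,d2 \code{hgcamt_dend} objects.
#' @return List with \code{cophenetic_correlation},
#'   \code{n_matched_leaves}, \code{entanglement} and \code{shared_leaves}.
#' @export
compare_dendrograms <- function(d1, d2) {
  shared <- intersect(d1$labels, d2$labels)
  if (length(shared) < 3L) stop("need at least 3 shared leaves")
  c1 <- d1$cophenetic[shared, shared]
  c2 <- d2$cophenetic[shared, shared]
  lower <- lower.tri(c1)
  r <- cor(c1[lower], c2[lower])
  o1 <- canonical_leaf_order(d1); o1 <- o1[o1 %in% shared]
  o2 <- canonical_leaf_order(d2); o2 <- o2[o2 %in% shared]
  pos1 <- match(shared, o1); pos2 <- match(shared, o2)
  n <- length(shared)
  disp <- sum(abs(pos1 - pos2))
  max_disp <- floor(n^2 / 2)
  list(cophenetic_correlation = r,
       n_matched_leaves = sum(pos1 == pos2),
       entanglement = disp / max_disp,
       shared_leaves = n)
}

#' Export a dendrogram to Newick
#'
#' Merge heights become branch lengths (ultrametric tree).
#'
#' @param dend An \code{hgcamt_dend}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(dend$hclust), file = path)
  invisible(path)
}
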