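# Line x tester analysis of variance and combining-ability estimation.
#
# The observation model is
#   y_ijkr = mu + E_k + R(E)_kr + g_i + t_j + s_ij
#            + (gE)_ik + (tE)_jk + (sE)_ijk + e_ijkr
# for line i, tester j, season k, replicate r.  All sums of squares are the
# standard balanced factorial quantities on cell means; the genotype sum of
# squares is partitioned exactly into GCA(line) + GCA(tester) + SCA.  When
# the plots carry incomplete-block information, a BLOCK(E:REP) row
# (sequential after E and REP(E)) absorbs block-to-block variation and the
# residual is obtained by subtraction, reproducing the residual degrees of
# freedom of a lattice analysis.

anova_sources <- function() c(
  "E", "REP(E)", "BLOCK(E:REP)", "GENOTYPES", "LINE (GCA Line)",
  "TESTER (GCA Tester)", "LINE x TESTER (SCA)", "GENOTYPES x E",
  "GCA LINE x E", "GCA TESTER x E", "LINE x TESTER x E", "Residuals")

#' Line x tester ANOVA for one trait under one growing condition
#'
#' Requires balanced testcross data: every line x tester x season x
#' replicate cell observed exactly once for the trait (checks and any other
#' non-testcross entries are excluded first).  Sums of squares follow the
#' balanced factorial formulas on cell totals; the genotype line is
#' partitioned exactly into GCA(line), GCA(tester) and SCA, and the
#' genotype-by-season line into the corresponding interactions.  F tests
#' use the residual mean square for every source by default; set
#' \code{denominator = "interaction"} to test each main genetic source
#' against its own season interaction instead.
#'
#' @param obs Plot observations (see \code{\link{read_trial}}).
#' @param condition \code{"drought"} or \code{"rainfed"}.
#' @param trait Trait identifier.
#' @param denominator \code{"residual"} (default) or \code{"interaction"}.
#' @return A \code{data.frame} of class \code{lt_anova} with columns
#'   \code{source}, \code{df}, \code{sum_sq}, \code{mean_square}, \code{F},
#'   \code{p}, \code{sig}; the design counts (replicates \code{r}, seasons
#'   \code{e}, lines \code{l}, testers \code{t}) are stored as the
#'   \code{"design"} attribute.
#' @export
fit_linetester_anova <- function(obs, condition, trait,
                                 denominator = c("residual", "interaction")) {
  denominator <- match.arg(denominator)
  d <- obs[obs$condition == condition & obs$role == "testcross", , drop = FALSE]
  d <- d[!is.na(d[[trait]]), , drop = FALSE]
  if (nrow(d) == 0L) stop("no testcross observations for ", trait,
                          " under ", condition)
  li <- factor(d$line_parent); tj <- factor(d$tester_parent)
  ek <- factor(d$environment); rr <- factor(d$replicate)
  l <- nlevels(li); t <- nlevels(tj); e <- nlevels(ek); r <- nlevels(rr)
  cell <- table(li, tj, ek, rr)
  if (any(cell != 1L)) {
    bad <- which(cell != 1L, arr.ind = TRUE)
    bad <- bad[seq_len(min(nrow(bad), 5L)), , drop = FALSE]
    stop("unbalanced testcross data for ", trait, " under ", condition,
         "; first offending cells (line, tester, env, rep): ",
         paste(apply(bad, 1, function(ix) paste0(
           "(", levels(li)[ix[1]], ", ", levels(tj)[ix[2]], ", ",
           levels(ek)[ix[3]], ", ", levels(rr)[ix[4]], ")")),
           collapse = " "))
  }
  if (e < 2) warning("fewer than 2 seasons: season and GxE rows omitted")
  y <- d[[trait]]
  m <- mean(y)
  N <- length(y)
  mi <- tapply(y, li, mean); mj <- tapply(y, tj, mean)
  mk <- tapply(y, ek, mean)
  mij <- tapply(y, list(li, tj), mean)
  mik <- tapply(y, list(li, ek), mean)
  mjk <- tapply(y, list(tj, ek), mean)
  mkr <- tapply(y, list(ek, rr), mean)
  mijk <- tapply(y, list(li, tj, ek), mean)

  ss <- list()
  df <- list()
  ss$L <- t * e * r * sum((mi - m)^2);            df$L <- l - 1
  ss$T <- l * e * r * sum((mj - m)^2);            df$T <- t - 1
  ss$LT <- e * r * sum((sweep(sweep(mij, 1, mi), 2, mj) + m)^2)
  df$LT <- (l - 1) * (t - 1)
  ss$G <- ss$L + ss$T + ss$LT;                    df$G <- l * t - 1
  if (e >= 2) {
    ss$E <- l * t * r * sum((mk - m)^2);          df$E <- e - 1
    ss$REP <- l * t * sum(sweep(mkr, 1, mk)^2);   df$REP <- e * (r - 1)
    ss$LE <- t * r * sum((sweep(sweep(mik, 1, mi), 2, mk) + m)^2)
    df$LE <- (l - 1) * (e - 1)
    ss$TE <- l * r * sum((sweep(sweep(mjk, 1, mj), 2, mk) + m)^2)
    df$TE <- (t - 1) * (e - 1)
    resijk <- mijk
    for (i in seq_len(l)) for (j in seq_len(t)) for (k in seq_len(e))
      resijk[i, j, k] <- mijk[i, j, k] - mij[i, j] - mik[i, k] - mjk[j, k] +
        mi[i] + mj[j] + mk[k] - m
    ss$LTE <- r * sum(resijk^2); df$LTE <- (l - 1) * (t - 1) * (e - 1)
    ss$GE <- ss$LE + ss$TE + ss$LTE;              df$GE <- (l * t - 1) * (e - 1)
  } else {
    ss$REP <- l * t * sum(sweep(mkr, 1, mk)^2)
    df$REP <- e * (r - 1)
    if (r < 2) { ss$REP <- NULL; df$REP <- NULL }
  }

  # incomplete blocks: sequential SS after season and replicate
  has_blocks <- "block" %in% names(d) &&
    any(tapply(d$block, list(d$environment, d$replicate),
               function(b) length(unique(b))) > 1, na.rm = TRUE)
  if (has_blocks) {
    kr <- interaction(ek, rr, drop = TRUE)
    krb <- interaction(ek, rr, d$block, drop = TRUE)
    mkrb <- tapply(y, krb, mean)
    nkrb <- tapply(y, krb, length)
    parent_kr <- tapply(as.character(kr), krb, `[`, 1)
    m_parent <- tapply(y, kr, mean)[parent_kr]
    ss$BLK <- sum(nkrb * (mkrb - m_parent)^2)
    df$BLK <- nlevels(krb) - nlevels(kr)
  }

  ss$TOT <- sum((y - m)^2)
  used <- setdiff(names(ss), c("TOT", "G", "GE"))
  ss$RES <- max(ss$TOT - sum(unlist(ss[used])), 0)
  df$RES <- N - 1 - sum(unlist(df[setdiff(names(df), c("G", "GE"))]))

  order_keys <- c(E = "E", REP = "REP(E)", BLK = "BLOCK(E:REP)",
                  G = "GENOTYPES", L = "LINE (GCA Line)",
                  T = "TESTER (GCA Tester)", LT = "LINE x TESTER (SCA)",
                  GE = "GENOTYPES x E", LE = "GCA LINE x E",
                  TE = "GCA TESTER x E", LTE = "LINE x TESTER x E",
                  RES = "Residuals")
  keys <- names(order_keys)[names(order_keys) %in% names(ss)]
  tab <- data.frame(source = unname(order_keys[keys]),
                    df = unlist(df[keys], use.names = FALSE),
                    sum_sq = unlist(ss[keys], use.names = FALSE),
                    stringsAsFactors = FALSE)
  tab$mean_square <- ifelse(tab$df > 0, tab$sum_sq / tab$df, NA_real_)
  ms_res <- tab$mean_square[tab$source == "Residuals"]
  df_res <- tab$df[tab$source == "Residuals"]

  den_ms <- rep(ms_res, nrow(tab)); den_df <- rep(df_res, nrow(tab))
  if (denominator == "interaction" && e >= 2) {
    map <- c("LINE (GCA Line)" = "GCA LINE x E",
             "TESTER (GCA Tester)" = "GCA TESTER x E",
             "LINE x TESTER (SCA)" = "LINE x TESTER x E",
             "GENOTYPES" = "GENOTYPES x E")
    for (src in names(map)) {
      i <- match(src, tab$source); j <- match(map[[src]], tab$source)
      den_ms[i] <- tab$mean_square[j]; den_df[i] <- tab$df[j]
    }
  }
  ok <- !is.na(tab$mean_square) & !is.na(den_ms) & den_ms > 0 &
    tab$source != "Residuals" & tab$df > 0
  tab$F <- ifelse(ok, tab$mean_square / den_ms, NA_real_)
  tab$p <- ifelse(ok, pf(tab$mean_square / den_ms, tab$df, den_df,
                         lower.tail = FALSE), NA_real_)
  tab$sig <- sig_code(tab$p)
  attr(tab, "design") <- c(r = r, e = e, l = l, t = t)
  attr(tab, "trait") <- trait
  attr(tab, "condition") <- condition
  class(tab) <- c("lt_anova", "data.frame")
  tab
}

#' @export
print.lt_anova <- function(x, ...) {
  cat(sprintf("Line x tester ANOVA: %s under %s\n",
              attr(x, "trait"), attr(x, "condition")))
  print.data.frame(format(as.data.frame(x), digits = 6), row.names = FALSE)
  invisible(x)
}

#' GCA and SCA effects from testcross means
#'
#' Over testcross means pooled across seasons and replicates:
#' \eqn{\hat g_i = \bar y_{i..} - \bar y_{...}},
#' \eqn{\hat t_j = \bar y_{.j.} - \bar y_{...}},
#' \eqn{\hat s_{ij} = \bar y_{ij} - \bar y_{i..} - \bar y_{.j.} + \bar y_{...}}.
#' Standard errors use the residual mean square of the line x tester ANOVA
#' with the effect's replication count (\eqn{\sqrt{MS_e/(r e t)}} for line
#' GCA, \eqn{\sqrt{MS_e/(r e l)}} for tester GCA, \eqn{\sqrt{MS_e/(r e)}}
#' for SCA); two-sided t tests on the residual degrees of freedom.
#'
#' @inheritParams fit_linetester_anova
#' @return List of class \code{lt_effects}: \code{gca_line},
#'   \code{gca_tester} (parent, effect, se, t, p, sig), \code{sca} (line,
#'   tester, effect, se, t, p, sig), \code{grand_mean}, \code{design}.
#' @export
estimate_effects <- function(obs, condition, trait) {
  an <- fit_linetester_anova(obs, condition, trait)
  dsn <- attr(an, "design")
  d <- obs[obs$condition == condition & obs$role == "testcross", , drop = FALSE]
  d <- d[!is.na(d[[trait]]), , drop = FALSE]
  li <- factor(d$line_parent); tj <- factor(d$tester_parent)
  y <- d[[trait]]
  m <- mean(y)
  mi <- tapply(y, li, mean); mj <- tapply(y, tj, mean)
  mij <- tapply(y, list(li, tj), mean)
  g <- mi - m; tt <- mj - m
  s <- sweep(sweep(mij, 1, mi), 2, mj) + m
  ms_res <- an$mean_square[an$source == "Residuals"]
  df_res <- an$df[an$source == "Residuals"]
  re <- dsn[["r"]] * dsn[["e"]]
  mk_tab <- function(effect, se, ids) {
    tstat <- if (is.finite(se) && se > 0) effect / se else rep(NA_real_,
                                                              length(effect))
    p <- if (df_res > 0) 2 * pt(abs(tstat), df_res, lower.tail = FALSE)
         else rep(NA_real_, length(effect))
    data.frame(ids, effect = as.numeric(effect), se = se, t = as.numeric(tstat),
               p = as.numeric(p), sig = sig_code(p), stringsAsFactors = FALSE)
  }
  se_g <- sqrt(ms_res / (re * dsn[["t"]]))
  se_t <- sqrt(ms_res / (re * dsn[["l"]]))
  se_s <- sqrt(ms_res / re)
  out <- list(
    gca_line = mk_tab(g, se_g, data.frame(parent = names(g))),
    gca_tester = mk_tab(tt, se_t, data.frame(parent = names(tt))),
    sca = mk_tab(as.vector(s), se_s,
                 data.frame(line = rep(rownames(s), ncol(s)),
                            tester = rep(colnames(s), each = nrow(s)))),
    grand_mean = m, design = dsn, trait = trait, condition = condition)
  class(out) <- "lt_effects"
  out
}

#' Variance components from the line x tester mean squares
#'
#' Method-of-moments estimates from expected mean squares, treating lines,
#' testers and their interactions as random and seasons as fixed:
#' \deqn{\hat\sigma^2_{SCA} = (MS_{SCA} - MS_e)/(re)}
#' \deqn{\hat\sigma^2_{GCA,line} = (MS_{line} - MS_{SCA})/(ret)}
#' \deqn{\hat\sigma^2_{GCA,tester} = (MS_{tester} - MS_{SCA})/(rel)}
#' and analogously for the season interactions
#' (\eqn{(MS_{LxTxE} - MS_e)/r}, \eqn{(MS_{LxE} - MS_{LxTxE})/(rt)},
#' \eqn{(MS_{TxE} - MS_{LxTxE})/(rl)}).  Negative estimates are truncated
#' to 0 and flagged.
#'
#' @param anova An \code{lt_anova} table.
#' @param design Named vector \code{c(r, e, l, t)}; defaults to the table's
#'   design attribute.
#' @return List of class \code{lt_components} with the seven components,
#'   the design, and \code{truncated} (names of zero-truncated components).
#' @export
estimate_components <- function(anova, design = attr(anova, "design")) {
  if (is.null(design)) stop("design counts (r, e, l, t) required")
  r <- design[["r"]]; e <- design[["e"]]
  l <- design[["l"]]; t <- design[["t"]]
  if (r * e == 0) stop("config error: r and e must be positive")
  ms <- function(src) {
    i <- match(src, anova$source)
    if (is.na(i)) stop("ANOVA table is missing the row '", src, "'")
    anova$mean_square[i]
  }
  raw <- c(
    sigma2_sca = (ms("LINE x TESTER (SCA)") - ms("Residuals")) / (r * e),
    sigma2_gca_line = (ms("LINE (GCA Line)") -
                         ms("LINE x TESTER (SCA)")) / (r * e * t),
    sigma2_gca_tester = (ms("TESTER (GCA Tester)") -
                           ms("LINE x TESTER (SCA)")) / (r * e * l))
  if ("LINE x TESTER x E" %in% anova$source) {
    raw <- c(raw,
      sigma2_gxe_sca = (ms("LINE x TESTER x E") - ms("Residuals")) / r,
      sigma2_gxe_line = (ms("GCA LINE x E") -
                           ms("LINE x TESTER x E")) / (r * t),
      sigma2_gxe_tester = (ms("GCA TESTER x E") -
                             ms("LINE x TESTER x E")) / (r * l))
  }
  raw <- c(raw, sigma2_error = ms("Residuals"))
  truncated <- names(raw)[raw < 0]
  out <- as.list(pmax(raw, 0))
  out$design <- c(r = r, e = e, l = l, t = t)
  out$truncated <- truncated
  class(out) <- "lt_components"
  out
}

#' GCA/SCA contribution percentages and Baker's predictability ratio
#'
#' Mean-square based contribution
#' \eqn{100 (MS_{line} + MS_{tester}) / (MS_{line} + MS_{tester} + MS_{SCA})},
#' its df-weighted sum-of-squares analogue, and Baker's ratio
#' \eqn{2(\sigma^2_{GCA,line} + \sigma^2_{GCA,tester}) /
#' (2(\sigma^2_{GCA,line} + \sigma^2_{GCA,tester}) + \sigma^2_{SCA})}
#' clipped to [0, 1].  A ratio near 1 means hybrid performance is
#' predictable from parental GCA alone.
#'
#' @param anova An \code{lt_anova} table.
#' @return Named numeric vector \code{pct_gca_ms}, \code{pct_sca_ms},
#'   \code{pct_gca_ss}, \code{pct_sca_ss}, \code{baker_ratio}.
#' @export
gca_sca_contribution <- function(anova) {
  g <- function(src, col) anova[[col]][match(src, anova$source)]
  ms_l <- g("LINE (GCA Line)", "mean_square")
  ms_t <- g("TESTER (GCA Tester)", "mean_square")
  ms_s <- g("LINE x TESTER (SCA)", "mean_square")
  if (anyNA(c(ms_l, ms_t, ms_s)))
    stop("ANOVA table must contain GCA and SCA rows")
  den_ms <- ms_l + ms_t + ms_s
  pct_gca_ms <- if (den_ms > 0) 100 * (ms_l + ms_t) / den_ms else NA_real_
  ss_l <- g("LINE (GCA Line)", "sum_sq"); ss_t <- g("TESTER (GCA Tester)",
                                                    "sum_sq")
  ss_s <- g("LINE x TESTER (SCA)", "sum_sq")
  den_ss <- ss_l + ss_t + ss_s
  pct_gca_ss <- if (den_ss > 0) 100 * (ss_l + ss_t) / den_ss else NA_real_
  comp <- estimate_components(anova)
  num <- 2 * (comp$sigma2_gca_line + comp$sigma2_gca_tester)
  den_b <- num + comp$sigma2_sca
  baker <- if (den_b > 0) min(max(num / den_b, 0), 1) else NA_real_
  c(pct_gca_ms = pct_gca_ms, pct_sca_ms = 100 - pct_gca_ms,
    pct_gca_ss = pct_gca_ss, pct_sca_ss = 100 - pct_gca_ss,
    baker_ratio = baker)
}
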