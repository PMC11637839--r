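# Additive/dominance variances and heritability on the entry-mean basis.

#' Additive and dominance variances from combining-ability components
#'
#' Under the usual line x tester assumptions the SCA variance estimates
#' \eqn{(1+F)^2/4 \cdot \sigma^2_D} and the pooled GCA variance estimates
#' covariance among half sibs, so
#' \deqn{\hat\sigma^2_D = \frac{4}{(1+F)^2}\,\sigma^2_{SCA}, \qquad
#'       \hat\sigma^2_A = \frac{2}{1+F}\,
#'         (\sigma^2_{GCA,line} + \sigma^2_{GCA,tester}).}
#' With fully inbred parents treated as non-inbred gametic samples
#' (\code{F = 0}, the default) this reduces to
#' \eqn{\sigma^2_D = 4\sigma^2_{SCA}} and
#' \eqn{\sigma^2_A = 2(\sigma^2_{GCA,line} + \sigma^2_{GCA,tester})}.
#'
#' @param components An \code{lt_components} list (or any list with
#'   \code{sigma2_gca_line}, \code{sigma2_gca_tester}, \code{sigma2_sca}).
#' @param F Inbreeding coefficient of the parents, in [0, 1].
#' @return Named vector \code{c(sigma2_A, sigma2_D)}.
#' @export
#' @examples
#' derive_A_D(list(sigma2_gca_line = 110197.54,
#'                 sigma2_gca_tester = 18193.65,
#'                 sigma2_sca = 54808.25))
derive_A_D <- function(components, F = 0) {
  stopifnot(F >= 0, F <= 1)
  v <- c(components$sigma2_gca_line, components$sigma2_gca_tester,
         components$sigma2_sca)
  if (length(v) != 3L || anyNA(v))
    stop("components must supply sigma2_gca_line, sigma2_gca_tester, sigma2_sca")
  if (any(v < 0))
    stop("negative variance component; truncate components before deriving")
  c(sigma2_A = (2 / (1 + F)) * (v[1] + v[2]),
    sigma2_D = (4 / (1 + F)^2) * v[3])
}

#' Non-genetic variance on the entry-mean basis
#'
#' From the genotype-by-season and residual mean squares:
#' \deqn{\hat\sigma^2_E = \frac{\max(MS_{GxE} - MS_e, 0)}{r}
#'   + \frac{MS_e}{re}}
#' with \code{r} replicates and \code{e} seasons.
#'
#' @param anova An \code{lt_anova} table containing \code{GENOTYPES x E}
#'   and \code{Residuals} rows.
#' @param design Named vector with \code{r} and \code{e}; defaults to the
#'   table's design attribute.
#' @return The non-genetic variance (trait units squared).
#' @export
derive_sigma2_E <- function(anova, design = attr(anova, "design")) {
  ms_ge <- anova$mean_square[match("GENOTYPES x E", anova$source)]
  ms_e <- anova$mean_square[match("Residuals", anova$source)]
  if (anyNA(c(ms_ge, ms_e)))
    stop("ANOVA table must contain 'GENOTYPES x E' and 'Residuals' rows")
  r <- design[["r"]]; e <- design[["e"]]
  max(ms_ge - ms_e, 0) / r + ms_e / (r * e)
}

#' Broad- and narrow-sense heritability
#'
#' On the entry-mean basis,
#' \deqn{H^2 = \frac{\sigma^2_A + \sigma^2_D}
#'   {\sigma^2_A + \sigma^2_D + \sigma^2_E}, \qquad
#'   h^2 = \frac{\sigma^2_A}{\sigma^2_A + \sigma^2_D + \sigma^2_E}.}
#' Both lie in [0, 1] with \eqn{h^2 \le H^2}; they are invariant to a common
#' rescaling of the three inputs.  Components may come from
#' \code{\link{derive_A_D}} / \code{\link{derive_sigma2_E}} or be supplied
#' directly.
#'
#' @param sigma2_A Additive variance (>= 0).
#' @param sigma2_D Dominance variance (>= 0).
#' @param sigma2_E Non-genetic variance (>= 0).
#' @return Named vector \code{c(H2, h2)}; \code{NA} with a warning when all
#'   three inputs are zero.
#' @export
#' @examples
#' heritability(274664.01, 219233.01, 254256.89)  # ~0.66 / 0.37
heritability <- function(sigma2_A, sigma2_D, sigma2_E) {
  stopifnot(sigma2_A >= 0, sigma2_D >= 0, sigma2_E >= 0)
  den <- sigma2_A + sigma2_D + sigma2_E
  if (den == 0) {
    warning("all variance components are zero; heritability undefined")
    return(c(H2 = NA_real_, h2 = NA_real_))
  }
  c(H2 = (sigma2_A + sigma2_D) / den, h2 = sigma2_A / den)
}
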