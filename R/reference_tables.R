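# Published reference estimates from the motivating extra-early orange
# maize testcross study (Ikenne, Nigeria; two dry and two rainy seasons;
# 36 lines x 5 testers).  These are *inputs* — printed grain-yield mean
# squares, variance components and best-testcross yields — used to verify
# the package's arithmetic (EMS divisors, heritability and heterosis
# formulas) against an independent analysis of the same design.

#' Reference grain-yield mean squares
#'
#' Grain-yield line x tester ANOVA mean squares from the reference
#' multi-environment trial, one table per growing condition, in the row
#' layout of \code{\link{fit_linetester_anova}}.
#'
#' @param condition \code{"drought"} or \code{"rainfed"}.
#' @return An \code{lt_anova}-classed data frame (sums of squares are
#'   reconstructed as df x mean square) with the reference design
#'   (r = 2, e = 2, l = 36, t = 5) attached.
#' @export
reference_mean_squares <- function(condition = c("drought", "rainfed")) {
  condition <- match.arg(condition)
  f <- system.file("extdata", "reference_mean_squares.csv",
                   package = "linetester", mustWork = TRUE)
  d <- read.csv(f, stringsAsFactors = FALSE)
  d <- d[d$condition == condition, c("source", "df", "mean_square")]
  d$sum_sq <- d$df * d$mean_square
  tab <- d[, c("source", "df", "sum_sq", "mean_square")]
  attr(tab, "design") <- c(r = 2, e = 2, l = 36, t = 5)
  attr(tab, "trait") <- "GY"
  attr(tab, "condition") <- condition
  class(tab) <- c("lt_anova", "data.frame")
  tab
}

#' Reference variance components and heritabilities
#'
#' Per-trait, per-condition GCA/SCA variances, additive, dominance and
#' non-genetic variances, and broad-/narrow-sense heritabilities from the
#' reference trial.
#'
#' @return Data frame with columns \code{trait}, \code{condition},
#'   \code{sigma2_gca_line}, \code{sigma2_gca_tester}, \code{sigma2_sca},
#'   \code{sigma2_A}, \code{sigma2_D}, \code{sigma2_E}, \code{H2},
#'   \code{h2}.
#' @export
reference_variance_components <- function() {
  f <- system.file("extdata", "reference_variance_components.csv",
                   package = "linetester", mustWork = TRUE)
  read.csv(f, stringsAsFactors = FALSE)
}

#' Reference best-testcross grain yields
#'
#' Grain yields of the testcrosses that out-yielded the best commercial
#' check in the reference trial, together with the best check itself, per
#' growing condition.
#'
#' @return Data frame with columns \code{condition}, \code{genotype},
#'   \code{role}, \code{GY}.
#' @export
reference_best_testcrosses <- function() {
  f <- system.file("extdata", "reference_best_testcrosses.csv",
                   package = "linetester", mustWork = TRUE)
  read.csv(f, stringsAsFactors = FALSE)
}
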