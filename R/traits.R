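#' Declare a trait measured in the trial
#'
#' A trait specification records the unit, measurement kind, selection
#' direction and the growing conditions in which the trait is scored.
#' Ordinal-score traits are bounded in \code{[1, 9]} (1 = best expression for
#' lower-better scores such as plant aspect).
#'
#' @param name Trait identifier (e.g. \code{"GY"}).
#' @param units Free-text unit string (e.g. \code{"kg/ha"}).
#' @param kind One of \code{"continuous"}, \code{"ordinal-score"},
#'   \code{"count-ratio"}.
#' @param direction \code{"higher-better"} or \code{"lower-better"}.
#' @param conditions Character subset of \code{c("drought", "rainfed")} in
#'   which the trait is measured.
#' @return An object of class \code{trait_spec}.
#' @export
#' @examples
#' trait_spec("GY", "kg/ha", "continuous", "higher-better")
trait_spec <- function(name, units = "", kind = "continuous",
                       direction = "higher-better",
                       conditions = c("drought", "rainfed")) {
  kind <- match.arg(kind, c("continuous", "ordinal-score", "count-ratio"))
  direction <- match.arg(direction, c("higher-better", "lower-better"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  conditions <- match.arg(conditions, c("drought", "rainfed"),
                          several.ok = TRUE)
  structure(list(name = name, units = units, kind = kind,
                 direction = direction, conditions = conditions),
            class = "trait_spec")
}

#' @export
print.trait_spec <- function(x, ...) {
  cat(sprintf("<trait_spec> %s [%s] %s, %s; measured under: %s\n",
              x$name, x$units, x$kind, x$direction,
              paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' Default trait panel for an extra-early maize testcross trial
#'
#' Grain yield plus the standard drought-adaptation secondary traits:
#' flowering dates, anthesis-silking interval, plant/ear height, ears per
#' plant, 1-9 visual scores for plant aspect, ear aspect and husk cover, and
#' the stay-green score (drought only, leaf-senescence rating at 70 days).
#'
#' @return Named list of \code{\link{trait_spec}} objects.
#' @export
default_trait_specs <- function() {
  sp <- list(
    trait_spec("GY",   "kg/ha", "continuous",    "higher-better"),
    trait_spec("DP",   "days",  "continuous",    "lower-better"),
    trait_spec("DS",   "days",  "continuous",    "lower-better"),
    trait_spec("ASI",  "days",  "continuous",    "lower-better"),
    trait_spec("PHT",  "cm",    "continuous",    "higher-better"),
    trait_spec("EHT",  "cm",    "continuous",    "higher-better"),
    trait_spec("EPP",  "ratio", "count-ratio",   "higher-better"),
    trait_spec("PASP", "1-9",   "ordinal-score", "lower-better"),
    trait_spec("EASP", "1-9",   "ordinal-score", "lower-better"),
    trait_spec("HCV",  "1-9",   "ordinal-score", "lower-better"),
    trait_spec("STGC", "1-9",   "ordinal-score", "lower-better",
               conditions = "drought")
  )
  setNames(sp, vapply(sp, `[[`, "", "name"))
}

# Internal: validate a vector of values against a trait spec. Returns a
# character vector of problems (empty when clean). `rows` are original row
# numbers for diagnostics.
validate_trait_values <- function(values, spec, rows) {
  probs <- character(0)
  finite <- !is.na(values)
  if (spec$kind == "ordinal-score") {
    bad <- finite & (values < 1 | values > 9)
    if (any(bad))
      probs <- c(probs, sprintf(
        "row %d: %s = %g outside ordinal-score bound [1,9]",
        rows[bad], spec$name, values[bad]))
  }
  if (spec$kind == "count-ratio") {
    bad <- finite & values < 0
    if (any(bad))
      probs <- c(probs, sprintf("row %d: %s = %g negative count-ratio",
                                rows[bad], spec$name, values[bad]))
  }
  probs
}
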