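#' @keywords internal
design_columns <- function() {
  c("condition", "environment", "replicate", "block",
    "genotype", "role", "line_parent", "tester_parent")
}

valid_roles <- function() c("testcross", "line", "tester", "check", "diallel")

# Internal: validate a plot-observation data frame against trait specs.
# Stops with row-numbered diagnostics on any violation.
validate_observations <- function(df, trait_specs) {
  need <- design_columns()
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("format error: missing design column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  traits <- intersect(names(trait_specs), names(df))
  if (!length(traits))
    stop("format error: no declared trait column found in input",
         call. = FALSE)
  rows <- seq_len(nrow(df))
  probs <- character(0)

  bad_role <- !df$role %in% valid_roles()
  if (any(bad_role))
    probs <- c(probs, sprintf("row %d: unknown role '%s'",
                              rows[bad_role], df$role[bad_role]))

  bad_cond <- !df$condition %in% c("drought", "rainfed")
  if (any(bad_cond))
    probs <- c(probs, sprintf("row %d: unknown condition '%s'",
                              rows[bad_cond], df$condition[bad_cond]))

  # role/parent cross-validation: testcrosses carry both parents, per-se
  # entries (lines, testers, checks) carry none
  has_lp <- !is.na(df$line_parent) & nzchar(as.character(df$line_parent))
  has_tp <- !is.na(df$tester_parent) & nzchar(as.character(df$tester_parent))
  tc <- df$role == "testcross"
  bad_tc <- tc & !(has_lp & has_tp)
  if (any(bad_tc))
    probs <- c(probs,
               sprintf("row %d: testcross '%s' must declare both parents",
                       rows[bad_tc], df$genotype[bad_tc]))
  perse <- df$role %in% c("line", "tester", "check")
  bad_ps <- perse & (has_lp | has_tp)
  if (any(bad_ps))
    probs <- c(probs,
               sprintf("row %d: per-se entry '%s' must not declare parents",
                       rows[bad_ps], df$genotype[bad_ps]))

  for (tr in traits)
    probs <- c(probs,
               validate_trait_values(df[[tr]], trait_specs[[tr]], rows))

  # condition-restricted traits (e.g. stay-green scored under drought only)
  for (tr in traits) {
    allowed <- trait_specs[[tr]]$conditions
    off <- !is.na(df[[tr]]) & !df$condition %in% allowed
    if (any(off))
      probs <- c(probs, sprintf(
        "row %d: trait %s is only measured under %s but has a value under %s",
        rows[off], tr, paste(allowed, collapse = "/"), df$condition[off]))
  }

  if (length(probs))
    stop("validation error:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  invisible(df)
}

#' Read plot-level trial data from CSV
#'
#' Expects one row per plot with the design columns \code{condition},
#' \code{environment}, \code{replicate}, \code{block}, \code{genotype},
#' \code{role}, \code{line_parent}, \code{tester_parent} followed by one
#' column per declared trait.  Empty strings are missing values.  Every row
#' is validated (role labels, parent consistency, ordinal-score bounds,
#' condition restrictions) and rejected with row-numbered diagnostics.
#'
#' @param path Path to a CSV file.
#' @param trait_specs Named list of \code{\link{trait_spec}}; defaults to
#'   \code{\link{default_trait_specs}}.
#' @return A \code{data.frame} of plot observations with attribute
#'   \code{"traits"} listing the trait columns present.
#' @export
read_trial <- function(path, trait_specs = default_trait_specs()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"), check.names = FALSE)
  validate_observations(df, trait_specs)
  df$replicate <- as.integer(df$replicate)
  df$block <- as.integer(df$block)
  attr(df, "traits") <- intersect(names(trait_specs), names(df))
  df
}

#' Write plot-level trial data to CSV
#'
#' Inverse of \code{\link{read_trial}}: comma-separated, UTF-8, one header
#' row, empty string for missing.  \code{read_trial(write_trial(x))} is
#' lossless for finite values.
#'
#' @param obs Plot-observation data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_trial <- function(obs, path) {
  write.csv(obs, path, row.names = FALSE, na = "")
  invisible(path)
}
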