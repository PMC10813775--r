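# APACHE II severity grouping and mortality lookup.
#
# The APACHE II score (0-71) summarises acute physiology and chronic health;
# cohorts are dichotomized at the score whose predicted mortality first
# exceeds ~50%: scores <= 24 form the low-severity group (L), scores > 24
# the high-severity group (H).

apache_mortality_table <- function() {
  path <- system.file("extdata", "apache2_mortality.csv", package = "ecmonirs")
  if (path == "") path <- file.path("inst", "extdata", "apache2_mortality.csv")
  utils::read.csv(path)
}

#' Assign the severity group for an APACHE II score
#'
#' @param apache_score Integer score(s) in 0..71.
#' @return `"L"` (score <= 24) or `"H"` (score > 24), vectorized.
#' @examples
#' assign_group(c(24, 25))  # "L" "H"
#' @export
assign_group <- function(apache_score) {
  if (any(!is.finite(apache_score)) || any(apache_score < 0) ||
      any(apache_score > 71)) {
    stop("APACHE II scores must lie in 0..71", call. = FALSE)
  }
  ifelse(apache_score <= 24, "L", "H")
}

#' Predicted mortality for an APACHE II score
#'
#' Banded lookup of the classical score-to-mortality table: 0-4 -> 4%,
#' 5-9 -> 8%, 10-14 -> 15%, 15-19 -> 25%, 20-24 -> 40%, 25-29 -> 55%,
#' 30-34 -> 75%, over 34 -> 85%. The band point estimates are shipped as a
#' CSV under `inst/extdata/` so alternative tabulations can be substituted.
#'
#' @param apache_score Integer score(s) in 0..71.
#' @return Predicted mortality in percent, vectorized.
#' @examples
#' mortality_lookup(22)  # 40
#' @export
mortality_lookup <- function(apache_score) {
  if (any(!is.finite(apache_score)) || any(apache_score < 0) ||
      any(apache_score > 71)) {
    stop("APACHE II scores must lie in 0..71", call. = FALSE)
  }
  tab <- apache_mortality_table()
  idx <- findInterval(apache_score, tab$score_min)
  tab$mortality_pct[idx]
}

#' Severity label for an APACHE II score
#'
#' @param apache_score Integer score in 0..71.
#' @return A list with `apache_score`, `group` and `predicted_mortality_pct`.
#' @export
severity_label <- function(apache_score) {
  list(apache_score = as.integer(apache_score),
       group = assign_group(apache_score),
       predicted_mortality_pct = mortality_lookup(apache_score))
}
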