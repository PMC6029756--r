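#' Concentration-response functions for short-term ozone and mortality
#'
#' Pooled two-stage (city GLM + hierarchical Bayes) estimates from a
#' nationwide multi-city time-series study: percent increase in daily
#' mortality per 10 ug/m3 (~5 ppb) increase in MDA8 ozone, with 95%
#' confidence intervals, by cause of death, age group, and season.
#'
#' @return Tibble `stratum_type, stratum, pct, ci_low, ci_high`.
#' @export
#' @examples
#' default_crf_table()
default_crf_table <- function() {
  tibble(
    stratum_type = c(rep("cause", 3), rep("age", 3), rep("season", 2)),
    stratum = c("non-accidental", "cardiovascular", "respiratory",
                "5-64", "65-74", "75+", "warm", "cold"),
    pct = c(0.24, 0.27, 0.18, 0.13, 0.19, 0.42, 0.20, 0.43),
    ci_low = c(0.13, 0.10, -0.11, -0.23, 0.03, 0.21, 0.08, 0.21),
    ci_high = c(0.35, 0.44, 0.47, 0.48, 0.34, 0.64, 0.31, 0.65)
  )
}

#' Read a CRF table from CSV
#'
#' Expected columns: `stratum_type, stratum, pct, ci_low, ci_high`.
#'
#' @param path CSV file path.
#' @return CRF tibble (validated).
#' @export
read_crf_table <- function(path) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("stratum_type", "stratum", "pct", "ci_low", "ci_high")
  if (!all(need %in% names(df))) {
    abort(paste("CRF table must have columns:", paste(need, collapse = ", ")))
  }
  if (any(df$ci_low > df$pct | df$pct > df$ci_high)) {
    abort("CRF confidence limits must bracket the point estimate")
  }
  df
}

#' Convert a CRF percent increase to a log-scale coefficient per ppb
#'
#' CRFs are reported as percent increase per 10 ug/m3, which is 5 ppb under
#' the adopted 2.0 ug/m3-per-ppb conversion. On the log-linear (GLM
#' log-link) scale, `beta = log(1 + pct/100) / 5` per ppb.
#'
#' @param pct Percent increase per 10 ug/m3 (vectorized; must be > -100).
#' @return Coefficient per ppb.
#' @export
#' @examples
#' beta_from_percent(0.24) # log(1.0024) / 5
beta_from_percent <- function(pct) {
  if (any(pct <= -100, na.rm = TRUE)) {
    abort("percent change must exceed -100")
  }
  log(1 + pct / 100) / (10 / UGM3_PER_PPB)
}
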