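#' Branch-point definitions of the monolignol network
#'
#' The branch points at which flux partitioning controls lignin composition,
#' each with its entering flux(es) and diverging fluxes.  Partition ratios are
#' the diverging fluxes normalized by the total flux entering the branch
#' point, so they sum to one at every branch.
#'
#' @return Named list; each element has `entering` and `outgoing` reaction-id
#'   vectors.
#' @export
branch_definitions <- function() {
  list(
    cinnamic_acid = list(entering = "v1", outgoing = c("v2", "v22")),
    p_coumaroyl_CoA = list(entering = "v3", outgoing = c("v4", "v7", "v23")),
    caffeoyl_CoA = list(entering = "v9", outgoing = c("v10", "v11")),
    coniferyl_aldehyde = list(entering = c("v12", "v13"),
                              outgoing = c("v14", "v16")),
    coniferyl_alcohol = list(entering = "v14", outgoing = c("v15", "v20")),
    `5OH_coniferyl_alcohol` = list(entering = "v20", outgoing = c("v21", "v24"))
  )
}

#' Branch-point partition ratios across internodes
#'
#' For each branch point and each diverging flux, computes the flux divided by
#' the total flux entering the branch point, per internode.  A zero entering
#' flux yields the marker value `NA` (flagged in the `defined` column) rather
#' than propagating NaN.
#'
#' @param distributions Named list of `flux_distribution` objects, one per
#'   internode, in maturity order (names are internode labels, e.g. `"1-2"`,
#'   `"3"`, ...).
#' @param branches Branch definitions (default [branch_definitions()]);
#'   branches whose reactions are absent from the network (e.g. overflows on
#'   the un-extended variant) are skipped.
#' @return Data frame with columns `branch_point`, `ratio_id`, `internode`,
#'   `value`, `defined`.
#' @export
partition_ratios <- function(distributions, branches = branch_definitions()) {
  stopifnot(length(distributions) >= 1)
  labs <- names(distributions)
  if (is.null(labs)) labs <- as.character(seq_along(distributions))
  ids <- names(distributions[[1]]$values)
  out <- list()
  for (bp in names(branches)) {
    br <- branches[[bp]]
    if (!all(c(br$entering, br$outgoing) %in% ids)) next
    for (flux in br$outgoing) {
      vals <- vapply(distributions, function(fd) {
        inflow <- sum(fd$values[br$entering])
        if (inflow <= 0) NA_real_ else fd$values[[flux]] / inflow
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        branch_point = bp,
        ratio_id = paste0(flux, "/", paste(br$entering, collapse = "+")),
        internode = labs, value = as.numeric(vals),
        defined = !is.na(vals), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Trend classifier configuration
#'
#' @param unchanged_rel_range Series whose range is below this fraction of the
#'   mean absolute level are "essentially unchanged" (default 0.05).
#' @param rho_threshold Minimum absolute Spearman rank correlation for a
#'   non-monotone series to count as increasing/decreasing with minor
#'   variations (default 0.6).
#' @return List of class `trend_config`.
#' @export
trend_config <- function(unchanged_rel_range = 0.05, rho_threshold = 0.6) {
  stopifnot(unchanged_rel_range >= 0, rho_threshold >= 0, rho_threshold <= 1)
  structure(list(unchanged_rel_range = unchanged_rel_range,
                 rho_threshold = rho_threshold), class = "trend_config")
}

#' Trend category levels
#' @export
TREND_LEVELS <- c("MONO_UP", "UP_MINOR", "UNCHANGED", "DOWN_MINOR", "MONO_DOWN")

#' Classify a developmental trend
#'
#' Maps an ordered series of partition ratios (young to mature internodes)
#' into one of five categories: monotonically increasing (`MONO_UP`),
#' increasing with minor variations (`UP_MINOR`), essentially unchanged
#' (`UNCHANGED`), decreasing with minor variations (`DOWN_MINOR`), or
#' monotonically decreasing (`MONO_DOWN`).  Strict monotonicity wins; an
#' overall relative range under the configured fraction of the mean level is
#' `UNCHANGED`; otherwise the sign of the Spearman rank correlation with the
#' internode order decides, if strong enough.  The classification is
#' invariant to positive rescaling of the series.
#'
#' @param series Numeric vector, length >= 3.
#' @param config A [trend_config()].
#' @return One of [TREND_LEVELS] as a character scalar.
#' @export
classify_trend <- function(series, config = trend_config()) {
  if (length(series) < 3L) stop("need at least 3 points to classify a trend")
  if (any(!is.finite(series))) stop("series must be finite")
  d <- diff(series)
  if (all(d > 0)) return("MONO_UP")
  if (all(d < 0)) return("MONO_DOWN")
  level <- mean(abs(series))
  if (level == 0) return("UNCHANGED")
  if ((max(series) - min(series)) / level < config$unchanged_rel_range)
    return("UNCHANGED")
  rho <- suppressWarnings(
    stats::cor(seq_along(series), series, method = "spearman"))
  if (!is.finite(rho) || abs(rho) < config$rho_threshold) return("UNCHANGED")
  if (rho > 0) "UP_MINOR" else "DOWN_MINOR"
}

#' Pearson correlation between two fluxes across flux distributions
#'
#' Pools flux values over a collection of solved distributions (typically all
#' internodes of several transgenic lines) and returns the Pearson
#' correlation between the two flux series, as used to quantify the coupling
#' of the CCR1 (`v13`) and CAD (`v14`) steps.
#'
#' @param distributions List of `flux_distribution` objects (length >= 3).
#' @param flux_a,flux_b Reaction ids.
#' @return List with `flux_pair`, `pearson_rho` (NA with `defined = FALSE`
#'   when either series has zero variance) and `n_points`.
#' @export
pairwise_flux_correlation <- function(distributions, flux_a, flux_b) {
  if (length(distributions) < 3L) stop("need at least 3 distributions")
  a <- vapply(distributions, function(fd) fd$values[[flux_a]], numeric(1))
  b <- vapply(distributions, function(fd) fd$values[[flux_b]], numeric(1))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(flux_pair = c(flux_a, flux_b), pearson_rho = NA_real_,
                defined = FALSE, n_points = length(a)))
  }
  list(flux_pair = c(flux_a, flux_b),
       pearson_rho = stats::cor(a, b), defined = TRUE, n_points = length(a))
}
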