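#' Sampling configuration for the kinetic ensemble
#'
#' Each vmax and km is drawn independently log-uniformly from its range; in
#' Hill mode the cooperativity exponents are drawn uniformly from
#' `hill_n_range`, in Michaelis-Menten mode they are fixed at 1.  The influx
#' `J` is a fixed boundary condition chosen so that roughly half of the
#' unconstrained draws possess a steady state under the default ranges.
#'
#' @param n_draws Number of parameter sets (default 10000).
#' @param vmax_range,km_range Positive ranges for the log-uniform draws
#'   (defaults `c(0.1, 10)` in model units).
#' @param hill If `TRUE`, Hill kinetics with sampled exponents.
#' @param hill_n_range Range of the Hill exponents (default `c(1, 4)`).
#' @param influx Influx `J` (default 0.5).
#' @param seed Integer seed for reproducibility.
#' @return List of class `sampling_config`.
#' @export
sampling_config <- function(n_draws = 10000, vmax_range = c(0.1, 10),
                            km_range = c(0.1, 10), hill = FALSE,
                            hill_n_range = c(1, 4), influx = 0.5,
                            seed = 1L) {
  stopifnot(n_draws >= 1, length(vmax_range) == 2, length(km_range) == 2,
            all(vmax_range > 0), all(km_range > 0),
            vmax_range[1] < vmax_range[2], km_range[1] < km_range[2],
            influx > 0)
  if (hill) stopifnot(length(hill_n_range) == 2, hill_n_range[1] >= 1,
                      hill_n_range[1] < hill_n_range[2])
  structure(list(n_draws = as.integer(n_draws), vmax_range = vmax_range,
                 km_range = km_range, hill = isTRUE(hill),
                 hill_n_range = hill_n_range, influx = influx,
                 seed = as.integer(seed)),
            class = "sampling_config")
}

#' Admissibility configuration
#'
#' A random parameter set is admissible when its baseline steady state exists
#' (all pools converge to finite positive concentrations) and the baseline
#' S/G ratio falls inside a physiologically plausible window; the default
#' window `[0.09, 0.64]` spans the wild-type range observed across alfalfa
#' stem internodes.  An optional minimum baseline flux through each route can
#' be demanded.
#'
#' @param require_convergence Require a steady state (default `TRUE`).
#' @param sg_window Admissible baseline S/G window (default `c(0.09, 0.64)`).
#' @param min_route_flux Minimum baseline flux through each of `v10`, `v11`,
#'   `v15`, `v16 + v20` (default 0).
#' @return List of class `admissibility_config`.
#' @export
admissibility_config <- function(require_convergence = TRUE,
                                 sg_window = c(0.09, 0.64),
                                 min_route_flux = 0) {
  stopifnot(length(sg_window) == 2, sg_window[1] < sg_window[2],
            min_route_flux >= 0)
  structure(list(require_convergence = isTRUE(require_convergence),
                 sg_window = sg_window, min_route_flux = min_route_flux),
            class = "admissibility_config")
}

#' Draw one kinetic parameter set
#'
#' Draws from the current R random-number stream (callers seed it; ensembles
#' do so from their `sampling_config`).
#'
#' @param config A `sampling_config`.
#' @return A `branch_model`.
#' @export
sample_parameter_set <- function(config) {
  stopifnot(inherits(config, "sampling_config"))
  runif_log <- function(n, r) exp(stats::runif(n, log(r[1]), log(r[2])))
  vmax <- runif_log(8, config$vmax_range)
  km <- runif_log(8, config$km_range)
  hn <- if (config$hill) stats::runif(8, config$hill_n_range[1],
                                      config$hill_n_range[2]) else rep(1, 8)
  ks <- lapply(seq_along(.BRANCH_REACTIONS), function(i)
    branch_kinetics(.BRANCH_REACTIONS[i], vmax[i], km[i], hn[i]))
  branch_model(ks, config$influx)
}

#' Admissibility of one parameter set
#'
#' @param model A `branch_model`.
#' @param adm_config An `admissibility_config`.
#' @return List with `admissible` (flag), `reason` (`"ok"`, `"no steady
#'   state"`, `"S/G outside window"`, `"route flux below minimum"`), and the
#'   baseline `state`.
#' @export
is_admissible <- function(model, adm_config = admissibility_config()) {
  st <- steady_state(model)
  if (!st$converged) {
    if (adm_config$require_convergence)
      return(list(admissible = FALSE, reason = "no steady state", state = st))
  } else if (any(!is.finite(st$concentrations)) ||
             any(st$concentrations < 0)) {
    return(list(admissible = FALSE, reason = "no steady state", state = st))
  }
  sg <- st$sg_ratio
  if (!is.finite(sg) || sg < adm_config$sg_window[1] ||
      sg > adm_config$sg_window[2])
    return(list(admissible = FALSE, reason = "S/G outside window", state = st))
  if (adm_config$min_route_flux > 0) {
    routes <- c(st$fluxes[["v10"]], st$fluxes[["v11"]], st$fluxes[["v15"]],
                st$fluxes[["v16"]] + st$fluxes[["v20"]])
    if (any(routes < adm_config$min_route_flux))
      return(list(admissible = FALSE, reason = "route flux below minimum",
                  state = st))
  }
  list(admissible = TRUE, reason = "ok", state = st)
}

#' Run a Monte Carlo knockdown ensemble
#'
#' Samples `n_draws` random kinetic parameter sets, screens them for
#' admissibility, applies the enzyme knockdown to every admissible draw via
#' [perturbation_response()], and summarizes the distribution of relative
#' S/G changes.  Draws whose perturbed model loses its steady state are
#' flagged and excluded from the response fractions.
#'
#' @param sampling A `sampling_config` (its `seed` fixes the ensemble).
#' @param admissibility An `admissibility_config`.
#' @param target_enzyme `"CCoAOMT"` or `"CCR1"`.
#' @param factor Residual activity factor (0.2 = 80% knockdown).
#' @param significance_threshold Relative S/G change counted as a significant
#'   increase (default 0.05, i.e. +5%).
#' @return Object of class `mc_summary`: counts, `frac_significant_increase`,
#'   `frac_small_change` (|change| < 5%), `max_abs_relative_change`, the
#'   configs, and a per-draw `records` data frame (`draw`, `admissible`,
#'   `reason`, `sg_baseline`, `sg_perturbed`, `relative_change`,
#'   `perturbed_converged`).
#' @export
run_ensemble <- function(sampling, admissibility = admissibility_config(),
                         target_enzyme = c("CCoAOMT", "CCR1"), factor = 0.2,
                         significance_threshold = 0.05) {
  target_enzyme <- match.arg(target_enzyme)
  stopifnot(inherits(sampling, "sampling_config"),
            factor > 0, factor <= 1)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(sampling$seed)
  n <- sampling$n_draws
  rec <- data.frame(draw = seq_len(n), admissible = FALSE,
                    reason = character(n), sg_baseline = NA_real_,
                    sg_perturbed = NA_real_, relative_change = NA_real_,
                    perturbed_converged = NA, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    model <- sample_parameter_set(sampling)
    adm <- is_admissible(model, admissibility)
    rec$admissible[i] <- adm$admissible
    rec$reason[i] <- adm$reason
    if (adm$state$converged) rec$sg_baseline[i] <- adm$state$sg_ratio
    if (!adm$admissible) next
    resp <- perturbation_response(model, target_enzyme, factor)
    rec$perturbed_converged[i] <- resp$converged
    rec$sg_perturbed[i] <- resp$sg_perturbed
    rec$relative_change[i] <- resp$relative_change
  }
  chg <- rec$relative_change[rec$admissible & !is.na(rec$relative_change)]
  n_adm <- sum(rec$admissible)
  structure(list(
    n_draws = n, n_admissible = n_adm,
    n_perturbed_converged = length(chg),
    frac_significant_increase = if (length(chg)) mean(chg > significance_threshold) else NA_real_,
    frac_small_change = if (length(chg)) mean(abs(chg) < 0.05) else NA_real_,
    max_abs_relative_change = if (length(chg)) max(abs(chg)) else NA_real_,
    significance_threshold = significance_threshold,
    target_enzyme = target_enzyme, factor = factor,
    sampling = sampling, admissibility = admissibility,
    records = rec), class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Monte Carlo ensemble: %s knockdown to %.0f%%, %d draws (%s kinetics)\n",
    "  admissible: %d (%.1f%%)\n",
    "  significant S/G increase (> +%.0f%%): %s\n",
    "  |change| < 5%%: %s;  max |relative change|: %s\n"),
    x$target_enzyme, 100 * x$factor, x$n_draws,
    if (x$sampling$hill) "Hill" else "Michaelis-Menten",
    x$n_admissible, 100 * x$n_admissible / x$n_draws,
    100 * x$significance_threshold,
    if (is.na(x$frac_significant_increase)) "undefined (no admissible draws)"
    else sprintf("%.2f%%", 100 * x$frac_significant_increase),
    if (is.na(x$frac_small_change)) "undefined"
    else sprintf("%.1f%%", 100 * x$frac_small_change),
    if (is.na(x$max_abs_relative_change)) "undefined"
    else format(x$max_abs_relative_change)))
  invisible(x)
}
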