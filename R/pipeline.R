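#' Pipeline configuration
#'
#' Bundles every tunable of the full analysis: observation source, network
#' variant, wild-type reference selection policy, trend-classifier
#' thresholds, Monte Carlo settings, and the global seed (fanned out
#' deterministically to the synthetic-data and ensemble stages).
#'
#' @param seed Global integer seed.
#' @param design [study_design()] for the synthetic observations (ignored
#'   when `observations` is supplied).
#' @param observations Optional observation data frame (as from
#'   [read_observations()]); when `NULL` a synthetic study is generated.
#' @param variant Network variant for the flux analyses (default
#'   `"extended"`).
#' @param policy Wild-type reference selection policy (default
#'   `"main-route"`, which routes wild-type G/S flux through the
#'   CCoAOMT--CCR1 path; `"min-norm"` selects the minimum-norm point of the
#'   optimal face instead).
#' @param trend [trend_config()].
#' @param mc_n_draws Draws per Monte Carlo ensemble (default 2000).
#' @param mc_targets Enzymes to knock down in the ensembles.
#' @param mc_factor Residual activity factor (default 0.2).
#' @param mc_hill Use Hill kinetics in the ensembles (default FALSE).
#' @param correlation_pair Flux pair for the cross-flux correlation.
#' @param correlation_exclude Lines excluded from the correlation pool
#'   (default `"CCoAOMT"`, the line whose CCR2 shunt decouples the pair).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, design = study_design(),
                            observations = NULL,
                            variant = c("extended", "unextended"),
                            policy = c("main-route", "min-norm"),
                            trend = trend_config(),
                            mc_n_draws = 2000, mc_targets = c("CCoAOMT", "CCR1"),
                            mc_factor = 0.2, mc_hill = FALSE,
                            correlation_pair = c("v13", "v14"),
                            correlation_exclude = "CCoAOMT") {
  variant <- match.arg(variant)
  policy <- match.arg(policy)
  stopifnot(is.numeric(seed), length(seed) == 1L,
            mc_n_draws >= 1, mc_factor > 0, mc_factor <= 1,
            length(correlation_pair) == 2L)
  structure(list(seed = as.integer(seed), design = design,
                 observations = observations, variant = variant,
                 policy = policy, trend = trend,
                 mc_n_draws = as.integer(mc_n_draws),
                 mc_targets = match.arg(mc_targets, c("CCoAOMT", "CCR1"),
                                        several.ok = TRUE),
                 mc_factor = mc_factor, mc_hill = isTRUE(mc_hill),
                 correlation_pair = correlation_pair,
                 correlation_exclude = correlation_exclude),
            class = "pipeline_config")
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  path
}

#' Run the full integrative analysis
#'
#' Executes every stage on one observation table: (1) load or generate the
#' observations; (2) per-internode wild-type FBA with alternate-optima
#' enumeration and unique reference selection; (3) MOMA prediction of every
#' transgenic line x internode (infeasible cases are recorded, not fatal);
#' (4) branch-point partition ratios and developmental trend classification;
#' (5) the cross-flux correlation; (6) the Monte Carlo knockdown ensembles.
#' All outputs are written to `out_dir` as CSV/JSON together with a manifest
#' listing each file with its MD5 content hash and the configuration used.
#' Rerunning with the same seed reproduces the outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`observations`,
#'   `wildtype` reference distributions, `moma` results, `trends`,
#'   `correlation`, `mc` summaries) and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("lignoflux_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- build_reference_network(config$variant)
  obs <- config$observations
  if (is.null(obs)) {
    obs <- generate_synthetic_study(config$design, seed = config$seed + 1L)
  }
  validate_observations(obs)
  files <- character()
  files["observations"] <- write_observations(obs, file.path(out_dir, "observations.csv"))

  # wild-type FBA per internode
  wt <- list()
  wt_json <- list()
  for (ik in INTERNODES) {
    comp <- observation_composition(obs, "WT", ik)
    prob <- fba_problem(net, comp)
    sol <- solve_fba(prob)
    if (inherits(sol, "fba_infeasibility")) {
      stop("wild-type FBA infeasible at internode ", ik, " (balance: ",
           paste(sol$certificate, collapse = ", "), ")")
    }
    face <- enumerate_alternate_optima(prob, sol)
    ref <- select_reference_distribution(face, config$policy)
    wt[[ik]] <- ref
    wt_json[[length(wt_json) + 1L]] <- list(
      internode = ik, policy = config$policy,
      objective = ref$objective, n_alternate_optima = length(face$vertices),
      fluxes = as.list(ref$values))
  }
  files["wildtype_fluxes"] <- .write_json(wt_json, file.path(out_dir, "wt_fluxes.json"))

  # MOMA per transgenic line x internode
  lines <- setdiff(unique(obs$line_id), "WT")
  moma <- list()
  infeasible <- data.frame(line_id = character(), internode = character(),
                           certificate = character(), stringsAsFactors = FALSE)
  for (ln in lines) {
    enzyme <- ln  # line ids name the down-regulated enzyme
    per_line <- list()
    for (ik in INTERNODES) {
      row <- obs[obs$line_id == ln & obs$internode == ik, ]
      spec <- knockdown_spec(enzyme, row$alpha)
      res <- solve_moma(net, spec, monomer_composition(row$h, row$g, row$s),
                        wt[[ik]])
      moma[[ln]][[ik]] <- res
      if (res$feasible) {
        per_line[[length(per_line) + 1L]] <- list(
          internode = ik, feasible = TRUE, distance = res$distance,
          fluxes = as.list(res$fluxes$values))
      } else {
        per_line[[length(per_line) + 1L]] <- list(
          internode = ik, feasible = FALSE,
          certificate = res$certificate)
        infeasible <- rbind(infeasible, data.frame(
          line_id = ln, internode = ik,
          certificate = paste(res$certificate, collapse = ";"),
          stringsAsFactors = FALSE))
      }
    }
    files[paste0("moma_", ln)] <-
      .write_json(per_line, file.path(out_dir, paste0("moma_", ln, ".json")))
  }

  # branch-point partitioning and developmental trends
  trend_rows <- list()
  all_dists <- c(list(WT = wt), moma_fluxes <- lapply(moma, function(per)
    lapply(per, function(r) if (r$feasible) r$fluxes else NULL)))
  for (ln in names(all_dists)) {
    dists <- Filter(Negate(is.null), all_dists[[ln]])
    if (length(dists) < 3L) next
    pr <- partition_ratios(dists)
    for (rid in unique(pr$ratio_id)) {
      sub <- pr[pr$ratio_id == rid, ]
      cat_lab <- if (all(sub$defined))
        classify_trend(sub$value, config$trend) else NA_character_
      trend_rows[[length(trend_rows) + 1L]] <- data.frame(
        line_id = ln, branch_point = sub$branch_point[1], ratio_id = rid,
        category = cat_lab,
        t(stats::setNames(sub$value, paste0("i", sub$internode))),
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  trends <- do.call(rbind, trend_rows)
  utils::write.csv(trends, file.path(out_dir, "trends.csv"), row.names = FALSE)
  files["trends"] <- file.path(out_dir, "trends.csv")

  # cross-flux correlation over MOMA solutions (pooled lines x internodes)
  pool <- list()
  for (ln in setdiff(lines, config$correlation_exclude)) {
    for (ik in INTERNODES) {
      r <- moma[[ln]][[ik]]
      if (!is.null(r) && r$feasible) pool[[length(pool) + 1L]] <- r$fluxes
    }
  }
  correlation <- pairwise_flux_correlation(pool, config$correlation_pair[1],
                                           config$correlation_pair[2])
  files["correlation"] <- .write_json(correlation,
                                      file.path(out_dir, "correlation.json"))

  # Monte Carlo kinetic ensembles
  mc <- list()
  for (i in seq_along(config$mc_targets)) {
    tg <- config$mc_targets[i]
    samp <- sampling_config(n_draws = config$mc_n_draws,
                            hill = config$mc_hill,
                            seed = config$seed + 10L + i)
    mc[[tg]] <- run_ensemble(samp, admissibility_config(), tg,
                             factor = config$mc_factor)
    summ <- mc[[tg]][setdiff(names(mc[[tg]]), "records")]
    summ$sampling <- unclass(summ$sampling)
    summ$admissibility <- unclass(summ$admissibility)
    files[paste0("mc_", tg)] <-
      .write_json(summ, file.path(out_dir, paste0("mc_", tg, ".json")))
  }

  manifest <- list(
    config = list(seed = config$seed, variant = config$variant,
                  policy = config$policy, mc_n_draws = config$mc_n_draws,
                  mc_targets = config$mc_targets, mc_factor = config$mc_factor,
                  mc_hill = config$mc_hill,
                  correlation_pair = config$correlation_pair,
                  correlation_exclude = config$correlation_exclude),
    n_wildtype_internodes = length(wt),
    n_moma_feasible = sum(vapply(moma, function(per)
      sum(vapply(per, function(r) r$feasible, logical(1))), numeric(1))),
    infeasibilities = if (nrow(infeasible)) infeasible else NULL,
    files = lapply(stats::setNames(nm = names(files)), function(k)
      list(path = basename(files[[k]]),
           md5 = unname(tools::md5sum(files[[k]])))))
  files["manifest"] <- .write_json(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(out_dir = out_dir, observations = obs, wildtype = wt,
                 moma = moma, trends = trends, correlation = correlation,
                 mc = mc, manifest = manifest, files = files))
}
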