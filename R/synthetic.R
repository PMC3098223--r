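# Synthetic observation tables emulating the transgenic alfalfa study:
# 6 down-regulated lines plus wild type, seven internode records each
# (internodes 1 and 2 pooled, then 3..8), with lignin monomer composition,
# total lignin content and the residual activity fraction of the targeted
# enzyme.

#' Internode labels in maturity order
#' @export
INTERNODES <- c("1-2", "3", "4", "5", "6", "7", "8")

#' Transgenic line identifiers
#' @export
STUDY_LINES <- c("WT", "PAL", "C4H", "HCT", "C3H", "CCoAOMT", "COMT")

# wild-type composition trajectory: H share declines linearly from its
# internode 1-2 value (7/85.5/7.4 normalized) to 1% at internode 8, while the
# S/G ratio rises linearly from 7.4/85.5 to 0.64.
.wildtype_trajectory <- function() {
  anchor <- monomer_composition(7, 85.5, 7.4)
  h <- seq(anchor[["h"]], 0.01, length.out = 7)
  sg <- seq(anchor[["s"]] / anchor[["g"]], 0.64, length.out = 7)
  g <- (1 - h) / (1 + sg)
  data.frame(internode = INTERNODES, h = h, g = g, s = sg * g,
             stringsAsFactors = FALSE)
}

#' Deterministic wild-type observation table
#'
#' The wild-type anchor records: internodes 1--2 carry the measured
#' composition 7% H / 85.5% G / 7.4% S (normalized), internode 8 carries a 1%
#' H share and an S/G ratio of 0.64, and the intermediate internodes
#' interpolate both the H share and the S/G ratio linearly (strictly monotone
#' in both).  Total lignin rises linearly from 50 to 140 mg/g cell wall over
#' the maturity gradient.
#'
#' @return Observation data frame: `line_id`, `internode`, `h`, `g`, `s`
#'   (fractions), `total_lignin` (mg/g cell wall), `alpha` (1 for wild type).
#' @export
wildtype_reference_observations <- function() {
  tr <- .wildtype_trajectory()
  data.frame(line_id = "WT", internode = tr$internode,
             h = tr$h, g = tr$g, s = tr$s,
             total_lignin = seq(50, 140, length.out = 7), alpha = 1,
             stringsAsFactors = FALSE)
}

#' Study design for the synthetic observation generator
#'
#' Per-line settings emulating the transgenic study: the residual activity
#' fraction `alpha` of the targeted enzyme, multiplicative shifts of the H
#' share and of the S/G ratio relative to the wild-type trajectory
#' (CCoAOMT- and PAL-deficient lines shift S/G up, C4H and COMT down, C3H and
#' HCT raise the H share), a total-lignin multiplier, and the noise scale.
#' The noise is a truncated Gaussian applied to the logit of each monomer
#' fraction (truncated at 3 sd); the default `noise_sd = 0.1` yields a
#' replicate S/G standard deviation of about 0.03 at wild-type mid-stem
#' compositions.
#'
#' @param lines Data frame with columns `line_id`, `alpha`, `h_mult`,
#'   `sg_mult`, `lignin_mult`; defaults cover the seven study lines.
#' @param noise_sd Logit-scale noise standard deviation (default 0.1).
#' @param lignin_noise_sd Relative noise on total lignin (default 0.05).
#' @return List of class `study_design`.
#' @export
study_design <- function(lines = NULL, noise_sd = 0.1,
                         lignin_noise_sd = 0.05) {
  if (is.null(lines)) {
    lines <- data.frame(
      line_id = STUDY_LINES,
      alpha = c(1, 0.4, 0.45, 0.3, 0.3, 0.2, 0.2),
      h_mult = c(1, 1, 1, 2.5, 4, 1.3, 1),
      sg_mult = c(1, 1.35, 0.7, 0.9, 1, 1.5, 0.35),
      lignin_mult = c(1, 0.75, 0.7, 0.5, 0.5, 0.8, 0.85),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("line_id", "alpha", "h_mult", "sg_mult", "lignin_mult")
                %in% names(lines)),
            all(lines$alpha > 0 & lines$alpha <= 1),
            noise_sd >= 0, lignin_noise_sd >= 0)
  structure(list(lines = lines, noise_sd = noise_sd,
                 lignin_noise_sd = lignin_noise_sd), class = "study_design")
}

# shift a wild-type composition by per-line multipliers on H share and S/G
.shift_composition <- function(h, sg, h_mult, sg_mult) {
  h2 <- min(h * h_mult, 0.95)
  sg2 <- sg * sg_mult
  g2 <- (1 - h2) / (1 + sg2)
  c(h = h2, g = g2, s = sg2 * g2)
}

#' Generate a synthetic observation table
#'
#' Builds the full 7-line x 7-internode table from a [study_design()]:
#' line-shifted smooth composition trajectories plus truncated-Gaussian noise
#' on the logit fractions (renormalized afterwards), noisy total lignin, and
#' the per-line residual activity fractions.  Reproducible from `seed`; with
#' `noise_sd = 0` the wild-type rows equal
#' [wildtype_reference_observations()] exactly.
#'
#' @param design A `study_design`.
#' @param seed Integer seed.
#' @return Observation data frame (columns as in
#'   [wildtype_reference_observations()]).
#' @export
generate_synthetic_study <- function(design = study_design(), seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  seed <- as.integer(seed)  # force before snapshotting the RNG state
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  tr <- .wildtype_trajectory()
  wt_lignin <- seq(50, 140, length.out = 7)
  rtrunc <- function(n, sd) {
    if (sd == 0) return(rep(0, n))
    x <- stats::rnorm(n, 0, sd)
    pmax(pmin(x, 3 * sd), -3 * sd)
  }
  rows <- list()
  for (i in seq_len(nrow(design$lines))) {
    ln <- design$lines[i, ]
    for (k in seq_len(7)) {
      base <- .shift_composition(tr$h[k], tr$s[k] / tr$g[k],
                                 ln$h_mult, ln$sg_mult)
      lf <- stats::qlogis(base) + rtrunc(3, design$noise_sd)
      frac <- stats::plogis(lf)
      if (any(frac <= 0)) {
        warning("noise produced a non-positive fraction; clipping")
        frac <- pmax(frac, 1e-6)
      }
      frac <- frac / sum(frac)
      lig <- wt_lignin[k] * ln$lignin_mult *
        (1 + rtrunc(1, design$lignin_noise_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        line_id = ln$line_id, internode = INTERNODES[k],
        h = frac[[1]], g = frac[[2]], s = frac[[3]],
        total_lignin = lig, alpha = ln$alpha, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  validate_observations(tab)
  tab
}

#' Validate an observation table
#'
#' Checks column presence, fraction validity (each in `[0,1]`, rows summing
#' to 1 within 1e-6), `alpha` in `(0, 1]`, and seven internode records per
#' line.
#'
#' @param table Observation data frame.
#' @return `table`, invisibly.
#' @export
validate_observations <- function(table) {
  need <- c("line_id", "internode", "h", "g", "s", "total_lignin", "alpha")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  frac <- as.matrix(table[, c("h", "g", "s")])
  if (any(frac < 0) || any(frac > 1)) stop("monomer fractions outside [0, 1]")
  bad <- which(abs(rowSums(frac) - 1) > 1e-6)
  if (length(bad)) stop("fractions do not sum to 1 in row(s): ",
                        paste(bad, collapse = ", "))
  if (any(table$alpha <= 0 | table$alpha > 1)) stop("alpha outside (0, 1]")
  cnt <- table(table$line_id)
  if (any(cnt != 7L))
    stop("expected 7 internode records per line; got: ",
         paste(names(cnt)[cnt != 7L], collapse = ", "))
  invisible(table)
}

#' Read / write observation tables as CSV
#'
#' The CSV dialect carries percentages: header
#' `line_id,internode,h_pct,g_pct,s_pct,total_lignin,alpha`.  Percentages are
#' accepted on the 0--100 scale and stored internally as fractions; rows
#' whose monomer percentages do not sum to 100 +/- 1 are rejected with the
#' offending row number.  Unknown columns are preserved on the round-trip.
#'
#' @param path CSV file path.
#' @param table Observation data frame (fraction columns `h`, `g`, `s`).
#' @return `read_observations` returns the observation data frame;
#'   `write_observations` returns `path` invisibly.
#' @export
read_observations <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("line_id", "internode", "h_pct", "g_pct", "s_pct",
            "total_lignin", "alpha")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  tot <- raw$h_pct + raw$g_pct + raw$s_pct
  bad <- which(abs(tot - 100) > 1)
  if (length(bad))
    stop("monomer percentages do not sum to 100 +/- 1 in row(s): ",
         paste(bad, collapse = ", "))
  tab <- data.frame(line_id = as.character(raw$line_id),
                    internode = as.character(raw$internode),
                    h = raw$h_pct / tot, g = raw$g_pct / tot,
                    s = raw$s_pct / tot,
                    total_lignin = raw$total_lignin, alpha = raw$alpha,
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(raw), need)
  for (cl in extra) tab[[cl]] <- raw[[cl]]
  tab
}

#' @rdname read_observations
#' @export
write_observations <- function(table, path) {
  need <- c("line_id", "internode", "h", "g", "s", "total_lignin", "alpha")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(line_id = table$line_id, internode = table$internode,
                    h_pct = 100 * table$h, g_pct = 100 * table$g,
                    s_pct = 100 * table$s,
                    total_lignin = table$total_lignin, alpha = table$alpha,
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(table), need)
  for (cl in extra) out[[cl]] <- table[[cl]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Composition of one observation row
#'
#' @param table Observation data frame.
#' @param line Line id.
#' @param internode Internode label.
#' @return A `monomer_composition`.
#' @export
observation_composition <- function(table, line, internode) {
  row <- table[table$line_id == line & table$internode == internode, ]
  if (nrow(row) != 1L) stop("no unique record for ", line, " internode ", internode)
  monomer_composition(row$h, row$g, row$s)
}
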