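#' Knockdown specification
#'
#' A transgenic down-regulation: the targeted enzyme retains at most a
#' fraction `alpha` of its wild-type activity, imposed as one inequality
#' `v_j <= alpha * v*_j` per reaction `j` the enzyme catalyzes.
#'
#' @param enzyme Enzyme symbol (a gene product; `TRANSPORT`/`OVERFLOW` are
#'   rejected).
#' @param alpha Residual activity fraction in `[0, 1]`.
#' @return An object of class `knockdown_spec`.
#' @export
knockdown_spec <- function(enzyme, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a single number in [0, 1]")
  if (enzyme %in% c("TRANSPORT", "OVERFLOW"))
    stop(enzyme, " is not a gene product; cannot be knocked down")
  structure(list(enzyme = enzyme, alpha = alpha), class = "knockdown_spec")
}

#' Knockdown inequality constraints
#'
#' Builds the mutant flux caps `v_j <= alpha * v*_j` for every reaction
#' catalyzed by the down-regulated enzyme (multi-function enzymes such as
#' COMT or CAD receive one constraint per catalyzed step).
#'
#' @param net A `lignin_network`.
#' @param spec A `knockdown_spec` (or enzyme + alpha via `...`).
#' @param wildtype_fluxes A `flux_distribution` for the wild-type reference
#'   `v*` (same internode).
#' @return Data frame with columns `reaction` and `bound`
#'   (`v_reaction <= bound`).
#' @export
knockdown_constraints <- function(net, spec, wildtype_fluxes) {
  stopifnot(inherits(spec, "knockdown_spec"),
            inherits(wildtype_fluxes, "flux_distribution"))
  rx <- reactions_for_enzyme(net, spec$enzyme, knockdown = TRUE)
  if (length(rx) == 0L) stop("enzyme maps to no reaction in this network")
  data.frame(reaction = rx,
             bound = spec$alpha * wildtype_fluxes$values[rx],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Assemble the mutant constraint set.  The wild-type normalization v1 = 1 is
# kept for the mutant, except when the knockdown itself targets v1 (a PAL
# line): there the equality would contradict v1 <= alpha < 1, so the
# normalization row is dropped and v1 is left free below its knockdown cap --
# the reading under which all transgenic lines admit solutions on the
# extended network.
.moma_matrices <- function(net, spec, mutant_composition, wildtype_fluxes) {
  problem <- fba_problem(net, mutant_composition)
  m <- .fba_matrices(problem)
  kc <- knockdown_constraints(net, spec, wildtype_fluxes)
  n <- length(m$ids)
  Ain <- matrix(0, nrow(kc), n,
                dimnames = list(paste0("knockdown_", kc$reaction), m$ids))
  Ain[cbind(seq_len(nrow(kc)), match(kc$reaction, m$ids))] <- 1
  bin <- kc$bound
  if ("v1" %in% kc$reaction && spec$alpha < 1) {
    keep <- rownames(m$Aeq) != "v1_normalization"
    m$Aeq <- m$Aeq[keep, , drop = FALSE]
    m$beq <- m$beq[keep]
  }
  c(m, list(Ain = Ain, bin = bin, problem = problem))
}

#' Predict a transgenic flux distribution by MOMA
#'
#' Minimization of metabolic adjustment: the mutant flux state is the point of
#' the mutant-feasible polytope (mass balance, bounds, the mutant's measured
#' monomer composition as proportionality constraints, and the knockdown
#' caps) closest to the wild-type reference in Euclidean distance over all
#' fluxes.  The problem is a strictly convex quadratic program, so the
#' solution is unique.
#'
#' @param net A `lignin_network` (extended for the published analysis).
#' @param spec A `knockdown_spec`.
#' @param mutant_composition The mutant's measured `monomer_composition`.
#' @param wildtype_fluxes Wild-type reference `flux_distribution` for the same
#'   internode.
#' @return An object of class `moma_result`: `fluxes` (a
#'   `flux_distribution`, policy `"moma"`), `distance`, and `feasible`.  When
#'   the constraint set is empty, `feasible` is `FALSE` and a `certificate`
#'   names an unsatisfiable balance (never an exception).
#' @export
solve_moma <- function(net, spec, mutant_composition, wildtype_fluxes) {
  m <- .moma_matrices(net, spec, mutant_composition, wildtype_fluxes)
  vstar <- wildtype_fluxes$values[m$ids]
  pr <- .qp_project(vstar, m$Aeq, m$beq, m$Ain, m$bin, m$lb, m$ub)
  if (!pr$feasible) {
    cert <- .infeasibility_certificate(m, m$Ain, m$bin)
    return(structure(list(feasible = FALSE, fluxes = NULL,
                          distance = NA_real_,
                          certificate = cert$certificate),
                     class = "moma_result"))
  }
  v <- stats::setNames(pr$x, m$ids)
  structure(list(feasible = TRUE,
                 fluxes = flux_distribution(v, policy = "moma"),
                 distance = pr$distance, certificate = character()),
            class = "moma_result")
}

#' @export
print.moma_result <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("MOMA solution: distance to wild-type reference %.6f\n",
                x$distance))
  } else {
    cat("MOMA infeasible; unsatisfiable balance at:",
        paste(x$certificate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Check feasibility of a mutant constraint set
#'
#' Decides whether any flux distribution satisfies the mutant constraints,
#' and when none does, names at least one metabolite whose mass balance
#' cannot be satisfied.  On the un-extended 21-reaction network a C4H
#' knockdown to 45% with `v1 = 1` is the canonical infeasible case: the
#' cinnamic-acid balance forces `v2 = v1 = 1`, contradicting
#' `v2 <= 0.45`; the overflow-extended network restores feasibility.
#'
#' @inheritParams solve_moma
#' @return List with `feasible` (flag) and `certificate` (character vector of
#'   metabolite ids, empty when feasible).
#' @export
check_feasibility <- function(net, spec, mutant_composition, wildtype_fluxes) {
  m <- .moma_matrices(net, spec, mutant_composition, wildtype_fluxes)
  lv <- .least_violation(m$Aeq, m$beq, m$Ain, m$bin, m$lb, m$ub)
  if (lv$feasible) return(list(feasible = TRUE, certificate = character()))
  cert <- .infeasibility_certificate(m, m$Ain, m$bin)
  list(feasible = FALSE, certificate = cert$certificate)
}
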