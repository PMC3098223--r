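#' Wild-type FBA problem
#'
#' Bundles a pathway network with a measured monomer composition into the
#' per-internode linear program: steady-state mass balance `N v = 0`,
#' normalization `v1 = 1`, flux bounds (overflows bounded below by 0.01 in the
#' extended network), the two proportionality constraints tying the transport
#' fluxes `v6`, `v15`, `v19` to the composition, and the objective of
#' maximizing total monomer production `v6 + v15 + v19`.
#'
#' @param network A `lignin_network` (the extended 24-reaction variant for
#'   wild-type analyses).
#' @param composition A `monomer_composition` (or length-3 vector).
#' @return An object of class `fba_problem`.
#' @export
fba_problem <- function(network, composition) {
  stopifnot(inherits(network, "lignin_network"))
  if (!inherits(composition, "monomer_composition")) {
    composition <- monomer_composition(composition[[1]], composition[[2]],
                                       composition[[3]])
  }
  structure(list(network = network, composition = composition),
            class = "fba_problem")
}

# Assemble the constraint matrices for a problem.  Rows of Aeq are named so
# infeasibility certificates can point at the violated balance.
.fba_matrices <- function(problem) {
  net <- problem$network
  N <- stoichiometric_matrix(net)
  ids <- net$reactions$id
  n <- length(ids)
  v1row <- as.numeric(ids == "v1")
  cc <- composition_constraints(problem$composition)
  comp_rows <- matrix(0, 2, n, dimnames = list(c("composition_h", "composition_g"), ids))
  comp_rows[, colnames(cc$A)] <- cc$A
  Aeq <- rbind(N, v1_normalization = v1row, comp_rows)
  beq <- c(rep(0, nrow(N)), 1, 0, 0)
  names(beq) <- rownames(Aeq)
  obj <- as.numeric(ids %in% c("v6", "v15", "v19"))
  list(Aeq = Aeq, beq = beq, lb = net$reactions$lower_bound,
       ub = net$reactions$upper_bound, obj = obj, ids = ids,
       met_rows = rownames(N))
}

#' Construct a flux distribution object
#'
#' @param values Named numeric vector of fluxes (names `v1`, `v2`, ...).
#' @param objective Objective value (total monomer transport).
#' @param policy Selection-policy tag (`"min-norm"`, `"main-route"`,
#'   `"vertex"`, `"moma"`, ...).
#' @return An object of class `flux_distribution`.
#' @export
flux_distribution <- function(values, objective = sum(values[c("v6", "v15", "v19")]),
                              policy = "unspecified") {
  stopifnot(!is.null(names(values)))
  structure(list(values = values, objective = objective, policy = policy),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("Flux distribution (%s): objective %.6f, %d fluxes\n",
              x$policy, x$objective, length(x$values)))
  print(round(x$values, 6))
  invisible(x)
}

#' Validate a flux distribution against its problem
#'
#' Checks `||N v||_inf <= tol`, `v1 = 1`, the flux bounds, and the
#' composition proportionality constraints.
#'
#' @param fd A `flux_distribution`.
#' @param problem The `fba_problem` it should satisfy.
#' @param tol Feasibility tolerance (default `1e-8`).
#' @return `TRUE` invisibly, or an error naming the violated constraint.
#' @export
validate_flux_distribution <- function(fd, problem, tol = 1e-8) {
  m <- .fba_matrices(problem)
  v <- fd$values[m$ids]
  resid <- abs(m$Aeq %*% v - m$beq)
  if (max(resid) > tol)
    stop("equality constraint violated: ", rownames(m$Aeq)[which.max(resid)],
         " (", format(max(resid)), ")")
  if (any(v < m$lb - tol) || any(v > m$ub + tol))
    stop("flux bound violated: ",
         m$ids[which.max(pmax(m$lb - v, v - m$ub))])
  invisible(TRUE)
}

#' Solve the wild-type FBA linear program
#'
#' Maximizes total monomer transport `v6 + v15 + v19` over the feasible flux
#' polytope.  Because every unit of `v1` ends in exactly one of the six sinks,
#' the optimum pins the three overflow fluxes at their 0.01 lower bounds and
#' equals `1 - (v22+v23+v24) = 0.97` whenever the problem is feasible.  Among
#' the (generally non-unique) optimal flux distributions the solver returns
#' the minimum-Euclidean-norm point of the optimal face, which is also the
#' package's default unique reference selection.
#'
#' @param problem An `fba_problem`.
#' @return A `flux_distribution` (policy `"min-norm"`) when feasible;
#'   otherwise an object of class `fba_infeasibility` carrying a
#'   `certificate` naming at least one metabolite whose balance cannot be
#'   satisfied.
#' @export
solve_fba <- function(problem) {
  m <- .fba_matrices(problem)
  ans <- .lp_solve(m$obj, m$Aeq, m$beq, lb = m$lb, ub = m$ub, maximize = TRUE)
  if (ans$status == "infeasible") {
    return(.infeasibility_certificate(m))
  }
  if (ans$status != "optimal")
    stop("LP regularization path could not be certified")
  v <- stats::setNames(ans$x, m$ids)
  fd <- flux_distribution(v, objective = ans$objective, policy = "min-norm")
  validate_flux_distribution(fd, problem)
  fd
}

.infeasibility_certificate <- function(m, Ain = NULL, bin = NULL) {
  lv <- .least_violation(m$Aeq, m$beq, Ain, bin, m$lb, m$ub)
  res <- lv$residuals
  internal <- intersect(rownames(m$Aeq), m$met_rows)
  viol <- internal[abs(res[internal]) > lv$tol]
  if (length(viol) == 0L) viol <- names(res)[abs(res) > lv$tol]
  structure(list(feasible = FALSE, certificate = viol, residuals = res),
            class = "fba_infeasibility")
}

#' @export
print.fba_infeasibility <- function(x, ...) {
  cat("Infeasible constraint set; unsatisfiable balance at:",
      paste(x$certificate, collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate the vertices of the optimal face
#'
#' The maximization of monomer production usually leaves routing freedom (the
#' CCoAOMT--CCR1 vs. CCR2--COMT parallel routes, and the aldehyde- vs.
#' alcohol-level F5H routes), so the optimum is a face of the flux polytope
#' rather than a point.  This enumerates all its vertices: flux ranges on the
#' face are computed first (flux variability restricted to the optimal face),
#' constant fluxes are pinned, and all combinations of `d` active bounds
#' (`d` = face dimension) are solved and screened for feasibility.
#'
#' @param problem An `fba_problem`.
#' @param optimum Optional `flux_distribution` from [solve_fba()]; solved
#'   internally when omitted.
#' @param tol Numerical tolerance for pinning and feasibility screening.
#' @return An object of class `optimal_face`: list with `vertices` (list of
#'   named flux vectors), `objective`, `dim`, `ranges` (FVA ranges on the
#'   face) and the defining matrices.
#' @export
enumerate_alternate_optima <- function(problem, optimum = NULL, tol = 1e-7) {
  m <- .fba_matrices(problem)
  if (is.null(optimum)) optimum <- solve_fba(problem)
  if (inherits(optimum, "fba_infeasibility"))
    stop("cannot enumerate optima of an infeasible problem")
  fstar <- optimum$objective
  AeqF <- rbind(m$Aeq, objective = m$obj)
  beqF <- c(m$beq, objective = fstar)
  n <- length(m$ids)

  # flux variability on the optimal face
  lo <- hi <- numeric(n)
  for (j in seq_len(n)) {
    e <- as.numeric(seq_len(n) == j)
    lo[j] <- .lp_solve(e, AeqF, beqF, lb = m$lb, ub = m$ub)$objective
    hi[j] <- .lp_solve(e, AeqF, beqF, lb = m$lb, ub = m$ub, maximize = TRUE)$objective
  }
  pinned <- which(hi - lo <= tol)
  free <- setdiff(seq_len(n), pinned)
  pin_rows <- matrix(0, length(pinned), n)
  pin_rows[cbind(seq_along(pinned), pinned)] <- 1
  A2 <- rbind(AeqF, pin_rows)
  b2 <- c(beqF, (lo[pinned] + hi[pinned]) / 2)
  d <- n - qr(A2, tol = 1e-10)$rank

  ranges <- data.frame(id = m$ids, min = lo, max = hi)
  face <- list(Aeq = AeqF, beq = beqF, lb = m$lb, ub = m$ub, ids = m$ids)

  if (d == 0) {
    v <- qr.solve(A2, b2, tol = 1e-10)
    verts <- list(stats::setNames(v, m$ids))
  } else {
    # candidate active bounds: bounds actually attainable on the face
    cand <- list()
    for (j in free) {
      if (lo[j] <= m$lb[j] + tol) cand <- c(cand, list(c(j, m$lb[j])))
      if (hi[j] >= m$ub[j] - tol) cand <- c(cand, list(c(j, m$ub[j])))
    }
    if (length(cand) < d) stop("degenerate face: not enough candidate bounds")
    combos <- utils::combn(length(cand), d, simplify = FALSE)
    verts <- list()
    seen <- character()
    for (cb in combos) {
      rows <- matrix(0, d, n)
      rhs <- numeric(d)
      for (k in seq_len(d)) {
        rows[k, cand[[cb[k]]][1]] <- 1
        rhs[k] <- cand[[cb[k]]][2]
      }
      A3 <- rbind(A2, rows)
      b3 <- c(b2, rhs)
      if (qr(A3, tol = 1e-10)$rank < n) next
      v <- try(qr.solve(A3, b3, tol = 1e-10), silent = TRUE)
      if (inherits(v, "try-error")) next
      if (max(abs(A3 %*% v - b3)) > 1e-6) next
      if (any(v < m$lb - tol) || any(v > m$ub + tol)) next
      key <- paste(round(v, 8), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      verts <- c(verts, list(stats::setNames(as.numeric(v), m$ids)))
    }
  }
  structure(list(vertices = verts, objective = fstar, dim = d,
                 ranges = ranges, face = face, problem = problem),
            class = "optimal_face")
}

#' @export
print.optimal_face <- function(x, ...) {
  cat(sprintf("Optimal face: objective %.6f, dimension %d, %d vertices\n",
              x$objective, x$dim, length(x$vertices)))
  invisible(x)
}

#' Select a unique reference flux distribution
#'
#' Reduces the optimal face to a single, reproducible wild-type reference
#' point.  Policy `"min-norm"` takes the minimum-Euclidean-norm point of the
#' face (unique by strict convexity).  Policy `"main-route"` first
#' lexicographically minimizes `v10` (the CCR2 shunt, dispensable in wild-type
#' plants) and then `v20` (the alcohol-level F5H route) before applying the
#' norm criterion; on the reference network this routes all G/S flux through
#' CCoAOMT--CCR1 and the aldehyde-level F5H step.
#'
#' @param face An `optimal_face` from [enumerate_alternate_optima()].
#' @param policy `"min-norm"` (default) or `"main-route"`.
#' @return A `flux_distribution`.
#' @export
select_reference_distribution <- function(face,
                                          policy = c("min-norm", "main-route")) {
  policy <- match.arg(policy)
  stopifnot(inherits(face, "optimal_face"))
  f <- face$face
  if (length(face$vertices) == 1L && face$dim == 0L) {
    return(flux_distribution(face$vertices[[1]], objective = face$objective,
                             policy = policy))
  }
  Aeq <- f$Aeq
  beq <- f$beq
  if (policy == "main-route") {
    for (target in c("v10", "v20")) {
      e <- as.numeric(f$ids == target)
      val <- .lp_solve(e, Aeq, beq, lb = f$lb, ub = f$ub)$objective
      Aeq <- rbind(Aeq, e)
      beq <- c(beq, val)
    }
  }
  pr <- .qp_project(rep(0, length(f$ids)), Aeq, beq, lb = f$lb, ub = f$ub)
  if (!pr$feasible) stop("optimal face projection failed")
  flux_distribution(stats::setNames(pr$x, f$ids), objective = face$objective,
                    policy = policy)
}
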