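# Internal convex-optimization layer.
#
# Every linear or quadratic program in the package is solved through the
# Goldfarb-Idnani dual active-set method (quadprog::solve.QP), which is exact
# for positive-definite QPs and needs no starting point.  Linear programs are
# solved on the regularization path: for eps below a finite problem-dependent
# threshold, the minimizer of eps/2*||x||^2 - c'x over a polytope is *exactly*
# the least-norm point of the LP's optimal face (the LP "normal solution").
# We solve at two eps values and require agreement, which certifies that the
# threshold was passed; the LP objective value is then exact, and the returned
# point is the minimum-norm optimizer -- which is also precisely the unique
# flux-distribution selection rule this package defaults to.
#
# Problems are expressed as:  Aeq x = beq,  Ain x <= bin,  lb <= x <= ub.

.qp_call <- function(Dmat, dvec, Aeq, beq, Ain, bin, lb, ub) {
  n <- length(dvec)
  rows <- Aeq
  rhs <- beq
  meq <- length(beq)
  if (!is.null(Ain) && nrow(Ain) > 0) {
    rows <- rbind(rows, -Ain)
    rhs <- c(rhs, -bin)
  }
  fin_lb <- which(is.finite(lb))
  if (length(fin_lb)) {
    B <- matrix(0, length(fin_lb), n)
    B[cbind(seq_along(fin_lb), fin_lb)] <- 1
    rows <- rbind(rows, B)
    rhs <- c(rhs, lb[fin_lb])
  }
  fin_ub <- which(is.finite(ub))
  if (length(fin_ub)) {
    B <- matrix(0, length(fin_ub), n)
    B[cbind(seq_along(fin_ub), fin_ub)] <- -1
    rows <- rbind(rows, B)
    rhs <- c(rhs, -ub[fin_ub])
  }
  quadprog::solve.QP(Dmat, dvec, t(rows), rhs, meq = meq)
}

# Minimize 0.5*||x - target||^2 subject to the polytope; `feasible = FALSE`
# (never an exception) when the constraint set is empty.  The Goldfarb-Idnani
# active-set path can spuriously report "inconsistent constraints" on
# degenerate vertices, so an error is retried under tiny reformulations
# (scaled metric, hair-relaxed bounds) before the set is declared empty.
.qp_project <- function(target, Aeq, beq, Ain = NULL, bin = NULL,
                        lb = rep(-Inf, length(target)),
                        ub = rep(Inf, length(target))) {
  n <- length(target)
  attempts <- list(
    function() .qp_call(diag(2, n), 2 * target, Aeq, beq, Ain, bin, lb, ub),
    function() .qp_call(diag(0.5, n), 0.5 * target, Aeq, beq, Ain, bin, lb, ub),
    function() .qp_call(diag(2, n), 2 * target, Aeq, beq, Ain, bin,
                        lb - 1e-11, ub + 1e-11)
  )
  for (f in attempts) {
    ans <- try(f(), silent = TRUE)
    if (!inherits(ans, "try-error")) {
      return(list(feasible = TRUE, x = ans$solution,
                  distance = sqrt(sum((ans$solution - target)^2))))
    }
  }
  list(feasible = FALSE, x = NULL, distance = NA_real_)
}

# Exact LP via the regularization path.  maximize=TRUE flips the sign of obj.
# Returns the least-norm optimizer; status "infeasible" when the polytope is
# empty, "unverified" if the two-eps certification fails even after shrinking.
.lp_solve <- function(obj, Aeq, beq, Ain = NULL, bin = NULL,
                      lb, ub, maximize = FALSE, check_tol = 1e-7) {
  n <- length(obj)
  cc <- if (maximize) obj else -obj
  solve_eps <- function(e) {
    ans <- try(.qp_call(diag(e, n), cc, Aeq, beq, Ain, bin, lb, ub),
               silent = TRUE)
    if (inherits(ans, "try-error")) NULL else ans$solution
  }
  # the path is piecewise: once eps is below a finite threshold the solution
  # is exactly the least-norm LP optimum, so two agreeing eps values certify
  # optimality.  Individual eps values can fail on degenerate active sets,
  # hence the ladder.
  ladder <- c(1e-3, 1e-4, 2.5e-5, 1e-5, 2.5e-6, 1e-2)
  sols <- list()
  for (e in ladder) {
    x <- solve_eps(e)
    if (is.null(x)) next
    for (prev in sols) {
      if (max(abs(x - prev)) <= check_tol) {
        return(list(status = "optimal", x = x, objective = sum(obj * x)))
      }
    }
    sols <- c(sols, list(x))
  }
  if (length(sols) == 0L) {
    # distinguish genuine infeasibility from solver failure
    pr <- .qp_project(rep(0, n), Aeq, beq, Ain, bin, lb, ub)
    if (!pr$feasible)
      return(list(status = "infeasible", x = NULL, objective = NA_real_))
    return(list(status = "unverified", x = pr$x, objective = sum(obj * pr$x)))
  }
  x <- sols[[length(sols)]]
  list(status = "unverified", x = x, objective = sum(obj * x))
}

# Least-violation certificate: minimize ||s||^2 over (x, s) with
# Aeq x - s = beq plus the inequalities/bounds on x.  A tiny ridge on x keeps
# the QP positive definite; it biases x, not the attainable violation, beyond
# O(ridge).  Residuals above `tol` name the unsatisfiable balance rows.
.least_violation <- function(Aeq, beq, Ain = NULL, bin = NULL, lb, ub,
                             ridge = 1e-7, tol = 1e-6) {
  n <- ncol(Aeq)
  m <- nrow(Aeq)
  Dmat <- diag(c(rep(ridge, n), rep(1, m)))
  AeqS <- cbind(Aeq, -diag(m))
  AinS <- if (!is.null(Ain) && nrow(Ain) > 0)
    cbind(Ain, matrix(0, nrow(Ain), m)) else NULL
  ans <- try(.qp_call(Dmat, rep(0, n + m), AeqS, beq, AinS, bin,
                      c(lb, rep(-Inf, m)), c(ub, rep(Inf, m))),
             silent = TRUE)
  if (inherits(ans, "try-error")) {
    # bounds/inequalities alone are inconsistent (cannot occur for box bounds
    # with lb <= ub); report global infeasibility with no named row
    return(list(feasible = FALSE, residuals = rep(NA_real_, m)))
  }
  s <- ans$solution[n + seq_len(m)]
  names(s) <- rownames(Aeq)
  list(feasible = max(abs(s)) <= tol, residuals = s, tol = tol)
}
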