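# Reduced kinetic model of the caffeoyl-CoA -> coniferyl aldehyde region and
# the two principal branch points where G- and S-lignin fluxes diverge.
#
# Species:  caffeoyl-CoA (fed by a constant influx J), feruloyl-CoA, caffeyl
# aldehyde, coniferyl aldehyde, coniferyl alcohol.
# Reactions (8, each with vmax and km, optionally a Hill exponent):
#   v10 CCR2     caffeoyl-CoA      -> caffeyl aldehyde
#   v11 CCoAOMT  caffeoyl-CoA      -> feruloyl-CoA
#   v12 COMT     caffeyl aldehyde  -> coniferyl aldehyde
#   v13 CCR1     feruloyl-CoA      -> coniferyl aldehyde
#   v14 CAD      coniferyl aldehyde-> coniferyl alcohol
#   v15 export   coniferyl alcohol -> G pool
#   v16 F5H      coniferyl aldehyde-> S pool (downstream S machinery lumped)
#   v20 F5H      coniferyl alcohol -> S pool (alcohol-level route, lumped)
# In Michaelis-Menten mode the model therefore has exactly 16 free kinetic
# parameters.

.BRANCH_REACTIONS <- c("v10", "v11", "v12", "v13", "v14", "v15", "v16", "v20")

#' Kinetic parameters of one branch-model reaction
#'
#' @param reaction One of `v10, v11, v12, v13, v14, v15, v16, v20`.
#' @param vmax Maximal rate (> 0, model units of concentration/time).
#' @param km Half-saturation constant (> 0, concentration units).
#' @param hill_n Hill cooperativity coefficient (>= 1; 1 gives
#'   Michaelis-Menten kinetics).
#' @return Object of class `branch_kinetics`.
#' @export
branch_kinetics <- function(reaction, vmax, km, hill_n = 1) {
  if (!(reaction %in% .BRANCH_REACTIONS))
    stop("reaction must be one of: ", paste(.BRANCH_REACTIONS, collapse = ", "))
  if (!is.finite(vmax) || vmax <= 0) stop("vmax must be > 0")
  if (!is.finite(km) || km <= 0) stop("km must be > 0")
  if (!is.finite(hill_n) || hill_n < 1) stop("hill_n must be >= 1")
  structure(list(reaction = reaction, vmax = vmax, km = km, hill_n = hill_n),
            class = "branch_kinetics")
}

#' Michaelis-Menten / Hill reaction rate
#'
#' `vmax * c^n / (km^n + c^n)`: zero at `c = 0`, `vmax/2` at `c = km`,
#' saturating at `vmax`.
#'
#' @param kinetics A `branch_kinetics`.
#' @param substrate_conc Substrate concentration(s), >= 0.
#' @return Rate(s), same length as `substrate_conc`.
#' @export
reaction_rate <- function(kinetics, substrate_conc) {
  stopifnot(inherits(kinetics, "branch_kinetics"))
  if (any(substrate_conc < 0) || any(!is.finite(substrate_conc)))
    stop("substrate concentration must be finite and >= 0")
  cn <- substrate_conc^kinetics$hill_n
  kinetics$vmax * cn / (kinetics$km^kinetics$hill_n + cn)
}

# inverse of the rate law: the concentration at which the reaction runs at
# rate u (requires 0 <= u < vmax)
.rate_inverse <- function(k, u) {
  k$km * (u / (k$vmax - u))^(1 / k$hill_n)
}

#' Reduced kinetic branch-point model
#'
#' @param kinetics List of eight `branch_kinetics`, one per reaction of the
#'   reduced model (any order; matched by reaction id).
#' @param influx Constant influx `J` into caffeoyl-CoA (> 0).  `J` is a fixed
#'   boundary condition of the model, not a kinetic parameter.
#' @return Object of class `branch_model`.
#' @export
branch_model <- function(kinetics, influx) {
  if (!is.finite(influx) || influx <= 0) stop("influx J must be > 0")
  ids <- vapply(kinetics, function(k) k$reaction, character(1))
  if (!setequal(ids, .BRANCH_REACTIONS) || length(ids) != 8L)
    stop("kinetics must cover exactly the 8 branch-model reactions")
  names(kinetics) <- ids
  structure(list(kinetics = kinetics[.BRANCH_REACTIONS], influx = influx),
            class = "branch_model")
}

#' Number of free kinetic parameters
#'
#' Sixteen (8 reactions x \{vmax, km\}) in Michaelis-Menten mode; the eight
#' Hill exponents count as additional free parameters when any exceeds 1.
#'
#' @param model A `branch_model`.
#' @return Integer.
#' @export
n_free_parameters <- function(model) {
  stopifnot(inherits(model, "branch_model"))
  hill <- any(vapply(model$kinetics, function(k) k$hill_n, numeric(1)) > 1)
  if (hill) 24L else 16L
}

# monotone 1-d solve: sum of rates over `ids` equals `target`
.solve_pool <- function(model, ids, target, cap = 1e12) {
  ks <- model$kinetics[ids]
  total_vmax <- sum(vapply(ks, function(k) k$vmax, numeric(1)))
  if (total_vmax <= target * (1 + 1e-12)) return(NULL)
  f <- function(conc) sum(vapply(ks, reaction_rate, numeric(1),
                                 substrate_conc = conc)) - target
  hi <- max(vapply(ks, function(k) k$km, numeric(1)))
  while (f(hi) < 0) {
    hi <- hi * 10
    if (hi > cap) return(NULL)
  }
  stats::uniroot(f, c(0, hi), tol = .Machine$double.eps^0.75)$root
}

#' Steady state of the branch model
#'
#' Solves the steady-state equations exactly by walking the feedforward
#' cascade: the caffeoyl-CoA pool is found from
#' `r10(C) + r11(C) = J` (monotone in `C`), the linear steps are inverted in
#' closed form, and the two branch-point pools solve the analogous monotone
#' one-dimensional balances.  The steady state is unique and globally
#' attracting whenever the capacity conditions hold; when total downstream
#' capacity falls short of the influx at any pool, the substrate accumulates
#' without bound and the model has no steady state (`converged = FALSE` with
#' a diagnostic naming the saturated pool).
#'
#' @param model A `branch_model`.
#' @return Object of class `branch_steady_state`: `concentrations` (5 pools),
#'   `fluxes` (8 reactions), `g_flux` (`v15`), `s_flux` (`v16 + v20`),
#'   `sg_ratio`, `converged`, `diagnostic`, `residual` (largest net
#'   production rate among pools; ~0 at a true steady state).
#' @export
steady_state <- function(model) {
  stopifnot(inherits(model, "branch_model"))
  J <- model$influx
  fail <- function(where) {
    structure(list(concentrations = NULL, fluxes = NULL,
                   g_flux = NA_real_, s_flux = NA_real_,
                   sg_ratio = NA_real_, converged = FALSE,
                   residual = NA_real_,
                   diagnostic = paste0("no steady state: capacity exceeded at ",
                                       where)),
              class = "branch_steady_state")
  }
  ks <- model$kinetics
  C <- .solve_pool(model, c("v10", "v11"), J)
  if (is.null(C)) return(fail("caffeoyl-CoA"))
  r10 <- reaction_rate(ks$v10, C)
  r11 <- J - r10
  if (r11 >= ks$v13$vmax) return(fail("feruloyl-CoA"))
  if (r10 >= ks$v12$vmax) return(fail("caffeyl aldehyde"))
  Fer <- .rate_inverse(ks$v13, r11)
  Cal <- .rate_inverse(ks$v12, r10)
  CA <- .solve_pool(model, c("v14", "v16"), J)
  if (is.null(CA)) return(fail("coniferyl aldehyde"))
  r14 <- reaction_rate(ks$v14, CA)
  r16 <- J - r14
  A <- .solve_pool(model, c("v15", "v20"), r14)
  if (is.null(A)) return(fail("coniferyl alcohol"))
  r15 <- reaction_rate(ks$v15, A)
  r20 <- r14 - r15
  conc <- c(caffeoyl_CoA = C, feruloyl_CoA = Fer, caffeyl_aldehyde = Cal,
            coniferyl_aldehyde = CA, coniferyl_alcohol = A)
  flux <- c(v10 = r10, v11 = r11, v12 = r10, v13 = r11, v14 = r14,
            v15 = r15, v16 = r16, v20 = r20)
  residual <- max(abs(c(J - r10 - r11,
                        r11 - reaction_rate(ks$v13, Fer),
                        r10 - reaction_rate(ks$v12, Cal),
                        r10 + r11 - r14 - r16,
                        r14 - r15 - r20)))
  structure(list(concentrations = conc, fluxes = flux,
                 g_flux = r15, s_flux = r16 + r20,
                 sg_ratio = (r16 + r20) / r15,
                 converged = TRUE, residual = residual, diagnostic = "ok"),
            class = "branch_steady_state")
}

#' @export
print.branch_steady_state <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Branch steady state: G flux %.4f, S flux %.4f, S/G %.4f\n",
                x$g_flux, x$s_flux, x$sg_ratio))
  } else {
    cat("Branch model:", x$diagnostic, "\n")
  }
  invisible(x)
}

#' Integrate the branch model ODEs
#'
#' Numerical integration of the five-pool ODE system from zero initial
#' concentrations with `deSolve::lsoda`.  This is the dynamic route to the
#' same steady state computed exactly by [steady_state()] and serves as an
#' independent cross-check; it also exposes the transient.
#'
#' @param model A `branch_model`.
#' @param times Output time points (default `seq(0, 1000, length.out = 51)`).
#' @param ... Passed to [deSolve::ode()] (e.g. `rtol`, `atol`).
#' @return A `deSolve` matrix: time and the five concentrations.
#' @export
integrate_branch_model <- function(model,
                                   times = seq(0, 1000, length.out = 51),
                                   ...) {
  stopifnot(inherits(model, "branch_model"))
  ks <- model$kinetics
  J <- model$influx
  deriv <- function(t, y, parms) {
    r10 <- reaction_rate(ks$v10, y[1]); r11 <- reaction_rate(ks$v11, y[1])
    r13 <- reaction_rate(ks$v13, y[2]); r12 <- reaction_rate(ks$v12, y[3])
    r14 <- reaction_rate(ks$v14, y[4]); r16 <- reaction_rate(ks$v16, y[4])
    r15 <- reaction_rate(ks$v15, y[5]); r20 <- reaction_rate(ks$v20, y[5])
    list(c(J - r10 - r11, r11 - r13, r10 - r12,
           r12 + r13 - r14 - r16, r14 - r15 - r20))
  }
  y0 <- stats::setNames(rep(0, 5),
                        c("caffeoyl_CoA", "feruloyl_CoA", "caffeyl_aldehyde",
                          "coniferyl_aldehyde", "coniferyl_alcohol"))
  deSolve::ode(y0, times, deriv, parms = NULL, ...)
}

#' S/G response to an enzyme knockdown
#'
#' Multiplies the vmax of the targeted reaction (`v11` for CCoAOMT, `v13` for
#' CCR1) by `factor`, re-solves the steady state, and reports the baseline
#' and perturbed S/G ratios together with the relative change
#' `(sg_perturbed - sg_baseline) / sg_baseline`.  A perturbed model whose
#' steady state no longer exists is flagged (`converged = FALSE`, relative
#' change `NA`) so that ensemble summaries can exclude it.
#'
#' @param model A `branch_model` whose baseline steady state exists.
#' @param target_enzyme `"CCoAOMT"` or `"CCR1"`.
#' @param factor Residual activity factor in `(0, 1]` (0.2 models an 80%
#'   knockdown).
#' @return List: `sg_baseline`, `sg_perturbed`, `relative_change`,
#'   `converged`.
#' @export
perturbation_response <- function(model,
                                  target_enzyme = c("CCoAOMT", "CCR1"),
                                  factor) {
  target_enzyme <- match.arg(target_enzyme)
  if (!is.finite(factor) || factor <= 0 || factor > 1)
    stop("factor must be in (0, 1]")
  base <- steady_state(model)
  if (!base$converged) stop("baseline model has no steady state")
  target <- c(CCoAOMT = "v11", CCR1 = "v13")[[target_enzyme]]
  pk <- model$kinetics
  pk[[target]]$vmax <- pk[[target]]$vmax * factor
  pert <- steady_state(branch_model(pk, model$influx))
  if (!pert$converged) {
    return(list(sg_baseline = base$sg_ratio, sg_perturbed = NA_real_,
                relative_change = NA_real_, converged = FALSE))
  }
  list(sg_baseline = base$sg_ratio, sg_perturbed = pert$sg_ratio,
       relative_change = (pert$sg_ratio - base$sg_ratio) / base$sg_ratio,
       converged = TRUE)
}
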