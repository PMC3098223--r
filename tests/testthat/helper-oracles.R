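# Independent oracles used to cross-check the solver layer.  Each oracle is a
# different algorithm from the implementation path it checks: a constructive
# closed-form optimum for the wild-type LP, exhaustive simplex-basis
# enumeration for the optimal-face vertices, Dykstra alternating projections
# for the MOMA quadratic program, and stiff ODE integration for the kinetic
# steady states.

# Constructive optimum of the wild-type FBA problem on the extended network:
# every unit of v1 ends in one of the six sinks, so the objective
# v6+v15+v19 = 1 - (v22+v23+v24) <= 1 - 3*0.01, and the bound is attained by
# the explicit main-route point below.  Returns the certified optimal
# objective together with a feasible point attaining it.
oracle_fba_optimum <- function(comp) {
  if (!inherits(comp, "monomer_composition"))
    comp <- monomer_composition(comp[1], comp[2], comp[3])
  total <- 1 - 3 * 0.01
  v <- stats::setNames(numeric(24), paste0("v", 1:24))
  v["v1"] <- 1
  v[c("v22", "v23", "v24")] <- 0.01
  v["v2"] <- v["v3"] <- 1 - 0.01
  v["v6"] <- comp[["h"]] * total
  v["v15"] <- comp[["g"]] * total
  v["v19"] <- comp[["s"]] * total
  v["v4"] <- v["v5"] <- v["v6"]
  v["v7"] <- v["v8"] <- v["v9"] <- v["v3"] - v["v4"] - v["v23"]
  v["v10"] <- v["v12"] <- 0
  v["v11"] <- v["v13"] <- v["v9"]
  v["v21"] <- 0
  v["v20"] <- 0.01
  v["v16"] <- v["v17"] <- v["v18"] <- v["v19"]
  v["v14"] <- v["v15"] + v["v20"]
  list(objective = total, point = v)
}

# Exhaustive basis enumeration of the vertices of the optimal face
# {Aeq v = beq, obj'v = fstar, lb <= v <= ub}: shift to v = lb + s, s >= 0,
# and solve every full-rank square basis.  Assumes (as holds on the wild-type
# optimal face, where all fluxes stay below 0.99) that upper bounds are
# inactive.
oracle_face_vertices <- function(Aeq, beq, obj, fstar, lb, ub) {
  A <- rbind(Aeq, obj)
  b <- c(beq, fstar)
  n <- ncol(A)
  bshift <- as.numeric(b - A %*% lb)
  rk <- qr(A)$rank
  combos <- utils::combn(n, rk, simplify = FALSE)
  verts <- list()
  seen <- character()
  for (S in combos) {
    q <- qr(A[, S, drop = FALSE])
    if (q$rank < rk) next
    xS <- qr.coef(q, bshift)
    if (any(is.na(xS))) next
    x <- rep(0, n)
    x[S] <- xS
    if (max(abs(A %*% x - bshift)) > 1e-8) next
    v <- x + lb
    if (any(v < lb - 1e-9) || any(v > ub + 1e-9)) next
    key <- paste(round(v, 8), collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      verts <- c(verts, list(stats::setNames(v, colnames(Aeq))))
    }
  }
  verts
}

vertex_keys <- function(vertices, digits = 6) {
  sort(vapply(vertices, function(v) paste(round(v, digits), collapse = ","),
              character(1)))
}

# Constraint matrices of a mutant MOMA problem, assembled here independently
# of the package's internal problem builder (from the public network
# primitives), for use by the Dykstra oracle.
oracle_moma_constraints <- function(net, enzyme, alpha, comp, wt) {
  N <- stoichiometric_matrix(net)
  ids <- colnames(N)
  n <- length(ids)
  cc <- composition_constraints(comp)
  comp_rows <- matrix(0, 2, n, dimnames = list(c("h", "g"), ids))
  comp_rows[, colnames(cc$A)] <- cc$A
  Aeq <- rbind(N, v1 = as.numeric(ids == "v1"), comp_rows)
  beq <- c(rep(0, nrow(N)), 1, 0, 0)
  rx <- reactions_for_enzyme(net, enzyme)
  Ain <- matrix(0, length(rx), n, dimnames = list(rx, ids))
  Ain[cbind(seq_along(rx), match(rx, ids))] <- 1
  bin <- alpha * as.numeric(wt$values[rx])
  list(Aeq = Aeq, beq = beq, Ain = Ain, bin = bin,
       lb = net$reactions$lower_bound, ub = net$reactions$upper_bound,
       ids = ids)
}

# Dykstra's alternating-projection method: the MOMA solution is the Euclidean
# projection of the wild-type reference onto the intersection of the affine
# balance set, the box, and the knockdown halfspaces, so cyclic projections
# with Dykstra corrections converge to it from first principles.
oracle_moma_dykstra <- function(net, enzyme, alpha, comp, wt, iters = 40000) {
  m <- oracle_moma_constraints(net, enzyme, alpha, comp, wt)
  target <- as.numeric(wt$values[m$ids])
  n <- length(target)
  AAt <- m$Aeq %*% t(m$Aeq)
  chA <- chol(AAt)
  proj_affine <- function(x) {
    r <- m$Aeq %*% x - m$beq
    x - as.numeric(t(m$Aeq) %*% backsolve(chA, forwardsolve(t(chA), r)))
  }
  proj_box <- function(x) pmin(pmax(x, m$lb), m$ub)
  hs <- lapply(seq_len(nrow(m$Ain)), function(i) {
    a <- as.numeric(m$Ain[i, ])
    list(a = a, b = m$bin[i], nn = sum(a * a))
  })
  proj_hs <- function(x, h) {
    viol <- sum(h$a * x) - h$b
    if (viol > 0) x - viol / h$nn * h$a else x
  }
  feas_gap <- function(x) {
    max(max(abs(m$Aeq %*% x - m$beq)),
        max(m$lb - x, 0), max(x - m$ub, 0),
        if (length(hs)) max(vapply(hs, function(h) sum(h$a * x) - h$b,
                                   numeric(1)), 0) else 0)
  }
  nsets <- 2 + length(hs)
  incs <- replicate(nsets, rep(0, n), simplify = FALSE)
  x <- target
  prev_d <- Inf
  for (it in seq_len(iters)) {
    for (k in seq_len(nsets)) {
      y <- x + incs[[k]]
      xn <- if (k == 1) proj_affine(y)
            else if (k == 2) proj_box(y)
            else proj_hs(y, hs[[k - 2]])
      incs[[k]] <- y - xn
      x <- xn
    }
    if (it %% 250 == 0) {
      d <- sqrt(sum((x - target)^2))
      # stop only once the iterate is both stationary and feasible
      if (abs(d - prev_d) < 1e-13 && feas_gap(x) < 1e-9) break
      prev_d <- d
    }
  }
  list(x = stats::setNames(x, m$ids), distance = sqrt(sum((x - target)^2)))
}

# random feasible composition (all fractions strictly positive)
random_composition <- function() {
  f <- stats::rexp(3) + 0.02
  monomer_composition(f[1], f[2], f[3])
}

# a fixed, well-behaved Michaelis-Menten branch model (all steps far from
# their capacity at influx J)
reference_branch_model <- function(J = 0.5, vmax = 2, km = 1, hill_n = 1) {
  ks <- lapply(c("v10", "v11", "v12", "v13", "v14", "v15", "v16", "v20"),
               branch_kinetics, vmax = vmax, km = km, hill_n = hill_n)
  branch_model(ks, J)
}

wt_reference <- function(policy = "main-route",
                         comp = monomer_composition(7, 85.5, 7.4)) {
  net <- build_reference_network("extended")
  prob <- fba_problem(net, comp)
  face <- enumerate_alternate_optima(prob)
  select_reference_distribution(face, policy)
}
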