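net_ext <- build_reference_network("extended")
anchor <- monomer_composition(7, 85.5, 7.4)

test_that("wild-type FBA reproduces the internode 1-2 solution", {
  sol <- solve_fba(fba_problem(net_ext, anchor))
  expect_s3_class(sol, "flux_distribution")
  expect_equal(sol$objective, 0.97, tolerance = 1e-9)
  v <- sol$values
  expect_equal(sum(v[c("v6", "v15", "v19")]), 0.97, tolerance = 1e-9)
  # v6 = h * 0.97 with h renormalized from the printed 7/85.5/7.4
  expect_equal(unname(v[["v6"]]), 0.97 * 7 / 99.9, tolerance = 1e-9)
  # overflows pinned at their lower bounds by the maximization
  expect_equal(unname(v[c("v22", "v23", "v24")]), rep(0.01, 3),
               tolerance = 1e-9)
  expect_true(validate_flux_distribution(sol, fba_problem(net_ext, anchor)))
})

test_that("degenerate all-H composition forces a pure H route", {
  sol <- solve_fba(fba_problem(net_ext, monomer_composition(1, 0, 0)))
  expect_equal(unname(sol$values[["v15"]]), 0, tolerance = 1e-9)
  expect_equal(unname(sol$values[["v19"]]), 0, tolerance = 1e-9)
  expect_equal(unname(sol$values[["v6"]]), 0.97, tolerance = 1e-9)
})

test_that("LP objective matches the constructive oracle on random compositions", {
  set.seed(101)
  for (i in 1:25) {
    comp <- random_composition()
    orc <- oracle_fba_optimum(comp)
    sol <- solve_fba(fba_problem(net_ext, comp))
    expect_equal(sol$objective, orc$objective, tolerance = 1e-8)
    # the oracle's point is feasible, so the optimum can be no smaller;
    # check the solution also honours the S/G ratio of the composition
    expect_equal(sol$values[["v19"]] / sol$values[["v15"]],
                 comp[["s"]] / comp[["g"]], tolerance = 1e-7)
  }
})

test_that("raising the overflow lower bound shifts the optimum linearly", {
  for (b in c(0.02, 0.05, 0.1)) {
    net_b <- net_ext
    net_b$reactions$lower_bound[net_b$reactions$enzyme == "OVERFLOW"] <- b
    sol <- solve_fba(fba_problem(net_b, anchor))
    expect_equal(sol$objective, 0.97 - 3 * (b - 0.01), tolerance = 1e-8)
  }
})

test_that("alternate optima enumeration finds the routing vertices", {
  prob <- fba_problem(net_ext, anchor)
  face <- enumerate_alternate_optima(prob)
  expect_gte(length(face$vertices), 2L)
  # vertices differ in the CCR2 vs CCoAOMT route split
  v10s <- vapply(face$vertices, function(v) v[["v10"]], numeric(1))
  expect_gt(max(v10s) - min(v10s), 0.5)
  # but all share the composition-fixed transports
  for (fx in c("v6", "v15", "v19")) {
    vals <- vapply(face$vertices, function(v) v[[fx]], numeric(1))
    expect_lt(max(vals) - min(vals), 1e-7)
  }
  # every vertex attains the optimal objective
  objs <- vapply(face$vertices, function(v) sum(v[c("v6", "v15", "v19")]),
                 numeric(1))
  expect_true(all(abs(objs - face$objective) <= 1e-8))
})

test_that("enumeration agrees with exhaustive basis enumeration", {
  for (comp in list(anchor, monomer_composition(1, 0, 0))) {
    prob <- fba_problem(net_ext, comp)
    sol <- solve_fba(prob)
    face <- enumerate_alternate_optima(prob, sol)
    m <- lignoflux:::.fba_matrices(prob)
    orc <- oracle_face_vertices(m$Aeq, m$beq, m$obj, sol$objective, m$lb, m$ub)
    expect_equal(vertex_keys(face$vertices), vertex_keys(orc))
  }
  # the all-H face still splits the residual overflow-driven flux at
  # caffeoyl-CoA between the CCR2 and CCoAOMT routes: exactly two vertices
  face1 <- enumerate_alternate_optima(fba_problem(net_ext,
                                                  monomer_composition(1, 0, 0)))
  expect_equal(length(face1$vertices), 2L)
})

test_that("reference selection policies behave as documented", {
  prob <- fba_problem(net_ext, anchor)
  face <- enumerate_alternate_optima(prob)
  mn <- select_reference_distribution(face, "min-norm")
  mr <- select_reference_distribution(face, "main-route")
  expect_error(select_reference_distribution(face, "random"))
  # main-route empties the CCR2-COMT shunt
  expect_equal(unname(mr$values[["v10"]]), 0, tolerance = 1e-8)
  expect_equal(unname(mr$values[["v12"]]), 0, tolerance = 1e-8)
  # min-norm splits the parallel routes evenly (v10 and v11 symmetric in norm)
  expect_equal(mn$values[["v10"]], mn$values[["v11"]], tolerance = 1e-7)
  # both lie on the optimal face and agree on the transports
  for (fx in c("v6", "v15", "v19"))
    expect_equal(mn$values[[fx]], mr$values[[fx]], tolerance = 1e-7)
  # min-norm is the norm minimizer among all face vertices
  expect_true(all(sqrt(sum(mn$values^2)) <=
                  vapply(face$vertices, function(v) sqrt(sum(v^2)), numeric(1)) + 1e-9))
  # degenerate single-vertex face: selection returns that vertex
  face1 <- enumerate_alternate_optima(fba_problem(net_ext,
                                                  monomer_composition(1, 0, 0)))
  if (face1$dim == 0L) {
    expect_equal(select_reference_distribution(face1, "min-norm")$values,
                 face1$vertices[[1]])
  }
})

test_that("infeasible problems return a certificate, not an exception", {
  # a composition demanding S flux on a network whose S route is closed
  net_cut <- net_ext
  net_cut$reactions$upper_bound[net_cut$reactions$id == "v16"] <- 0
  net_cut$reactions$upper_bound[net_cut$reactions$id == "v20"] <- 0
  res <- solve_fba(fba_problem(net_cut, monomer_composition(0.1, 0.4, 0.5)))
  expect_s3_class(res, "fba_infeasibility")
  expect_false(res$feasible)
  expect_gt(length(res$certificate), 0L)
})
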