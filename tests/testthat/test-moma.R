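net_ext <- build_reference_network("extended")
net_un <- build_reference_network("unextended")
anchor <- monomer_composition(7, 85.5, 7.4)
wt <- wt_reference("main-route", anchor)

test_that("knockdown constraints cap every reaction of the enzyme", {
  kc <- knockdown_constraints(net_ext, knockdown_spec("COMT", 0.2), wt)
  expect_setequal(kc$reaction, c("v12", "v17", "v21"))
  expect_equal(kc$bound, unname(0.2 * wt$values[kc$reaction]))
  kc1 <- knockdown_constraints(net_ext, knockdown_spec("PAL", 1), wt)
  expect_equal(kc1$reaction, "v1")
  expect_equal(kc1$bound, unname(wt$values["v1"]))
  kc2 <- knockdown_constraints(net_ext, knockdown_spec("C4H", 0.45), wt)
  expect_equal(kc2$bound, unname(0.45 * wt$values["v2"]))
  expect_error(knockdown_spec("TRANSPORT", 0.5), "knocked down")
  expect_error(knockdown_spec("C4H", 1.2), "\\[0, 1\\]")
})

test_that("a no-op knockdown with wild-type composition recovers the reference", {
  res <- solve_moma(net_ext, knockdown_spec("C4H", 1), anchor, wt)
  expect_true(res$feasible)
  expect_equal(res$distance, 0, tolerance = 1e-6)
  expect_equal(res$fluxes$values, wt$values, tolerance = 1e-5)
})

test_that("un-extended network is infeasible under the C4H knockdown, extended is not", {
  spec <- knockdown_spec("C4H", 0.45)
  fe_un <- check_feasibility(net_un, spec, anchor, wt)
  expect_false(fe_un$feasible)
  expect_true("cinnamic_acid" %in% fe_un$certificate)
  fe_ext <- check_feasibility(net_ext, spec, anchor, wt)
  expect_true(fe_ext$feasible)
  # and without the knockdown the un-extended network is fine, relative to
  # its own wild-type reference (the extended reference's v2 = 0.99 would
  # itself clash with the overflow-free balance v2 = 1)
  wt_un <- select_reference_distribution(
    enumerate_alternate_optima(fba_problem(net_un, anchor)), "main-route")
  fe_ok <- check_feasibility(net_un, knockdown_spec("C4H", 1), anchor, wt_un)
  expect_true(fe_ok$feasible)
  # solve_moma propagates infeasibility as a result, not an exception
  res <- solve_moma(net_un, spec, anchor, wt)
  expect_false(res$feasible)
  expect_true("cinnamic_acid" %in% res$certificate)
})

test_that("CCoAOMT knockdown reroutes flux through the CCR2-COMT shunt", {
  sshift <- monomer_composition(0.05, 0.80, 0.15)  # S-shifted mutant
  res <- solve_moma(net_ext, knockdown_spec("CCoAOMT", 0.2), sshift, wt)
  expect_true(res$feasible)
  expect_gt(res$fluxes$values[["v10"]], wt$values[["v10"]] + 0.01)
  # knockdown cap respected
  expect_lte(res$fluxes$values[["v11"]], 0.2 * wt$values[["v11"]] + 1e-8)
})

test_that("PAL lines stay solvable: the knockdown replaces the normalization", {
  res <- solve_moma(net_ext, knockdown_spec("PAL", 0.4), anchor, wt)
  expect_true(res$feasible)
  expect_equal(res$fluxes$values[["v1"]], 0.4, tolerance = 1e-6)
})

test_that("MOMA distance matches the Dykstra projection oracle", {
  set.seed(202)
  enzymes <- c("C4H", "HCT", "C3H", "CCoAOMT", "COMT", "CCR1", "CAD")
  for (i in 1:12) {
    enz <- sample(enzymes, 1)
    alpha <- stats::runif(1, 0.15, 0.95)
    comp <- random_composition()
    res <- solve_moma(net_ext, knockdown_spec(enz, alpha), comp, wt)
    expect_true(res$feasible)
    orc <- oracle_moma_dykstra(net_ext, enz, alpha, comp, wt)
    expect_equal(res$distance, orc$distance, tolerance = 1e-6)
  }
})

test_that("F5H knockdowns clash with the mandatory 5H efflux", {
  # v24 (5H incorporation) is bounded below by 0.01, which forces
  # v20 >= 0.01; any F5H knockdown caps v20 below that, so the constraint
  # set is empty -- consistent with the study excluding the F5H line
  fe <- check_feasibility(net_ext, knockdown_spec("F5H", 0.5), anchor, wt)
  expect_false(fe$feasible)
})

test_that("the minimal adjustment shrinks as the knockdown relaxes", {
  comp <- monomer_composition(0.05, 0.8, 0.15)
  dist_prev <- Inf
  for (alpha in c(0.1, 0.3, 0.5, 0.8, 1)) {
    res <- solve_moma(net_ext, knockdown_spec("COMT", alpha), comp, wt)
    expect_true(res$feasible)
    expect_lte(res$distance, dist_prev + 1e-9)
    dist_prev <- res$distance
  }
})

test_that("a strong knockdown leaves at least one cap active", {
  res <- solve_moma(net_ext, knockdown_spec("C4H", 0.3), anchor, wt)
  kc <- knockdown_constraints(net_ext, knockdown_spec("C4H", 0.3), wt)
  slack <- kc$bound - res$fluxes$values[kc$reaction]
  expect_lt(min(slack), 1e-7)
})
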