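qc_work <- isotype_profile(c(0.6, 0.3, 0.1, 0, 0, 0, 0, 0))
qh_work <- isotype_profile(c(0.8, 0.1, 0.1, 0, 0, 0, 0, 0))
cons_work <- otip_constraints(list(liver = qh_work), caps = 0.2)

test_that("unconstrained dot optimum is the argmax indicator", {
  res <- otip_optimize(qc_work)
  expect_equal(res$status, "optimal")
  expect_equal(pvec((res$optimal_profile)), c(1, rep(0, 7)))
  expect_identical(res$damage, 0.6)
  set.seed(31)
  for (i in 1:50) {
    q <- rand_simplex()
    res <- otip_optimize(q)
    i_star <- match(argmax_isotype(q), isotype_ids()$name)
    expect_equal(pvec((res$optimal_profile))[i_star], 1)
    expect_identical(res$damage, max(unclass(q)))
  }
})

test_that("worked constrained instance: vertex mixture 1/7, 6/7", {
  res <- otip_optimize(qc_work, cons_work)
  expect_equal(res$status, "optimal")
  expect_equal(pvec((res$optimal_profile)),
               c(1 / 7, 6 / 7, rep(0, 6)), tolerance = 1e-9)
  expect_equal(res$damage, 12 / 35, tolerance = 1e-9)
  expect_equal(res$active_constraints, "liver")
})

test_that("zero cap on a fully expressed tissue is infeasible", {
  cons <- otip_constraints(list(all = uniform_profile()), caps = 0)
  res <- otip_optimize(qc_work, cons)
  expect_equal(res$status, "infeasible")
  expect_null(res$optimal_profile)
  expect_match(res$message, "cap")
})

test_that("penalized net-benefit variant", {
  # v = 1 against the worked healthy profile: net (-0.2, 0.2, 0, ...)
  pen <- otip_constraints(list(liver = qh_work), caps = 1)
  res <- otip_sum_optimize(qc_work, pen)
  expect_equal(pvec((res$optimal_profile)),
               c(0, 1, rep(0, 6)))
  expect_equal(res$damage, 0.3)
  expect_equal(res$objective, 0.2, tolerance = 1e-12)

  # all v = 0 reduces to the unconstrained dot optimum
  set.seed(37)
  for (i in 1:25) {
    q <- rand_simplex()
    pen0 <- otip_constraints(list(a = rand_simplex(), b = rand_simplex()),
                             caps = c(0, 0))
    expect_equal(pvec(otip_sum_optimize(q, pen0)$optimal_profile),
                 pvec(otip_optimize(q)$optimal_profile))
  }

  # symmetric net vector: tie resolves to first canonical isotype
  qsym <- isotype_profile(c(0.5, 0.5, 0, 0, 0, 0, 0, 0))
  res <- otip_sum_optimize(qsym)
  expect_equal(argmax_isotype(res$optimal_profile), "betaI")
})

test_that("KL optimization: unconstrained optimum is the tumor profile", {
  set.seed(41)
  for (i in 1:50) {
    q <- rand_simplex()
    res <- otip_kl_optimize(q)
    expect_equal(pvec(res$optimal_profile), pvec(q))
    expect_lte(abs(res$objective), 1e-8)
  }
})

test_that("KL optimization: constrained cases", {
  # cap on betaI forces (0.2, 0.8) for the 50/50 tumor
  q <- isotype_profile(c(0.5, 0.5, 0, 0, 0, 0, 0, 0))
  cons <- otip_constraints(list(t = pure_profile(1)), caps = 0.2)
  res <- otip_kl_optimize(q, cons)
  expect_equal(res$status, "optimal")
  expect_equal(pvec((res$optimal_profile)),
               c(0.2, 0.8, rep(0, 6)), tolerance = 1e-6)
  expect_true("t" %in% res$active_constraints)
  # objective agrees with a 1-d grid oracle
  gr <- brute_force_oracle(q, cons, grid_step = 0.001, model = "kl")
  expect_gte(res$objective, gr$objective - 1e-5)

  # constraints already satisfied by q itself: optimum stays at q
  slack <- otip_constraints(list(t = pure_profile(1)), caps = 0.9)
  res2 <- otip_kl_optimize(q, slack)
  expect_equal(pvec(res2$optimal_profile), pvec(q),
               tolerance = 1e-9)
  expect_lte(abs(res2$objective), 1e-8)

  # infeasible caps
  res3 <- otip_kl_optimize(q, otip_constraints(list(t = uniform_profile()),
                                               caps = 0))
  expect_equal(res3$status, "infeasible")
})

test_that("KL solutions satisfy the caps on random instances", {
  set.seed(43)
  for (i in 1:30) {
    inst <- rand_instance(k = sample(3:4, 1), m = 2)
    res <- otip_kl_optimize(inst$qc, inst$constraints)
    if (res$status == "optimal") {
      A <- t(vapply(inst$constraints$profiles, unclass, numeric(8)))
      expect_true(all(A %*% unclass(res$optimal_profile) <=
                        inst$constraints$caps + 1e-7))
      expect_lte(res$objective, 1e-10)
    } else {
      # the solver's infeasibility claim is confirmed by the grid oracle
      # (the grid is a subset of the continuous feasible set)
      gr <- brute_force_oracle(inst$qc, inst$constraints,
                               grid_step = 0.01, model = "kl")
      expect_equal(gr$status, "infeasible")
    }
  }
})

test_that("drug evaluation against constraints", {
  res <- otip_optimize(qc_work, cons_work)
  ev <- evaluate_drug(res$optimal_profile, qc_work, cons_work,
                      reference = res)
  expect_true(ev$feasible)
  expect_equal(ev$fraction_of_optimum, 1, tolerance = 1e-9)

  ev2 <- evaluate_drug(pure_profile(1), qc_work, cons_work, reference = res)
  expect_false(ev2$feasible)
  expect_equal(ev2$violations$tissue, "liver")
  expect_equal(ev2$violations$damage, 0.8)
  expect_equal(ev2$violations$cap, 0.2)

  vac <- otip_constraints(list(liver = qh_work), caps = 1)
  set.seed(47)
  for (i in 1:10)
    expect_true(evaluate_drug(rand_simplex(), qc_work, vac)$feasible)
})

test_that("monotonicity: relaxing caps never hurts, adding constraints never helps", {
  set.seed(53)
  n_ok <- 0
  for (i in 1:40) {
    inst <- rand_instance(k = sample(3:4, 1), m = 2)
    res <- otip_optimize(inst$qc, inst$constraints)
    if (res$status != "optimal") next
    n_ok <- n_ok + 1
    lam <- runif(1, 1, 2)
    scaled <- otip_constraints(inst$constraints$profiles,
                               caps = lam * inst$constraints$caps,
                               tissues = inst$constraints$tissues)
    res_s <- otip_optimize(inst$qc, scaled)
    expect_equal(res_s$status, "optimal")
    expect_gte(res_s$damage, res$damage - 1e-9)

    extra <- otip_constraints(
      c(inst$constraints$profiles, list(extra = rand_simplex(dims = inst$dims))),
      caps = c(inst$constraints$caps, runif(1, 0.1, 0.5)))
    res_e <- otip_optimize(inst$qc, extra)
    if (res_e$status == "optimal")
      expect_lte(res_e$damage, res$damage + 1e-9)
  }
  expect_gte(n_ok, 20)  # the generator must mostly produce feasible cases
})

test_that("result JSON serializes and validates", {
  res <- otip_optimize(qc_work, cons_work)
  ctx <- cancer_context("demo", route = "iv", gender = "male")
  txt <- result_to_json(res, ctx)
  expect_true(validate_result_json(txt))
  obj <- jsonlite::fromJSON(txt)
  expect_equal(obj$status, "optimal")
  expect_equal(obj$context$cancer, "demo")
  expect_equal(sum(unlist(obj$optimal_profile$values)), 1, tolerance = 1e-12)
  # infeasible results serialize with a null profile
  inf <- otip_optimize(qc_work, otip_constraints(list(t = uniform_profile()),
                                                 caps = 0))
  expect_true(validate_result_json(result_to_json(inf)))
  expect_error(validate_result_json('{"status": "weird"}'), "missing key")
})
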