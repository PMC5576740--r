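test_that("initialization is seeded, reproducible, and strictly positive", {
  g <- random_lp_graph(12, 0.3, seed = 1)
  cfg <- fit_config(k = 3, seed = 5)
  a <- init_factors(g, config = cfg)
  b <- init_factors(g, config = cfg)
  expect_identical(a$U, b$U)
  expect_identical(a$Vstar, b$Vstar)
  d <- init_factors(g, config = fit_config(k = 3, seed = 6))
  expect_false(identical(a$U, d$U))

  inst <- generate_sbm(planted_spec(n = 10, m = 10, seed = 2))
  for (s in 1:20) {
    mod <- init_factors(inst$graph, inst$attributes,
                        fit_config(k = 3, seed = s))
    expect_true(all(mod$U > 0) && all(mod$V > 0) && all(mod$UB > 0) &&
                  all(mod$VB > 0) && all(mod$Vstar > 0))
  }
  expect_equal(a$q, colSums(a$U))
  expect_error(nmf_lp(g, config = fit_config(k = 12)), "smaller than")
})

test_that("exact factorizations are fixed points when penalties are off", {
  cfg <- fit_config(k = 3, lambda = 0, mu = 0, delta = 1e-15)
  mod <- random_model(n = 7, k = 3, m = 5, seed = 3)
  A <- mod$U %*% mod$V
  B <- mod$UB %*% mod$VB
  expect_equal(update_u(mod, A, cfg)$U, mod$U, tolerance = 1e-10)
  expect_equal(update_v(mod, A, cfg)$V, mod$V, tolerance = 1e-10)
  expect_equal(update_ub(mod, B, cfg)$UB, mod$UB, tolerance = 1e-10)
  expect_equal(update_vb(mod, B, cfg)$VB, mod$VB, tolerance = 1e-10)
})

test_that("each update step does not increase its own sub-objective", {
  for (seed in 1:10) {
    mod <- random_model(n = 6, k = 2, m = 4, seed = seed)
    A <- random_symmetric(6, seed + 100)
    B <- withr::with_seed(seed + 200, matrix(runif(24), 4, 6))
    cfg <- fit_config(k = 2, lambda = 1, mu = 1)

    expect_lte(f_of_u(update_u(mod, A, cfg), A, 1), f_of_u(mod, A, 1))
    expect_lte(f_of_ub(update_ub(mod, B, cfg), B, 1), f_of_ub(mod, B, 1))
    expect_lte(g_of_v(update_v(mod, A, cfg), A, 1), g_of_v(mod, A, 1))
    expect_lte(g_of_vb(update_vb(mod, B, cfg), B, 1), g_of_vb(mod, B, 1))
  }
})

test_that("zero penalties reduce the updates to classical multiplicative NMF", {
  cfg <- fit_config(k = 3, lambda = 0, mu = 0, delta = 1e-12)
  mod <- random_model(n = 8, k = 3, seed = 4)
  A <- random_symmetric(8, 40)
  # classical rules computed independently, term by term
  lee_seung_u <- mod$U * (A %*% t(mod$V)) /
    (mod$U %*% mod$V %*% t(mod$V) + 1e-12)
  lee_seung_v <- mod$V * (t(mod$U) %*% A) /
    (t(mod$U) %*% mod$U %*% mod$V + 1e-12)
  expect_equal(update_u(mod, A, cfg)$U, lee_seung_u, tolerance = 1e-12)
  expect_equal(update_v(mod, A, cfg)$V, lee_seung_v, tolerance = 1e-12)
})

test_that("consensus update is the exact minimizer of its objective", {
  mod <- random_model(n = 6, k = 3, m = 4, seed = 6)
  # equal inputs: consensus equals both
  mod_eq <- mod
  mod_eq$VB <- (mod_eq$q / mod_eq$qb) * mod_eq$V
  up <- update_vstar(mod_eq)
  expect_equal(up$Vstar, mod_eq$q * mod_eq$V, tolerance = 1e-12)

  # zero inputs: consensus zero
  mod0 <- mod
  mod0$V[] <- 0
  mod0$VB[] <- 0
  expect_true(all(update_vstar(mod0)$Vstar == 0))

  # any perturbation of the closed form increases H
  vstar <- update_vstar(mod)$Vstar
  h0 <- h_of_vstar(mod, vstar)
  for (seed in 1:10) {
    pert <- withr::with_seed(seed, vstar + matrix(rnorm(length(vstar),
                                                        sd = 0.05),
                                                  nrow(vstar)))
    expect_gt(h_of_vstar(mod, pert), h0)
  }

  # topology-only mode: consensus is the normalized embedding QV
  modt <- random_model(n = 6, k = 3, seed = 7)
  expect_equal(update_vstar(modt)$Vstar, modt$q * modt$V)
})

test_that("the objective matches a brute-force elementwise oracle", {
  mod <- random_model(n = 5, k = 2, m = 3, seed = 8)
  A <- random_symmetric(5, 80)
  B <- withr::with_seed(81, matrix(runif(15), 3, 5))
  cfg <- fit_config(k = 2, lambda = 0.7, mu = 1.3)
  expect_equal(objective_j(mod, A, B, cfg),
               brute_objective(mod, A, B, 0.7, 1.3), tolerance = 1e-10)

  # closed forms
  mod0 <- mod
  mod0$U[] <- 0; mod0$V[] <- 0; mod0$UB[] <- 0; mod0$VB[] <- 0
  mod0$Vstar[] <- 0; mod0$q <- colSums(mod0$U); mod0$qb <- colSums(mod0$UB)
  expect_equal(objective_j(mod0, A, B, cfg), sum(A^2) + sum(B^2))

  exact <- random_model(n = 5, k = 2, m = 3, seed = 9)
  exact$Vstar <- exact$q * exact$V
  exact$VB <- (exact$q / exact$qb) * exact$V
  expect_equal(objective_j(exact, exact$U %*% exact$V,
                           exact$UB %*% exact$VB, cfg),
               0, tolerance = 1e-20)
  expect_error(objective_j(mod, A[1:4, 1:4], B, cfg), "inconsistent")
})

test_that("factors stay non-negative across full fits", {
  inst <- generate_sbm(planted_spec(n = 15, m = 8, seed = 10))
  for (s in 1:5) {
    fit <- nmf_lp(inst$graph, inst$attributes,
                  fit_config(k = 3, seed = s, max_iter = 40))
    expect_true(all(fit$U >= 0) && all(fit$V >= 0) && all(fit$UB >= 0) &&
                  all(fit$VB >= 0) && all(fit$Vstar >= 0))
  }
})

test_that("the joint objective is non-increasing along the fit", {
  inst <- generate_sbm(planted_spec(n = 20, m = 10, seed = 11))
  for (s in 1:5) {
    fit <- nmf_lp(inst$graph, inst$attributes,
                  fit_config(k = 4, seed = s, max_iter = 120))
    h <- fit$history$objective
    expect_true(all(diff(h) <= 1e-9 * utils::head(h, -1)))
  }
})

test_that("a trivially satisfied error threshold stops after one iteration", {
  g <- random_lp_graph(10, 0.4, seed = 12)
  fit <- nmf_lp(g, config = fit_config(k = 2, eps = sum(g$A^2), seed = 1))
  expect_equal(nrow(fit$history), 1)
  expect_equal(fit$stopped_by, "eps")
})

test_that("hitting the iteration cap flags non-convergence, no error", {
  g <- random_lp_graph(12, 0.4, seed = 13)
  fit <- nmf_lp(g, config = fit_config(k = 3, max_iter = 3, eps = 1e-12,
                                       rel_tol = 1e-15, seed = 1))
  expect_false(fit$converged)
  expect_equal(fit$stopped_by, "max_iter")
  expect_equal(nrow(fit$history), 3)
})

test_that("stationary points satisfy the sub-objective KKT conditions", {
  # small instance run to (near) convergence with active penalties
  inst <- generate_sbm(planted_spec(n = 8, m = 4, p_in = 0.8, p_out = 0.2,
                                    seed = 14))
  fit <- nmf_lp(inst$graph, inst$attributes,
                fit_config(k = 2, seed = 2, max_iter = 8000, eps = 1e-300,
                           rel_tol = 1e-14))
  A <- inst$graph$A
  mod <- fit
  scale_ref <- max(1, abs(g_of_v(mod, A, 1)))
  gv <- numeric_gradient(function(V) {
    m2 <- mod; m2$V <- V
    g_of_v(m2, A, 1)
  }, mod$V)
  active <- mod$V > 1e-6
  expect_lt(max(abs(gv[active])) / scale_ref, 1e-3)
})

test_that("the denominator guard has negligible effect on well-posed fits", {
  g <- random_lp_graph(15, 0.4, seed = 15)
  f1 <- nmf_lp(g, config = fit_config(k = 3, seed = 3, delta = 1e-12,
                                      max_iter = 200))
  f2 <- nmf_lp(g, config = fit_config(k = 3, seed = 3, delta = 2e-12,
                                      max_iter = 200))
  j1 <- utils::tail(f1$history$objective, 1)
  j2 <- utils::tail(f2$history$objective, 1)
  expect_lt(abs(j1 - j2) / j1, 1e-6)
})

test_that("fits are reproducible from the configuration seed", {
  inst <- generate_sbm(planted_spec(n = 12, m = 6, seed = 16))
  cfg <- fit_config(k = 3, seed = 9, max_iter = 30)
  f1 <- nmf_lp(inst$graph, inst$attributes, cfg)
  f2 <- nmf_lp(inst$graph, inst$attributes, cfg)
  expect_identical(f1$Vstar, f2$Vstar)
  expect_identical(f1$history, f2$history)
})

test_that("an all-zero attribute row dies out when uncoupled", {
  # without the consensus coupling the update numerator for a dead
  # attribute row is zero, so the row must vanish; with coupling on, the
  # consensus term deliberately keeps it alive
  inst <- generate_sbm(planted_spec(n = 10, m = 5, seed = 17))
  B <- unclass(inst$attributes)
  B[3, ] <- 0
  attrs <- lp_attributes(B, normalize = FALSE)
  fit <- nmf_lp(inst$graph, attrs, fit_config(k = 2, mu = 0, seed = 1,
                                              max_iter = 400))
  expect_lt(max(fit$UB[3, ]), 1e-6)
})
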