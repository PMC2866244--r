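test_that("pi0 update equals the posterior root-absence fraction", {
  set.seed(51)
  tr <- rand_tree(4)
  m <- random_model(tr)
  sim <- simulate_dataset(tr, m, 150, seed = 1)
  st <- e_step(sim$dataset, m)
  upd <- m_step(st, m, em_config(), free = "pi0")
  pg <- st$per_gene[[1L]]
  expect_equal(upd$pi0, pg$node_post[1L, 1L] / sum(pg$node_post[1L, ]),
               tolerance = 1e-12)
  # and it maximizes the auxiliary function over a fine grid
  grid <- seq(1e-4, 1 - 1e-4, length.out = 2000L)
  qs <- vapply(grid, function(p) {
    mm <- upd; mm$pi0 <- p
    oracle_aux_Q(st, mm)
  }, 0)
  expect_equal(upd$pi0, grid[which.max(qs)], tolerance = 1e-3)
})

test_that("coordinate updates match a grid-search oracle of Q", {
  set.seed(52)
  tr <- rand_tree(4)
  m <- random_model(tr, G = 2)
  sim <- simulate_dataset(tr, m, c(120, 80), seed = 2)
  cfg <- em_config(k_eta = 2L, k_theta = 2L)
  cats <- discretize_rate_model(m$nu, m$lambda_eta, m$lambda_theta, 2L, 2L)
  st <- e_step(sim$dataset, m, cats = cats)

  check_coord <- function(free, field, idx, grid, argmax_tol = NULL) {
    upd <- m_step(st, m, cfg, free = free)
    qs <- vapply(grid, function(v) {
      mm <- upd; mm[[field]][idx] <- v
      oracle_aux_Q(st, mm)
    }, 0)
    q_impl <- oracle_aux_Q(st, upd)
    # the chosen value is at least as good as the best grid point
    expect_gte(q_impl, max(qs) - 1e-6)
    if (!is.null(argmax_tol))
      expect_lt(abs(upd[[field]][idx] - grid[which.max(qs)]), argmax_tol)
  }
  check_coord("xi", "xi", 2L, seq(1e-4, 1 - 1e-4, length.out = 10000L),
              argmax_tol = 0.01)
  check_coord("phi", "phi", 3L, seq(1e-4, 1 - 1e-4, length.out = 10000L),
              argmax_tol = 0.01)
  check_coord("eta", "eta", 1L, exp(seq(log(1e-3), log(50),
                                        length.out = 10000L)))
  check_coord("theta", "theta", 2L, exp(seq(log(1e-3), log(50),
                                            length.out = 10000L)))
})

test_that("a branch with no posterior gain mass gets xi = 0", {
  tr <- tree4()
  # root surely absent and loss impossible: an unseen gain would have
  # to reach the (all-absent) leaves, so no 0->1 mass anywhere
  m <- gl_model(tr, xi = 0.4, phi = 0, eta = 1, theta = 0, pi0 = 1,
                nu = 0, lambda_eta = 1, lambda_theta = 1)
  ds <- gl_patterns("0000", matrix(10L, 1L, 1L),
                    species = tr$labels[tr$leaves + 1L])
  st <- e_step(ds, m, k_eta = 1L, k_theta = 1L)
  upd <- m_step(st, m, em_config(k_eta = 1L, k_theta = 1L),
                free = c("xi", "phi"))
  expect_equal(upd$xi, rep(0, tr$n_branch))
})

test_that("EM is monotone and beats the generating parameters", {
  set.seed(53)
  tr <- rand_tree(4)
  m <- random_model(tr)
  sim <- simulate_dataset(tr, m, 500, seed = 3)
  cfg <- em_config(max_iter = 25L, k_eta = 2L, k_theta = 2L)
  init <- init_params(sim$dataset, tr, cfg)
  fit <- run_em(sim$dataset, init, cfg)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8 * abs(fit$loglik_trace[-1])))
  # the fit can only improve on the truth's likelihood on this data
  cats <- discretize_rate_model(m$nu, m$lambda_eta, m$lambda_theta, 2L, 2L)
  ll_truth <- data_loglikelihood(sim$dataset, m, cats = cats)
  expect_gte(fit$loglik, ll_truth)
  # determinism
  fit2 <- run_em(sim$dataset, init, cfg)
  expect_identical(fit$loglik_trace, fit2$loglik_trace)
  expect_identical(fit$params, fit2$params)
})

test_that("a pre-satisfied tolerance returns the init unchanged", {
  set.seed(54)
  tr <- rand_tree(3)
  m <- random_model(tr)
  sim <- simulate_dataset(tr, m, 50, seed = 4)
  fit <- run_em(sim$dataset, m, em_config(rel_tol = Inf))
  expect_identical(fit$params, m)
  expect_equal(fit$n_iter, 0L)
  expect_true(fit$converged)
  expect_equal(fit$loglik, data_loglikelihood(sim$dataset, m),
               tolerance = 1e-10)
})

test_that("histories track every free parameter from iteration 0", {
  set.seed(55)
  tr <- rand_tree(3)
  m <- random_model(tr)
  sim <- simulate_dataset(tr, m, 100, seed = 5)
  cfg <- em_config(max_iter = 4L, rel_tol = 1e-14)
  init <- init_params(sim$dataset, tr, cfg)
  fit <- run_em(sim$dataset, init, cfg)
  expect_setequal(
    names(fit$histories),
    c("pi0", "nu", "lambda_eta", "lambda_theta",
      paste0("xi_", 1:4), paste0("phi_", 1:4), "eta_gene1", "theta_gene1"))
  expect_true(all(lengths(fit$histories) == fit$n_iter + 1L))
  expect_equal(fit$histories$pi0[1L], init$pi0)
})
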