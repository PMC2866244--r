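test_that("simulated trees have the right shape and are ultrametric", {
  tr <- simulate_tree(2, 3.5, seed = 1)
  expect_equal(tr$n_nodes, 3L)
  expect_equal(tr$brlen[-1L], c(3.5, 3.5))
  tr <- simulate_tree(19, 1, seed = 2)
  expect_equal(tr$n_nodes, 37L)
  expect_equal(tr$n_branch, 36L)
  depths <- gainloss:::.node_depths(tr)
  expect_equal(unname(depths[tr$leaves + 1L]), rep(1, 19L),
               tolerance = 1e-9)
  # determinism
  tr2 <- simulate_tree(19, 1, seed = 2)
  expect_identical(tr, tr2)
  expect_error(simulate_tree(1), "num_leaves")
})

test_that("random models respect ranges, domains and seeds", {
  tr <- simulate_tree(5, 1, seed = 3)
  # collapsed ranges fix the values exactly
  m <- random_model(tr, G = 2,
                    ranges = list(xi = c(0.3, 0.3), phi = c(0.1, 0.1),
                                  eta = c(2, 2), theta = c(0.5, 0.5),
                                  pi0 = c(0.7, 0.7), nu = c(0.2, 0.2),
                                  lambda_eta = c(1, 1),
                                  lambda_theta = c(1, 1)),
                    seed = 4)
  expect_equal(m$xi, rep(0.3, tr$n_branch))
  expect_equal(m$eta, c(2, 2))
  expect_equal(m$pi0, 0.7)
  set.seed(99)
  for (rep in 1:20) {
    mm <- random_model(tr, G = 3)
    expect_s3_class(mm, "gl_model")
    expect_true(all(mm$xi >= 0 & mm$xi <= 1))
    expect_true(all(mm$theta >= 0))
  }
  expect_identical(random_model(tr, seed = 7), random_model(tr, seed = 7))
  expect_error(random_model(tr, ranges = list(xi = c(-0.5, 0.5))), "domain")
  expect_error(random_model(tr, ranges = list(bogus = c(0, 1))), "unknown")
})

test_that("degenerate simulations behave as dictated by the model", {
  tr <- simulate_tree(4, 1, seed = 5)
  # nothing can ever be gained
  m <- gl_model(tr, xi = 0.5, phi = 0.1, eta = 1, theta = 1, pi0 = 1,
                nu = 1, lambda_eta = 1, lambda_theta = 1)
  sim <- simulate_dataset(tr, m, 200, seed = 6)
  expect_equal(sim$dataset$P, 1L)
  expect_equal(sim$dataset$patterns, "0000")
  expect_equal(sum(sim$truth$gains) + sum(sim$truth$losses), 0)
  expect_equal(sum(sim$truth$occupancy), 0)
  # full masking
  m2 <- random_model(tr, seed = 7)
  sim2 <- simulate_dataset(tr, m2, 50, missing_rate = 1, seed = 8)
  expect_equal(sim2$dataset$patterns, "****")
  # determinism
  a <- simulate_dataset(tr, m2, 100, missing_rate = 0.2, seed = 9)
  b <- simulate_dataset(tr, m2, 100, missing_rate = 0.2, seed = 9)
  expect_identical(a$dataset$patterns, b$dataset$patterns)
  expect_identical(a$truth$per_gene[[1L]]$states, b$truth$per_gene[[1L]]$states)
})

test_that("recorded events are consistent with recorded states", {
  set.seed(81)
  tr <- rand_tree(5)
  m <- random_model(tr)
  sim <- simulate_dataset(tr, m, 300, seed = 10)
  pg <- sim$truth$per_gene[[1L]]
  for (t in seq_len(tr$n_branch)) {
    par <- pg$states[, tr$parent[t + 1L] + 1L]
    ch <- pg$states[, t + 1L]
    expect_equal(pg$gains[t], sum(par == 0L & ch == 1L))
    expect_equal(pg$losses[t], sum(par == 1L & ch == 0L))
    expect_equal(pg$retentions[t], sum(par == 1L & ch == 1L))
  }
  expect_equal(pg$occupancy, colSums(pg$states))
  # a zero site absent at the root can never gain the character
  absent <- pg$zero & pg$states[, 1L] == 0L
  if (any(absent))
    expect_true(all(pg$states[absent, ] == 0L))
})

test_that("empirical frequencies match their analytic values (3 SE)", {
  tr <- simulate_tree(6, 1, seed = 11)
  m <- gl_model(tr, xi = runif(tr$n_branch, 0.2, 0.8),
                phi = runif(tr$n_branch, 0.05, 0.3),
                eta = 1, theta = 1, pi0 = 0.7, nu = 0.3,
                lambda_eta = 1, lambda_theta = 1)
  n <- 1e5
  sim <- simulate_dataset(tr, m, n, seed = 12)
  pg <- sim$truth$per_gene[[1L]]
  # root absence and zero-site fraction
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(pg$states[, 1L] == 0L) - m$pi0), 3 * se(m$pi0))
  expect_lt(abs(mean(pg$zero) - m$nu), 3 * se(m$nu))
  # per-branch gain/loss event counts against their exact expectations;
  # the 3-SE rule is applied family-wise: with K simultaneous branch
  # comparisons the per-test cutoff is Bonferroni-adjusted so that the
  # whole family has the error rate of a single 3-sigma test
  cats <- discretize_rate_model(m$nu, m$lambda_eta, m$lambda_theta, 4L, 4L)
  an <- analytic_branch_event_probs(m, cats)
  K <- 2L * tr$n_branch
  z_crit <- qnorm(1 - (2 * pnorm(-3)) / (2 * K))
  for (t in seq_len(tr$n_branch)) {
    se_g <- sqrt(n * an$gain[t] * (1 - an$gain[t]))
    se_l <- sqrt(n * an$loss[t] * (1 - an$loss[t]))
    expect_lt(abs(pg$gains[t] - n * an$gain[t]), z_crit * se_g + 1)
    expect_lt(abs(pg$losses[t] - n * an$loss[t]), z_crit * se_l + 1)
  }
  # at the root's children the compound per-branch gain probability is
  # also the conditional gain frequency among parent-absent sites
  cmp <- compound_branch_probs(m)
  for (t in which(tr$parent[-1L] == 0L)) {
    par <- pg$states[, 1L]
    ch <- pg$states[, t + 1L]
    p_emp <- mean(ch[par == 0L] == 1L)
    expect_lt(abs(p_emp - cmp$gain[t]),
              3 * sqrt(cmp$gain[t] * (1 - cmp$gain[t]) / sum(par == 0L)))
  }
})
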