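test_that("transition_matrix matches the model algebra", {
  # zero time, no instantaneous loss: identity
  expect_equal(unname(transition_matrix(0.7, 0, 1, 1, 0)), diag(2))
  # xi = 0 makes gain impossible
  Tm <- transition_matrix(0, 0.3, 2, 1, 1.5)
  expect_equal(unname(Tm[1L, ]), c(1, 0))
  # hand evaluation: gain = 0.5 * (1 - 0.5), retention = 0.9 * 0.5
  Tm <- transition_matrix(0.5, 0.1, 1, 1, log(2))
  expect_equal(unname(Tm), matrix(c(0.75, 0.55, 0.25, 0.45), 2L),
               tolerance = 1e-12)
  # rate coefficients scale eta and theta inside the exponent
  Tm2 <- transition_matrix(0.5, 0.1, 0.5, 2, log(2), r_eta = 2, r_theta = 0.5)
  expect_equal(unname(Tm2), matrix(c(0.75, 0.55, 0.25, 0.45), 2L),
               tolerance = 1e-12)
  expect_error(transition_matrix(1.2, 0, 1, 1, 1), "xi")
  expect_error(transition_matrix(0.5, 0, -1, 1, 1), "eta")
  expect_error(transition_matrix(0.5, 0, 1, 1, -0.1), "delta")
})

test_that("transition rows are stochastic and monotone in the drivers", {
  set.seed(11)
  for (rep in 1:50) {
    xi <- runif(1); phi <- runif(1); eta <- rexp(1); theta <- rexp(1)
    d <- rexp(1); re <- rexp(1); rt <- rexp(1)
    Tm <- transition_matrix(xi, phi, eta, theta, d, re, rt)
    expect_equal(rowSums(Tm), c("0" = 1, "1" = 1), tolerance = 1e-12)
    expect_true(all(Tm >= 0 & Tm <= 1))
    # gain entry nondecreasing in xi, eta, r_eta, delta
    for (bump in list(c(1, 0, 0, 0), c(0, 1, 0, 0))) {
      Tup <- transition_matrix(min(1, xi + 0.1 * bump[1L]), phi,
                               eta + bump[2L], theta, d + bump[3L],
                               re + bump[4L], rt)
      expect_gte(Tup[1L, 2L], Tm[1L, 2L])
    }
    Tup <- transition_matrix(xi, phi, eta, theta, d + 0.5, re, rt)
    expect_gte(Tup[1L, 2L], Tm[1L, 2L])
    expect_lte(Tup[2L, 2L], Tm[2L, 2L])
    # retention nonincreasing in phi, theta, r_theta
    Tup <- transition_matrix(xi, min(1, phi + 0.1), eta, theta + 1, d,
                             re, rt + 1)
    expect_lte(Tup[2L, 2L], Tm[2L, 2L])
  }
})

test_that("root_distribution reads off pi0", {
  expect_equal(unname(root_distribution(1)), c(1, 0))
  expect_equal(unname(root_distribution(0)), c(0, 1))
  expect_equal(unname(root_distribution(0.7)), c(0.7, 0.3))
})

test_that("rate discretization is a proper mixture with the stated means", {
  # single category collapses to the overall mean
  cats <- discretize_rate_model(0, 1, 1, 1L, 1L)
  expect_equal(nrow(cats), 1L)
  expect_equal(cats$weight, 1)
  expect_equal(cats$r_eta, 1)
  expect_equal(cats$r_theta, 1)
  # pure zero atom
  cats <- discretize_rate_model(1, 1, 1, 4L, 3L)
  expect_true(all(cats$r_eta == 0))
  expect_equal(sum(cats$weight), 1)
  # quartile bin means of Exp(1) against a quadrature oracle
  cats <- discretize_rate_model(0, 1, 1, 4L, 1L)
  expect_equal(nrow(cats), 4L)
  expect_equal(cats$weight, rep(0.25, 4L))
  q <- c(0, qexp(c(0.25, 0.5, 0.75)), Inf)
  oracle <- vapply(1:4, function(i)
    integrate(function(x) x * dexp(x), q[i], q[i + 1L],
              rel.tol = 1e-12)$value / 0.25, 0)
  expect_equal(sort(cats$r_eta), sort(oracle), tolerance = 1e-8)
  expect_equal(sum(cats$weight * cats$r_eta), 1, tolerance = 1e-12)
  expect_error(discretize_rate_model(0.5, -1, 1), "lambda")
})

test_that("mixture normalization holds across shapes and zero fractions", {
  set.seed(5)
  for (rep in 1:25) {
    nu <- runif(1); le <- runif(1, 0.05, 5); lt <- runif(1, 0.05, 5)
    ke <- sample(1:6, 1); kt <- sample(1:6, 1)
    cats <- discretize_rate_model(nu, le, lt, ke, kt)
    expect_equal(sum(cats$weight), 1, tolerance = 1e-12)
    expect_equal(sum(cats$weight * cats$r_theta), 1, tolerance = 1e-10)
    expect_equal(sum(cats$weight * cats$r_eta), 1 - nu, tolerance = 1e-10)
  }
})

test_that("a model for (S, G) reports 2G + 4S free parameters", {
  tr <- tree4()
  m <- gl_model(tr, 0.5, 0.1, rep(1, 3), rep(1, 3), 0.6, 0.1, 1, 1)
  expect_equal(n_free_params(m), 2L * 3L + 4L * 4L)
  expect_equal(n_free_params(19, G = 1), 2L + 4L * 19L)
  expect_error(gl_model(tr, c(0.5, 0.5), 0.1, 1, 1, 0.5, 0, 1, 1),
               "per branch")
})
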