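test_that("an all-star pattern has likelihood exactly 1", {
  set.seed(31)
  tr <- rand_tree(4)
  m <- random_model(tr)
  expect_equal(pattern_likelihood(m, "****"), 1, tolerance = 1e-12)
})

test_that("two-leaf likelihood matches the closed form", {
  set.seed(32)
  tr <- tree2(0.8, 1.7)
  m <- random_model(tr)
  Tm <- lapply(1:2, function(t)
    transition_matrix(m$xi[t], m$phi[t], m$eta[1L], m$theta[1L],
                      tr$brlen[t + 1L]))
  closed <- m$pi0 * Tm[[1L]][1L, 1L] * Tm[[2L]][1L, 1L] +
    (1 - m$pi0) * Tm[[1L]][2L, 1L] * Tm[[2L]][2L, 1L]
  expect_equal(pattern_likelihood(m, "00"), closed, tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration on random instances", {
  set.seed(33)
  for (rep in 1:40) {
    S <- sample(2:5, 1)
    tr <- rand_tree(S)
    m <- random_model(tr)
    pat <- rand_pattern(S)
    cats <- discretize_rate_model(m$nu, m$lambda_eta, m$lambda_theta, 2L, 2L)
    orc <- oracle_enumerate(m, pat, cats = cats)
    for (c_ in seq_len(nrow(cats))) {
      pl <- pattern_likelihood(m, pat, r_eta = cats$r_eta[c_],
                               r_theta = cats$r_theta[c_])
      expect_equal(pl, orc$lik_cat[c_], tolerance = 1e-12)
    }
  }
})

test_that("data_loglikelihood assembles the weighted mixture", {
  set.seed(34)
  tr <- rand_tree(3)
  m <- random_model(tr, G = 2)
  pats <- c("001", "1*0")
  counts <- rbind(c(3L, 1L), c(0L, 5L))
  ds <- gl_patterns(pats, counts, species = tr$labels[tr$leaves + 1L])
  cats <- discretize_rate_model(m$nu, m$lambda_eta, m$lambda_theta, 3L, 2L)
  # brute-force assembly from enumeration per gene and pattern
  expected <- 0
  for (g in 1:2) for (p in 1:2) {
    if (counts[g, p] == 0L) next
    orc <- oracle_enumerate(m, pats[p], g = g, cats = cats)
    expected <- expected + counts[g, p] * log(orc$mix)
  }
  expect_equal(data_loglikelihood(ds, m, cats = cats), expected,
               tolerance = 1e-10)
  # degenerate mixture = plain pruning log-likelihood
  m1 <- m; m1$nu <- 0
  cats1 <- discretize_rate_model(0, 1, 1, 1L, 1L)
  plain <- 0
  for (g in 1:2) for (p in 1:2)
    plain <- plain + counts[g, p] * log(pattern_likelihood(m1, pats[p], g = g))
  expect_equal(data_loglikelihood(ds, m1, cats = cats1), plain,
               tolerance = 1e-10)
  # all counts zero: empty sum
  ds0 <- gl_patterns(pats, matrix(0L, 2L, 2L))
  expect_equal(data_loglikelihood(ds0, m), 0)
})

test_that("impossible patterns yield -Inf with a diagnostic", {
  tr <- tree2()
  m <- gl_model(tr, xi = 0, phi = 0, eta = 1, theta = 1, pi0 = 1,
                nu = 0, lambda_eta = 1, lambda_theta = 1)
  ds <- gl_patterns("11", matrix(1L, 1L, 1L))
  expect_warning(ll <- data_loglikelihood(ds, m), "11")
  expect_identical(ll, -Inf)
})

test_that("masking a leaf marginalizes: lik(*) = lik(0) + lik(1)", {
  set.seed(35)
  for (rep in 1:10) {
    S <- sample(3:6, 1)
    tr <- rand_tree(S)
    m <- random_model(tr)
    pat <- strsplit(rand_pattern(S, star_prob = 0), "")[[1L]]
    j <- sample(S, 1)
    p0 <- pat; p0[j] <- "0"
    p1 <- pat; p1[j] <- "1"
    ps <- pat; ps[j] <- "*"
    expect_equal(pattern_likelihood(m, paste(ps, collapse = "")),
                 pattern_likelihood(m, paste(p0, collapse = "")) +
                 pattern_likelihood(m, paste(p1, collapse = "")),
                 tolerance = 1e-12)
  }
})
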