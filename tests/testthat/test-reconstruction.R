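test_that("occupancy and events match enumeration on a toy instance", {
  set.seed(71)
  tr <- tree4()
  m <- random_model(tr, G = 2)
  pats <- c("0110", "1*01", "0000")
  counts <- rbind(c(2L, 1L, 3L), c(1L, 0L, 2L))
  ds <- gl_patterns(pats, counts, species = tr$labels[tr$leaves + 1L])
  cats <- discretize_rate_model(m$nu, m$lambda_eta, m$lambda_theta, 2L, 2L)
  st <- e_step(ds, m, cats = cats)
  occ <- node_occupancy(st)
  ev <- branch_events(st)
  for (g in 1:2) {
    occ_exp <- numeric(tr$n_nodes)
    gains_exp <- losses_exp <- ret_exp <- numeric(tr$n_branch)
    for (p in seq_along(pats)) {
      if (counts[g, p] == 0L) next
      orc <- oracle_enumerate(m, pats[p], g = g, cats = cats)
      occ_exp <- occ_exp + counts[g, p] * orc$node_marg[, 2L]
      gains_exp <- gains_exp + counts[g, p] * orc$branch_joint[2L, -1L]
      losses_exp <- losses_exp + counts[g, p] * orc$branch_joint[3L, -1L]
      ret_exp <- ret_exp + counts[g, p] * orc$branch_joint[4L, -1L]
    }
    og <- occ[occ$gene == paste0("gene", g), ]
    eg <- ev[ev$gene == paste0("gene", g), ]
    expect_equal(og$occupancy, occ_exp, tolerance = 1e-10)
    expect_equal(og$fraction, occ_exp / sum(counts[g, ]), tolerance = 1e-10)
    expect_equal(eg$gains, gains_exp, tolerance = 1e-10)
    expect_equal(eg$losses, losses_exp, tolerance = 1e-10)
    expect_equal(eg$retentions, ret_exp, tolerance = 1e-10)
  }
})

test_that("observed leaves have exact occupancy; impossible characters give 0", {
  set.seed(72)
  tr <- tree4()
  m <- random_model(tr)
  sim <- simulate_dataset(tr, m, 80, seed = 1)     # fully observed leaves
  st <- e_step(sim$dataset, m)
  occ <- node_occupancy(st)
  ones <- colSums(sim$dataset$counts[1L, ] * (sim$dataset$states == 1L))
  for (j in seq_along(tr$leaves)) {
    row <- occ[occ$node == tr$leaves[j], ]
    expect_equal(row$occupancy, unname(ones[j]), tolerance = 1e-9)
  }
  # pi0 = 1 and xi = 0: the character can never exist
  m0 <- gl_model(tr, xi = 0, phi = 0.2, eta = 1, theta = 1, pi0 = 1,
                 nu = 0, lambda_eta = 1, lambda_theta = 1)
  ds <- gl_patterns("0000", matrix(12L, 1L, 1L),
                    species = tr$labels[tr$leaves + 1L])
  st0 <- e_step(ds, m0)
  expect_equal(node_occupancy(st0)$occupancy, rep(0, tr$n_nodes))
  ev0 <- branch_events(st0)
  expect_equal(ev0$gains, rep(0, tr$n_branch))
  # phi = 0 and theta = 0: losses are impossible
  ml <- gl_model(tr, xi = 0.5, phi = 0, eta = 1, theta = 0, pi0 = 0.5,
                 nu = 0, lambda_eta = 1, lambda_theta = 1)
  stl <- e_step(sim$dataset, ml)
  expect_equal(branch_events(stl)$losses, rep(0, tr$n_branch),
               tolerance = 1e-12)
})

test_that("flow conservation: child occupancy = gains + retentions", {
  set.seed(73)
  for (rep in 1:5) {
    tr <- rand_tree(sample(3:6, 1))
    m <- random_model(tr, G = 2)
    sim <- simulate_dataset(tr, m, c(120, 60), missing_rate = 0.15, seed = rep)
    st <- e_step(sim$dataset, m)
    rec <- reconstruct(st)
    for (g in unique(rec$occupancy$gene)) {
      og <- rec$occupancy[rec$occupancy$gene == g, ]
      eg <- rec$events[rec$events$gene == g, ]
      for (t in seq_len(tr$n_branch)) {
        expect_equal(og$occupancy[og$node == t],
                     eg$gains[eg$branch == t] + eg$retentions[eg$branch == t],
                     tolerance = 1e-9)
      }
      ng <- sum(sim$dataset$counts[which(unique(rec$occupancy$gene) == g), ])
      expect_true(all(og$occupancy >= -1e-9 & og$occupancy <= ng + 1e-9))
    }
    # the overall table obeys the same identity
    oo <- rec$overall$occupancy
    oe <- rec$overall$events
    for (t in seq_len(tr$n_branch))
      expect_equal(oo$occupancy[oo$node == t],
                   oe$gains[oe$branch == t] + oe$retentions[oe$branch == t],
                   tolerance = 1e-9)
  }
})

test_that("the overall report sums the per-gene tables", {
  set.seed(74)
  tr <- rand_tree(4)
  m <- random_model(tr, G = 3)
  sim <- simulate_dataset(tr, m, c(50, 70, 30), seed = 9)
  rec <- reconstruct(e_step(sim$dataset, m))
  expect_equal(rec$overall$events$gains,
               as.numeric(tapply(rec$events$gains, rec$events$branch, sum)),
               tolerance = 1e-12)
  expect_equal(rec$overall$occupancy$occupancy,
               as.numeric(tapply(rec$occupancy$occupancy,
                                 rec$occupancy$node, sum)),
               tolerance = 1e-12)
  # G = 1: overall equals the single gene's table
  sim1 <- simulate_dataset(tr, random_model(tr), 40, seed = 10)
  rec1 <- reconstruct(e_step(sim1$dataset, random_model(tr)))
  expect_equal(rec1$overall$events$gains, rec1$events$gains)
})
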