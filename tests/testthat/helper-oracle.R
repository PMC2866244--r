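# Independent oracles: exhaustive enumeration over all node-state
# assignments, and the EM auxiliary function assembled directly from
# transition_matrix() entries.  These deliberately avoid the pruning /
# C++ code paths they are used to check.

# all 2^n_nodes state assignments consistent with an observed pattern
# (integer vector over tree leaves, NA = missing); rows = assignments
oracle_assignments <- function(tree, pattern) {
  n <- tree$n_nodes
  asg <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(asg) <- NULL
  keep <- rep(TRUE, nrow(asg))
  for (j in seq_along(tree$leaves)) {
    s <- pattern[j]
    if (!is.na(s)) keep <- keep & asg[, tree$leaves[j] + 1L] == s
  }
  asg[keep, , drop = FALSE]
}

# joint posterior quantities for one pattern under the category mixture
oracle_enumerate <- function(model, pattern, g = 1L, cats = NULL,
                             k_eta = 4L, k_theta = 4L) {
  tree <- model$tree
  if (is.character(pattern))
    pattern <- gainloss:::.pattern_states(pattern, tree$S)[1L, ]
  if (is.null(cats))
    cats <- discretize_rate_model(model$nu, model$lambda_eta,
                                  model$lambda_theta, k_eta, k_theta)
  asg <- oracle_assignments(tree, pattern)
  ncat <- nrow(cats)
  n <- tree$n_nodes
  pi_ <- root_distribution(model$pi0)
  lik_cat <- numeric(ncat)
  # P(assignment, cat) up to the category prior weight
  pa <- matrix(0, nrow(asg), ncat)
  for (c_ in seq_len(ncat)) {
    w <- pi_[asg[, 1L] + 1L]
    for (id in seq_len(n) - 1L) {
      if (id == 0L) next
      Tm <- transition_matrix(model$xi[id], model$phi[id],
                              model$eta[g], model$theta[g],
                              tree$brlen[id + 1L],
                              cats$r_eta[c_], cats$r_theta[c_])
      par <- asg[, tree$parent[id + 1L] + 1L]
      w <- w * Tm[cbind(par + 1L, asg[, id + 1L] + 1L)]
    }
    pa[, c_] <- cats$weight[c_] * w
    lik_cat[c_] <- sum(w)
  }
  mix <- sum(cats$weight * lik_cat)
  post <- pa / mix                       # posterior over (assignment, cat)
  node_marg <- matrix(0, n, 2L)
  for (id in seq_len(n) - 1L) {
    p1 <- sum(post[asg[, id + 1L] == 1L, ])
    node_marg[id + 1L, ] <- c(1 - p1, p1)
  }
  branch_joint <- matrix(0, 4L, n)       # rows: 00, 01, 10, 11
  for (id in seq_len(n) - 1L) {
    if (id == 0L) next
    par <- asg[, tree$parent[id + 1L] + 1L]
    ch <- asg[, id + 1L]
    for (i in 0:1) for (j in 0:1)
      branch_joint[2L * i + j + 1L, id + 1L] <-
        sum(post[par == i & ch == j, ])
  }
  list(lik_cat = lik_cat, mix = mix, node_marg = node_marg,
       branch_joint = branch_joint,
       cat_post = cats$weight * lik_cat / mix)
}

# EM auxiliary function Q(model') given E-step stats at the old model;
# category grid and weights are those of the E-step.
oracle_aux_Q <- function(stats, model) {
  cats <- stats$cats
  tree <- model$tree
  pi_ <- root_distribution(model$pi0)
  total <- 0
  for (g in seq_along(stats$per_gene)) {
    pg <- stats$per_gene[[g]]
    rp <- pg$node_post[1L, ]
    total <- total + sum(rp[rp > 0] * log(pi_[rp > 0]))
    for (c_ in seq_len(nrow(cats))) {
      for (id in seq_len(tree$n_nodes) - 1L) {
        if (id == 0L) next
        Tm <- transition_matrix(model$xi[id], model$phi[id],
                                model$eta[g], model$theta[g],
                                tree$brlen[id + 1L],
                                cats$r_eta[c_], cats$r_theta[c_])
        nn <- pg$trans[, id + 1L, c_]    # order 00, 01, 10, 11
        tv <- c(Tm[1L, 1L], Tm[1L, 2L], Tm[2L, 1L], Tm[2L, 2L])
        ok <- nn > 1e-12
        total <- total + sum(nn[ok] * log(tv[ok]))
      }
    }
  }
  total
}

# small random non-ultrametric tree with S leaves (uses the package's
# Yule simulator for topology, then jitters branch lengths)
rand_tree <- function(S, jitter = TRUE) {
  tr <- simulate_tree(S, time_span = 1)
  if (jitter) {
    bl <- tr$brlen
    bl[-1L] <- bl[-1L] * stats::runif(length(bl) - 1L, 0.3, 2)
    tr <- gl_tree(tr$parent, bl, tr$labels)
  }
  tr
}

# exact per-site probabilities of a gain / loss event on every branch,
# marginalized over the rate-category mixture: propagates per-category
# state marginals down the tree and averages the joint event
# probabilities over categories.
analytic_branch_event_probs <- function(model, cats, g = 1L) {
  tree <- model$tree
  ncat <- nrow(cats)
  p1 <- matrix(0, tree$n_nodes, ncat)       # P(state 1 at node | cat)
  p1[1L, ] <- 1 - model$pi0
  gain_p <- loss_p <- numeric(tree$n_branch)
  for (id in tree$preorder) {
    if (id == 0L) next
    d <- tree$brlen[id + 1L]
    gain_c <- model$xi[id] * (1 - exp(-cats$r_eta * model$eta[g] * d))
    ret_c <- (1 - model$phi[id]) * exp(-cats$r_theta * model$theta[g] * d)
    par1 <- p1[tree$parent[id + 1L] + 1L, ]
    p1[id + 1L, ] <- par1 * ret_c + (1 - par1) * gain_c
    gain_p[id] <- sum(cats$weight * (1 - par1) * gain_c)
    loss_p[id] <- sum(cats$weight * par1 * (1 - ret_c))
  }
  list(gain = gain_p, loss = loss_p, p1 = p1)
}

rand_pattern <- function(S, star_prob = 0.2) {
  s <- sample(c("0", "1", "*"), S, replace = TRUE,
              prob = c((1 - star_prob) / 2, (1 - star_prob) / 2, star_prob))
  paste(s, collapse = "")
}

# the worked 4-species x 10-site alignment fragment: six distinct
# patterns with multiplicities 2, 2, 3, 1, 1, 1
fig1_alignment <- function() {
  w1 <- c("0", "0", "0", "0"); w2 <- c("0", "1", "0", "1")
  w3 <- c("1", "1", "0", "1"); w4 <- c("0", "0", "1", "1")
  w5 <- c("0", "*", "1", "1"); w6 <- c("0", "*", "0", "1")
  cbind(w1, w1, w2, w2, w3, w3, w3, w4, w5, w6, deparse.level = 0)
}

# deterministic 4-leaf tree matching a balanced 4-species phylogeny
tree4 <- function(brlen = c(NA, 1, 0.5, 0.7, 1.2, 0.4, 0.9)) {
  # ids: 0 root; 1 internal (children 2,3); 4 internal (children 5,6)
  parent <- c(NA, 0L, 1L, 1L, 0L, 4L, 4L)
  labels <- c("", "", "A", "B", "", "C", "D")
  gl_tree(parent, brlen, labels)
}

tree2 <- function(b1 = 1, b2 = 2) {
  gl_tree(c(NA, 0L, 0L), c(NA, b1, b2), c("", "A", "B"))
}
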