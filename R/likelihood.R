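# 0-based traversal arrays handed to the C++ kernel
.tree_arrays <- function(tree) {
  n <- tree$n_nodes
  childL <- childR <- rep(-1L, n)
  for (k in seq_len(n)) {
    ch <- tree$children[[k]]
    if (length(ch) == 2L) { childL[k] <- ch[1L]; childR[k] <- ch[2L] }
  }
  leafcol <- rep(-1L, n)
  leafcol[tree$leaves + 1L] <- seq_along(tree$leaves) - 1L
  list(postorder = rev(tree$preorder), preorder = tree$preorder,
       parent = ifelse(is.na(tree$parent), -1L, tree$parent),
       childL = childL, childR = childR, leafcol = leafcol)
}

#' Likelihood of a single pattern under one rate category
#'
#' Computes, by postorder (pruning) recursion in plain R, the
#' probability of observing `pattern` at the leaves for gene `g` and a
#' fixed rate category: the sum over all internal-state assignments of
#' the root prior times the product of branch transition probabilities,
#' with `*` leaves marginalized (conditional likelihood 1 for both
#' states).
#'
#' @param model a [gl_model()].
#' @param pattern a string of `S` characters over `{0,1,*}` in the
#'   tree's leaf order, or an integer vector (0/1/`NA`).
#' @param g gene index (default 1).
#' @param r_eta,r_theta rate coefficients of the category (default 1).
#' @return the pattern likelihood (a probability).
#' @export
pattern_likelihood <- function(model, pattern, g = 1L,
                               r_eta = 1, r_theta = 1) {
  tree <- model$tree
  if (is.character(pattern)) {
    stopifnot(nchar(pattern) == tree$S)
    pattern <- .pattern_states(pattern, tree$S)[1L, ]
  }
  stopifnot(length(pattern) == tree$S)
  leafstate <- rep(NA_integer_, tree$n_nodes)
  leafstate[tree$leaves + 1L] <- as.integer(pattern)
  Tm <- vector("list", tree$n_nodes)
  for (id in seq_len(tree$n_nodes) - 1L) {
    if (id == 0L) next
    Tm[[id + 1L]] <- transition_matrix(model$xi[id], model$phi[id],
                                       model$eta[g], model$theta[g],
                                       tree$brlen[id + 1L],
                                       r_eta, r_theta)
  }
  L <- matrix(NA_real_, tree$n_nodes, 2L)
  for (id in rev(tree$preorder)) {
    ch <- tree$children[[id + 1L]]
    if (length(ch) == 0L) {
      s <- leafstate[id + 1L]
      L[id + 1L, ] <- if (is.na(s)) c(1, 1) else if (s == 0L) c(1, 0)
                      else c(0, 1)
    } else {
      m1 <- Tm[[ch[1L] + 1L]] %*% L[ch[1L] + 1L, ]
      m2 <- Tm[[ch[2L] + 1L]] %*% L[ch[2L] + 1L, ]
      L[id + 1L, ] <- as.vector(m1 * m2)
    }
  }
  sum(root_distribution(model$pi0) * L[1L, ])
}

# Tarr (4 x n_nodes x ncat) and per-pattern log-likelihood matrix for
# one gene; shared plumbing for the loglik and E-step entry points.
.loglik_matrix <- function(dataset, model, g, cats, arrays = NULL,
                           states = NULL) {
  tree <- model$tree
  if (is.null(arrays)) arrays <- .tree_arrays(tree)
  if (is.null(states)) states <- .states_for_tree(dataset, tree)
  Tarr <- .trans_array(model, g, cats)
  .cpp_loglik_cats(states, arrays$postorder, arrays$childL, arrays$childR,
                   arrays$leafcol, as.numeric(Tarr), tree$n_nodes,
                   model$pi0, nrow(cats))
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  ifelse(is.finite(mx), mx + log(rowSums(exp(m - mx))), -Inf)
}

#' Data log-likelihood under the discretized rate mixture
#'
#' \deqn{\ell = \sum_g \sum_p c_{gp} \log \sum_k w_k\, L(\omega_p \mid g, k)}
#' where the inner sum runs over the rate categories of
#' [discretize_rate_model()] and `c_gp` are the pattern counts.
#'
#' @param dataset a [gl_patterns()].
#' @param model a [gl_model()] on a tree with matching leaf set.
#' @param k_eta,k_theta discretization bin counts (default 4).
#' @param cats optional precomputed category grid (overrides the `k`s).
#' @return the total data log-likelihood; `-Inf`, with a warning naming
#'   the offending pattern, if some observed pattern has likelihood 0
#'   under every category.
#' @export
data_loglikelihood <- function(dataset, model, k_eta = 4L, k_theta = 4L,
                               cats = NULL) {
  if (is.null(cats))
    cats <- discretize_rate_model(model$nu, model$lambda_eta,
                                  model$lambda_theta, k_eta, k_theta)
  arrays <- .tree_arrays(model$tree)
  states <- .states_for_tree(dataset, model$tree)
  total <- 0
  for (g in seq_len(dataset$G)) {
    cnt <- dataset$counts[g, ]
    if (!any(cnt > 0)) next
    ll <- .loglik_matrix(dataset, model, g, cats, arrays, states)
    logmix <- .logsumexp_rows(sweep(ll, 2L, log(cats$weight), "+"))
    bad <- which(!is.finite(logmix) & cnt > 0)
    if (length(bad)) {
      warning("pattern '", dataset$patterns[bad[1L]],
              "' has zero likelihood under every rate category")
      return(-Inf)
    }
    total <- total + sum(cnt * logmix)
  }
  total
}

#' Expectation step: posterior sufficient statistics
#'
#' Runs, per gene and rate category, the upward (inside) and downward
#' (outside) recursions over the tree, and accumulates across sites
#' (patterns weighted by their counts):
#' * `node_post[v, s]` — expected number of sites in state `s` at node
#'   `v` (posterior occupancies),
#' * `trans[2i+j, v, k]` — expected number of `i -> j` transitions on
#'   the branch into node `v` under category `k`,
#' * `cat_tot[k]` — expected number of sites in category `k`,
#' all conditioned on the data and the current parameters.
#'
#' @inheritParams data_loglikelihood
#' @return an object of class `gl_stats`: a list with `tree`, `cats`,
#'   `gene_ids`, `n_sites` (per gene), `loglik` (total), `per_gene`
#'   (one list per gene with `node_post`, `trans`, `cat_tot`,
#'   `loglik`).
#' @export
e_step <- function(dataset, model, k_eta = 4L, k_theta = 4L, cats = NULL) {
  if (is.null(cats))
    cats <- discretize_rate_model(model$nu, model$lambda_eta,
                                  model$lambda_theta, k_eta, k_theta)
  tree <- model$tree
  arrays <- .tree_arrays(tree)
  states <- .states_for_tree(dataset, tree)
  ncat <- nrow(cats)
  per_gene <- vector("list", dataset$G)
  total_ll <- 0
  for (g in seq_len(dataset$G)) {
    cnt <- dataset$counts[g, ]
    if (!any(cnt > 0)) {
      per_gene[[g]] <- list(
        node_post = matrix(0, tree$n_nodes, 2L),
        trans = array(0, c(4L, tree$n_nodes, ncat)),
        cat_tot = numeric(ncat), loglik = 0)
      next
    }
    ll <- .loglik_matrix(dataset, model, g, cats, arrays, states)
    lw <- sweep(ll, 2L, log(cats$weight), "+")
    logmix <- .logsumexp_rows(lw)
    bad <- which(!is.finite(logmix) & cnt > 0)
    if (length(bad))
      stop("pattern '", dataset$patterns[bad[1L]],
           "' has zero likelihood under every rate category")
    # W[p, k] = count_p * Pr(category k | pattern p)
    W <- cnt * exp(lw - logmix)
    W[cnt == 0, ] <- 0
    Tarr <- .trans_array(model, g, cats)
    st <- .cpp_estep_stats(states, arrays$postorder, arrays$preorder,
                           arrays$parent, arrays$childL, arrays$childR,
                           arrays$leafcol, as.numeric(Tarr), tree$n_nodes,
                           model$pi0, W)
    gl <- sum(cnt * logmix)
    per_gene[[g]] <- list(node_post = st$node_post,
                          trans = array(st$trans, c(4L, tree$n_nodes, ncat)),
                          cat_tot = as.numeric(st$cat_tot), loglik = gl)
    total_ll <- total_ll + gl
  }
  structure(
    list(tree = tree, cats = cats, gene_ids = dataset$gene_ids,
         n_sites = rowSums(dataset$counts), loglik = total_ll,
         per_gene = per_gene),
    class = "gl_stats")
}

#' @export
print.gl_stats <- function(x, ...) {
  cat("gl_stats: ", length(x$per_gene), " gene(s), ",
      sum(x$n_sites), " sites, loglik = ", format(x$loglik), "\n", sep = "")
  invisible(x)
}
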