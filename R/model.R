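#' Per-branch, per-gene transition matrix of the gain/loss model
#'
#' The model assigns to branch `t` and gene `g` the 2x2 row-stochastic
#' matrix over states (0 = absent, 1 = present)
#' \deqn{T(g,t) = \begin{pmatrix}
#'   1 - \xi_t(1 - e^{-\eta_g \Delta_t}) & \xi_t(1 - e^{-\eta_g \Delta_t}) \\
#'   1 - (1-\phi_t) e^{-\theta_g \Delta_t} & (1-\phi_t) e^{-\theta_g \Delta_t}
#' \end{pmatrix}}
#' where \eqn{\xi_t, \phi_t \in [0,1]} are the branch gain and loss
#' coefficients, \eqn{\eta_g, \theta_g \ge 0} the gene gain and loss
#' rates, and \eqn{\Delta_t} the branch length.  Per-site rate
#' heterogeneity enters by scaling \eqn{\eta_g \leftarrow r^\eta \eta_g}
#' and \eqn{\theta_g \leftarrow r^\theta \theta_g} with the category's
#' rate coefficients.
#'
#' @param xi branch gain coefficient in `[0,1]`.
#' @param phi branch loss coefficient in `[0,1]`.
#' @param eta gene gain rate (>= 0, events per unit branch length).
#' @param theta gene loss rate (>= 0).
#' @param delta branch length (>= 0).
#' @param r_eta,r_theta site rate coefficients (>= 0), defaults 1.
#' @return a 2x2 numeric matrix; rows index the parent state, columns
#'   the child state, order (0, 1).
#' @export
transition_matrix <- function(xi, phi, eta, theta, delta,
                              r_eta = 1, r_theta = 1) {
  .check_unit(xi, "xi"); .check_unit(phi, "phi")
  .check_nonneg(eta, "eta"); .check_nonneg(theta, "theta")
  .check_nonneg(delta, "delta")
  .check_nonneg(r_eta, "r_eta"); .check_nonneg(r_theta, "r_theta")
  gain <- xi * (1 - exp(-r_eta * eta * delta))
  ret  <- (1 - phi) * exp(-r_theta * theta * delta)
  matrix(c(1 - gain, 1 - ret, gain, ret), 2L, 2L,
         dimnames = list(parent = c("0", "1"), child = c("0", "1")))
}

.check_unit <- function(x, sym) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("parameter '", sym, "' must lie in [0, 1]")
  invisible(x)
}
.check_nonneg <- function(x, sym) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("parameter '", sym, "' must be finite and >= 0")
  invisible(x)
}
.check_pos <- function(x, sym) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("parameter '", sym, "' must be finite and > 0")
  invisible(x)
}

#' Root state distribution
#'
#' `pi0` is the probability that a site is absent (state 0) at the root.
#'
#' @param pi0 root absence probability in `[0,1]`; alternatively a
#'   `gl_model` whose `pi0` is used.
#' @return numeric vector `c(pi0, 1 - pi0)` over states (0, 1).
#' @export
root_distribution <- function(pi0) {
  if (inherits(pi0, "gl_model")) pi0 <- pi0$pi0
  .check_unit(pi0, "pi0")
  c("0" = pi0, "1" = 1 - pi0)
}

#' Discretize the zero-inflated gamma rate mixture
#'
#' Site rate coefficients are drawn from
#' \deqn{r^\eta \sim \nu\,\delta(r) + (1-\nu)\,\Gamma(r; \lambda_\eta),
#'   \qquad r^\theta \sim \Gamma(r; \lambda_\theta),}
#' each gamma having unit mean, independently per site.  The continuous
#' mixture is integrated over a discrete grid: each gamma is cut into
#' equal-probability bins represented by their bin-conditional means
#' (which preserves the unit mean exactly), and the zero atom of the
#' gain side becomes a block of categories with `r_eta = 0`, crossed
#' with the loss grid.  Blocks with zero prior weight (`nu = 0` or
#' `nu = 1`) are dropped.
#'
#' @param nu zero-site fraction in `[0,1]` (sites incapable of gaining
#'   the character).
#' @param lambda_eta,lambda_theta gamma shape parameters (> 0).
#' @param k_eta,k_theta number of discretization bins per gamma (>= 1).
#' @return a data.frame with one row per category: `weight`, `r_eta`,
#'   `r_theta`, `zero` (logical: gain-zero atom), `eta_bin`, `theta_bin`
#'   (bin indices; `eta_bin` is `NA` for the zero block).  Weights sum
#'   to 1, `sum(weight * r_theta) = 1` and
#'   `sum(weight * r_eta) = 1 - nu` up to discretization error.
#' @export
discretize_rate_model <- function(nu, lambda_eta, lambda_theta,
                                  k_eta = 4L, k_theta = 4L) {
  .check_unit(nu, "nu")
  .check_pos(lambda_eta, "lambda_eta"); .check_pos(lambda_theta, "lambda_theta")
  if (k_eta < 1L || k_theta < 1L) stop("category counts must be >= 1")
  m_eta <- gamma_bin_means(lambda_eta, k_eta)
  m_theta <- gamma_bin_means(lambda_theta, k_theta)
  out <- NULL
  if (nu > 0) {
    out <- data.frame(weight = nu / k_theta, r_eta = 0,
                      r_theta = m_theta, zero = TRUE,
                      eta_bin = NA_integer_,
                      theta_bin = seq_len(k_theta))
  }
  if (nu < 1) {
    grid <- expand.grid(eta_bin = seq_len(k_eta),
                        theta_bin = seq_len(k_theta))
    blk <- data.frame(weight = (1 - nu) / (k_eta * k_theta),
                      r_eta = m_eta[grid$eta_bin],
                      r_theta = m_theta[grid$theta_bin], zero = FALSE,
                      eta_bin = grid$eta_bin, theta_bin = grid$theta_bin)
    out <- rbind(out, blk)
  }
  rownames(out) <- NULL
  out
}

#' Equal-probability bin means of a unit-mean gamma
#'
#' Cuts the Gamma(shape = lambda, rate = lambda) distribution (mean 1)
#' into `k` equal-probability bins and returns the conditional mean of
#' each bin.  Uses the identity
#' `E[X 1(X <= x)] = F(x; lambda + 1, lambda)` for unit-mean gammas, so
#' the weighted bin means average to exactly 1.
#'
#' @param lambda shape (> 0).
#' @param k number of bins (>= 1).
#' @return numeric vector of `k` increasing bin means.
#' @export
gamma_bin_means <- function(lambda, k) {
  .check_pos(lambda, "lambda")
  if (k == 1L) return(1)
  q <- stats::qgamma(seq_len(k - 1L) / k, shape = lambda, rate = lambda)
  cum <- c(0, stats::pgamma(q, shape = lambda + 1, rate = lambda), 1)
  k * diff(cum)
}

#' Full model parameter set
#'
#' Bundles the `2G + 4S` free parameters of the model on a given tree:
#' per-branch gain/loss coefficients (`xi`, `phi`; `2(2S-2)` values),
#' per-gene gain/loss rates (`eta`, `theta`; `2G` values) and the four
#' globals (`pi0`, `nu`, `lambda_eta`, `lambda_theta`).
#'
#' @param tree a [gl_tree()].
#' @param xi,phi numeric vectors of length `2S - 2` (branch `t` at
#'   position `t`), each in `[0,1]`.
#' @param eta,theta numeric vectors of length `G`, >= 0.
#' @param pi0 root absence probability.
#' @param nu zero-site fraction.
#' @param lambda_eta,lambda_theta gamma shapes (> 0).
#' @param gene_ids optional character vector of gene names (default
#'   `gene1, ...`).
#' @return an object of class `gl_model`.
#' @export
gl_model <- function(tree, xi, phi, eta, theta, pi0, nu,
                     lambda_eta, lambda_theta, gene_ids = NULL) {
  stopifnot(inherits(tree, "gl_tree"))
  nb <- tree$n_branch
  if (length(xi) == 1L) xi <- rep(xi, nb)
  if (length(phi) == 1L) phi <- rep(phi, nb)
  if (length(xi) != nb || length(phi) != nb)
    stop("xi and phi must have one entry per branch (", nb, ")")
  if (length(eta) != length(theta))
    stop("eta and theta must have one entry per gene")
  .check_unit(xi, "xi"); .check_unit(phi, "phi")
  .check_nonneg(eta, "eta"); .check_nonneg(theta, "theta")
  .check_unit(pi0, "pi0"); .check_unit(nu, "nu")
  .check_pos(lambda_eta, "lambda_eta"); .check_pos(lambda_theta, "lambda_theta")
  G <- length(eta)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(G))
  if (length(gene_ids) != G) stop("gene_ids must have length G")
  structure(
    list(tree = tree, xi = xi, phi = phi, eta = eta, theta = theta,
         pi0 = pi0, nu = nu, lambda_eta = lambda_eta,
         lambda_theta = lambda_theta, gene_ids = as.character(gene_ids)),
    class = "gl_model")
}

#' Number of free parameters of a model
#'
#' The full model has `2G + 4S` free parameters: 4 globals,
#' `2(2S - 2)` branch coefficients and `2G` gene rates.  The
#' homogeneous (supergene) phase sets `G = 1`, i.e. `2 + 4S`.
#'
#' @param model a `gl_model`, or the number of leaves `S` if `G` given.
#' @param G number of genes (only when `model` is a leaf count).
#' @return integer parameter count.
#' @export
n_free_params <- function(model, G = NULL) {
  if (inherits(model, "gl_model")) {
    S <- model$tree$S
    G <- length(model$eta)
  } else {
    S <- model
    if (is.null(G)) stop("supply G when giving a leaf count")
  }
  as.integer(2L * G + 4L * S)
}

#' @export
print.gl_model <- function(x, ...) {
  cat("gl_model: S = ", x$tree$S, ", G = ", length(x$eta),
      " (", n_free_params(x), " free parameters)\n", sep = "")
  cat(sprintf("  pi0 = %.4g  nu = %.4g  lambda_eta = %.4g  lambda_theta = %.4g\n",
              x$pi0, x$nu, x$lambda_eta, x$lambda_theta))
  cat(sprintf("  xi  in [%.3g, %.3g]  phi in [%.3g, %.3g]\n",
              min(x$xi), max(x$xi), min(x$phi), max(x$phi)))
  cat(sprintf("  eta in [%.3g, %.3g]  theta in [%.3g, %.3g]\n",
              min(x$eta), max(x$eta), min(x$theta), max(x$theta)))
  invisible(x)
}

# flat 4 x n_nodes x ncat array of transition entries (T00,T01,T10,T11)
# for gene g; column 1 (root) unused.
.trans_array <- function(model, g, cats) {
  tree <- model$tree
  nb <- tree$n_branch
  ncat <- nrow(cats)
  delta <- tree$brlen[-1L]          # branch t at position t
  out <- array(0, dim = c(4L, tree$n_nodes, ncat))
  for (c_ in seq_len(ncat)) {
    gain <- model$xi * (1 - exp(-cats$r_eta[c_] * model$eta[g] * delta))
    ret  <- (1 - model$phi) * exp(-cats$r_theta[c_] * model$theta[g] * delta)
    out[1L, -1L, c_] <- 1 - gain
    out[2L, -1L, c_] <- gain
    out[3L, -1L, c_] <- 1 - ret
    out[4L, -1L, c_] <- ret
  }
  out
}
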