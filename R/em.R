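#' EM configuration
#'
#' @param max_iter maximum number of EM iterations (M-steps, >= 1).
#' @param rel_tol relative log-likelihood convergence tolerance: stop
#'   when `|ll_i - ll_{i-1}| < rel_tol * (|ll_{i-1}| + 1e-12)`.  An
#'   infinite tolerance returns the initial parameters with their
#'   log-likelihood (no-op fit).
#' @param k_eta,k_theta discretization bin counts of the rate mixture.
#' @param opt_tol tolerance of the one-dimensional coordinate
#'   maximizations in the M-step.
#' @param init optional initialization: a [gl_model()] or a named list
#'   overriding the defaults of [init_params()].
#' @param seed optional RNG seed recorded in the config (the EM itself
#'   is deterministic).
#' @param rate_bounds,shape_bounds search bounds for the gene rates
#'   (`eta`, `theta`) and gamma shapes (`lambda_*`).
#' @return a list of class `gl_config`.
#' @export
em_config <- function(max_iter = 1000L, rel_tol = 1e-9,
                      k_eta = 4L, k_theta = 4L, opt_tol = 1e-8,
                      init = NULL, seed = NULL,
                      rate_bounds = c(1e-6, 1e3),
                      shape_bounds = c(1e-2, 1e2)) {
  stopifnot(max_iter >= 1L, rel_tol > 0, opt_tol > 0,
            k_eta >= 1L, k_theta >= 1L)
  structure(list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 k_eta = as.integer(k_eta), k_theta = as.integer(k_theta),
                 opt_tol = opt_tol, init = init, seed = seed,
                 rate_bounds = rate_bounds, shape_bounds = shape_bounds),
            class = "gl_config")
}

.all_free <- c("pi0", "nu", "lambda_eta", "lambda_theta",
               "xi", "phi", "eta", "theta")

#' Default initial parameters
#'
#' Neutral interior starting point: `xi = 0.5`, `phi = 0.1`,
#' `eta = theta = 1`, `nu = 0.1`, `lambda_eta = lambda_theta = 1`, and
#' `pi0` set to the observed fraction of absences among the non-missing
#' leaf entries of the data.
#'
#' @param dataset a [gl_patterns()].
#' @param tree a [gl_tree()].
#' @param config a [em_config()]; its `init` entry (a `gl_model` or a
#'   named list of overrides) takes precedence.
#' @return a [gl_model()] with `G = dataset$G` genes.
#' @export
init_params <- function(dataset, tree, config = em_config()) {
  if (inherits(config$init, "gl_model")) return(config$init)
  tot <- colSums(dataset$counts)
  n0 <- sum(vapply(seq_len(dataset$P), function(p)
    tot[p] * sum(dataset$states[p, ] == 0L, na.rm = TRUE), 0))
  n1 <- sum(vapply(seq_len(dataset$P), function(p)
    tot[p] * sum(dataset$states[p, ] == 1L, na.rm = TRUE), 0))
  defaults <- list(xi = 0.5, phi = 0.1, eta = 1, theta = 1,
                   pi0 = if (n0 + n1 > 0) n0 / (n0 + n1) else 0.5,
                   nu = 0.1, lambda_eta = 1, lambda_theta = 1)
  if (is.list(config$init))
    defaults[names(config$init)] <- config$init
  G <- max(1L, dataset$G)
  eta <- rep_len(defaults$eta, G)
  theta <- rep_len(defaults$theta, G)
  gl_model(tree, defaults$xi, defaults$phi, eta, theta,
           defaults$pi0, defaults$nu, defaults$lambda_eta,
           defaults$lambda_theta,
           gene_ids = if (dataset$G) dataset$gene_ids else "gene1")
}

# ---- expected complete-data log-likelihood pieces -------------------

# gain-side terms: n00*log(1 - gain) + n01*log(gain), gain = xi*a
.q_gain <- function(n00, n01, gain) {
  i0 <- n00 > 0; i1 <- n01 > 1e-12
  t1 <- if (any(i0)) sum(n00[i0] * log1p(-gain[i0])) else 0
  t2 <- if (any(i1)) sum(n01[i1] * log(gain[i1])) else 0
  t1 + t2
}

# loss-side terms: n11*log(ret) + n10*log(1 - ret), ret = (1-phi)*b
.q_loss <- function(n10, n11, ret) {
  i1 <- n11 > 1e-12; i0 <- n10 > 1e-12
  t1 <- if (any(i1)) sum(n11[i1] * log(ret[i1])) else 0
  t2 <- if (any(i0)) sum(n10[i0] * log1p(-ret[i0])) else 0
  t1 + t2
}

# bounded scalar maximization with incumbent fallback: never decreases Q
.coord_max <- function(f, lower, upper, incumbent, tol, log_scale = FALSE) {
  inc <- min(max(incumbent, lower), upper)
  f_inc <- f(inc)
  opt <- tryCatch({
    if (log_scale)
      exp(stats::optimize(function(x) f(exp(x)),
                          c(log(lower), log(upper)),
                          maximum = TRUE, tol = tol)$maximum)
    else
      stats::optimize(f, c(lower, upper), maximum = TRUE, tol = tol)$maximum
  }, error = function(e) {
    warning("coordinate optimizer failed (", conditionMessage(e),
            "); keeping incumbent value")
    inc
  })
  f_opt <- f(opt)
  if (is.finite(f_opt) && (f_opt >= f_inc || !is.finite(f_inc))) opt else inc
}

#' Maximization step: parameter-wise coordinate ascent
#'
#' Maximizes the expected complete-data log-likelihood (the EM auxiliary
#' function assembled from the [e_step()] statistics) one parameter at a
#' time by bounded one-dimensional maximization, in the fixed sweep
#' order: globals (`pi0`, `nu`, `lambda_eta`, `lambda_theta`), then per
#' branch `xi_t`, `phi_t` in index order, then per gene `eta_g`,
#' `theta_g`.  `pi0` and `nu` have closed forms (posterior root-absence
#' and zero-category fractions).  Each coordinate update keeps the
#' incumbent value whenever the optimizer cannot improve on it, so the
#' auxiliary function never decreases.
#'
#' @param stats a `gl_stats` from [e_step()] computed at `params`.
#' @param params the current [gl_model()].
#' @param config a [em_config()].
#' @param free character vector of parameter groups to update, a subset
#'   of `c("pi0","nu","lambda_eta","lambda_theta","xi","phi","eta","theta")`.
#' @return the updated [gl_model()].
#' @export
m_step <- function(stats, params, config = em_config(),
                   free = .all_free) {
  free <- match.arg(free, .all_free, several.ok = TRUE)
  tree <- params$tree
  nb <- tree$n_branch
  cats <- stats$cats
  ncat <- nrow(cats)
  G <- length(stats$per_gene)
  delta <- tree$brlen[-1L]
  tol <- config$opt_tol
  rb <- config$rate_bounds; sb <- config$shape_bounds

  trans <- lapply(stats$per_gene, function(x) x$trans)     # 4 x n_nodes x ncat
  n_tot <- sum(stats$n_sites)

  if ("pi0" %in% free && n_tot > 0) {
    root0 <- sum(vapply(stats$per_gene, function(x) x$node_post[1L, 1L], 0))
    root1 <- sum(vapply(stats$per_gene, function(x) x$node_post[1L, 2L], 0))
    if (root0 + root1 > 0) params$pi0 <- min(max(root0 / (root0 + root1), 0), 1)
  }
  if ("nu" %in% free && n_tot > 0 && any(cats$zero) && !all(cats$zero)) {
    zmass <- sum(vapply(stats$per_gene,
                        function(x) sum(x$cat_tot[cats$zero]), 0))
    tmass <- sum(vapply(stats$per_gene, function(x) sum(x$cat_tot), 0))
    if (tmass > 0) params$nu <- min(max(zmass / tmass, 0), 1)
  }

  # Q restricted to the gain side as a function of the eta-grid rates;
  # used for lambda_eta (r recomputed from the shape) and below for eta.
  q_gain_all <- function(r_eta_by_cat, eta_by_gene, xi) {
    tot <- 0
    for (g in seq_len(G)) {
      a <- 1 - exp(-outer(delta, r_eta_by_cat) * eta_by_gene[g])
      gain <- xi * a                      # nb x ncat, xi recycled by column
      n00 <- trans[[g]][1L, -1L, , drop = FALSE]
      n01 <- trans[[g]][2L, -1L, , drop = FALSE]
      tot <- tot + .q_gain(as.numeric(n00), as.numeric(n01),
                           as.numeric(gain))
    }
    tot
  }
  q_loss_all <- function(r_theta_by_cat, theta_by_gene, phi) {
    tot <- 0
    for (g in seq_len(G)) {
      b <- exp(-outer(delta, r_theta_by_cat) * theta_by_gene[g])
      ret <- (1 - phi) * b
      n10 <- trans[[g]][3L, -1L, , drop = FALSE]
      n11 <- trans[[g]][4L, -1L, , drop = FALSE]
      tot <- tot + .q_loss(as.numeric(n10), as.numeric(n11),
                           as.numeric(ret))
    }
    tot
  }

  if ("lambda_eta" %in% free && config$k_eta > 1L && !all(cats$zero)) {
    gb <- which(!cats$zero)
    f <- function(lam) {
      m <- gamma_bin_means(lam, config$k_eta)
      r <- cats$r_eta
      r[gb] <- m[cats$eta_bin[gb]]
      q_gain_all(r, params$eta, params$xi)
    }
    params$lambda_eta <- .coord_max(f, sb[1L], sb[2L], params$lambda_eta,
                                    tol, log_scale = TRUE)
  }
  if ("lambda_theta" %in% free && config$k_theta > 1L) {
    f <- function(lam) {
      m <- gamma_bin_means(lam, config$k_theta)
      q_loss_all(m[cats$theta_bin], params$theta, params$phi)
    }
    params$lambda_theta <- .coord_max(f, sb[1L], sb[2L], params$lambda_theta,
                                      tol, log_scale = TRUE)
  }

  if (any(c("xi", "phi") %in% free)) {
    for (t in seq_len(nb)) {
      # per-category gain/loss building blocks on branch t, per gene
      if ("xi" %in% free) {
        n00 <- unlist(lapply(trans, function(x) x[1L, t + 1L, ]))
        n01 <- unlist(lapply(trans, function(x) x[2L, t + 1L, ]))
        a <- unlist(lapply(seq_len(G), function(g)
          1 - exp(-cats$r_eta * params$eta[g] * delta[t])))
        if (sum(n01) <= 1e-12) {
          params$xi[t] <- 0
        } else {
          f <- function(x) .q_gain(n00, n01, x * a)
          params$xi[t] <- .coord_max(f, 0, 1, params$xi[t], tol)
        }
      }
      if ("phi" %in% free) {
        n10 <- unlist(lapply(trans, function(x) x[3L, t + 1L, ]))
        n11 <- unlist(lapply(trans, function(x) x[4L, t + 1L, ]))
        b <- unlist(lapply(seq_len(G), function(g)
          exp(-cats$r_theta * params$theta[g] * delta[t])))
        if (sum(n10) <= 1e-12) {
          params$phi[t] <- 0
        } else {
          f <- function(x) .q_loss(n10, n11, (1 - x) * b)
          params$phi[t] <- .coord_max(f, 0, 1, params$phi[t], tol)
        }
      }
    }
  }

  if ("eta" %in% free) {
    for (g in seq_len(G)) {
      n00 <- trans[[g]][1L, -1L, , drop = FALSE]
      n01 <- trans[[g]][2L, -1L, , drop = FALSE]
      f <- function(eta) {
        a <- 1 - exp(-outer(delta, cats$r_eta) * eta)
        .q_gain(as.numeric(n00), as.numeric(n01), as.numeric(params$xi * a))
      }
      params$eta[g] <- .coord_max(f, rb[1L], rb[2L], params$eta[g], tol,
                                  log_scale = TRUE)
    }
  }
  if ("theta" %in% free) {
    for (g in seq_len(G)) {
      n10 <- trans[[g]][3L, -1L, , drop = FALSE]
      n11 <- trans[[g]][4L, -1L, , drop = FALSE]
      f <- function(theta) {
        b <- exp(-outer(delta, cats$r_theta) * theta)
        .q_loss(as.numeric(n10), as.numeric(n11),
                as.numeric((1 - params$phi) * b))
      }
      params$theta[g] <- .coord_max(f, rb[1L], rb[2L], params$theta[g], tol,
                                    log_scale = TRUE)
    }
  }
  params
}

# Joint direct maximization of the actual data log-likelihood over the
# scalar (non-branch) free parameters.  EM crawls along the ridge that
# couples pi0, nu, the gamma shapes and the (super)gene rates; a short
# bounded quasi-Newton run on the true likelihood traverses it in a few
# evaluations.  The result is accepted only if it improves the
# likelihood, so monotone ascent is preserved.
.direct_step <- function(dataset, params, config, free, ll_current) {
  fields <- intersect(free, c("pi0", "nu", "lambda_eta", "lambda_theta",
                              "eta", "theta"))
  if (!length(fields))
    return(list(ll = -Inf, params = params))
  rb <- config$rate_bounds; sb <- config$shape_bounds
  x0 <- numeric(0); lo <- numeric(0); hi <- numeric(0)
  spec <- list()
  for (nm in fields) {
    v <- params[[nm]]
    if (nm %in% c("pi0", "nu")) {
      x0 <- c(x0, min(max(v, 1e-8), 1 - 1e-8))
      lo <- c(lo, 1e-8); hi <- c(hi, 1 - 1e-8)
      spec[[length(spec) + 1L]] <- list(nm = nm, n = 1L, log = FALSE)
    } else {
      b <- if (startsWith(nm, "lambda")) sb else rb
      x0 <- c(x0, log(pmin(pmax(v, b[1L]), b[2L])))
      lo <- c(lo, rep(log(b[1L]), length(v)))
      hi <- c(hi, rep(log(b[2L]), length(v)))
      spec[[length(spec) + 1L]] <- list(nm = nm, n = length(v), log = TRUE)
    }
  }
  if (length(x0) > 12L)
    return(list(ll = -Inf, params = params))
  unpack <- function(x) {
    i <- 0L
    for (s in spec) {
      v <- x[i + seq_len(s$n)]; i <- i + s$n
      params[[s$nm]] <- if (s$log) exp(v) else v
    }
    params
  }
  obj <- function(x) {
    m <- unpack(x)
    ll <- suppressWarnings(
      data_loglikelihood(dataset, m, k_eta = config$k_eta,
                         k_theta = config$k_theta))
    if (!is.finite(ll)) return(1e300)
    -ll
  }
  res <- tryCatch(
    stats::optim(x0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = 15L)),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value) || -res$value <= ll_current)
    return(list(ll = ll_current, params = params))
  list(ll = -res$value, params = unpack(res$par))
}

# flatten / restore the free parameters for the extrapolation step
.free_vec <- function(model, free) {
  out <- numeric(0)
  for (nm in c("pi0", "nu", "lambda_eta", "lambda_theta"))
    if (nm %in% free) out <- c(out, model[[nm]])
  if ("xi" %in% free) out <- c(out, model$xi)
  if ("phi" %in% free) out <- c(out, model$phi)
  if ("eta" %in% free) out <- c(out, model$eta)
  if ("theta" %in% free) out <- c(out, model$theta)
  out
}

.free_set <- function(model, free, x, config) {
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  i <- 0L
  take <- function(n) {
    v <- x[i + seq_len(n)]; i <<- i + n; v
  }
  rb <- config$rate_bounds; sb <- config$shape_bounds
  for (nm in c("pi0", "nu", "lambda_eta", "lambda_theta"))
    if (nm %in% free) {
      v <- take(1L)
      model[[nm]] <- if (nm %in% c("pi0", "nu")) clamp(v, 0, 1)
                     else clamp(v, sb[1L], sb[2L])
    }
  nb <- model$tree$n_branch
  if ("xi" %in% free) model$xi <- clamp(take(nb), 0, 1)
  if ("phi" %in% free) model$phi <- clamp(take(nb), 0, 1)
  G <- length(model$eta)
  if ("eta" %in% free) model$eta <- clamp(take(G), rb[1L], rb[2L])
  if ("theta" %in% free) model$theta <- clamp(take(G), rb[1L], rb[2L])
  model
}

.param_vec <- function(model, free) {
  out <- numeric(0)
  for (nm in c("pi0", "nu", "lambda_eta", "lambda_theta"))
    if (nm %in% free) out[nm] <- model[[nm]]
  nb <- model$tree$n_branch
  if ("xi" %in% free)
    out[paste0("xi_", seq_len(nb))] <- model$xi
  if ("phi" %in% free)
    out[paste0("phi_", seq_len(nb))] <- model$phi
  if ("eta" %in% free)
    out[paste0("eta_", model$gene_ids)] <- model$eta
  if ("theta" %in% free)
    out[paste0("theta_", model$gene_ids)] <- model$theta
  out
}

#' Run the EM algorithm
#'
#' Alternates [e_step()] and [m_step()] until the relative change of the
#' data log-likelihood falls below `config$rel_tol` or `config$max_iter`
#' M-steps have been performed.  With `accelerate = TRUE` (the default)
#' every pair of EM maps is followed by a squared-extrapolation step in
#' parameter space (the SQUAREM scheme): the extrapolated candidate is
#' clamped into the parameter bounds and *accepted only if its actual
#' data log-likelihood does not fall below the second EM iterate*, so
#' the monotone-ascent guarantee of EM is preserved while ridge-shaped
#' likelihoods (typically the pi0/nu/shape directions) converge an order
#' of magnitude faster.  Deterministic given dataset, init and config.
#' The log-likelihood trace is nondecreasing (up to 1e-8 numerical
#' slack); a larger decrease raises an internal-error diagnostic, as it
#' would indicate a bug rather than a user error.
#'
#' @param dataset a [gl_patterns()].
#' @param init initial [gl_model()].
#' @param config a [em_config()].
#' @param free parameter groups to estimate (see [m_step()]).
#' @param accelerate use squared extrapolation between EM pairs.
#' @return an object of class `gl_fit`: `params` (final model),
#'   `loglik_trace` (log-likelihood at the initial and at each visited
#'   parameter value, including the final one), `loglik` (final value),
#'   `converged`, `n_iter` (number of M-steps), `histories` (named list
#'   of per-parameter traces, entry 1 = initial value), `stats` (final
#'   `gl_stats` at the fitted parameters).
#' @export
run_em <- function(dataset, init, config = em_config(),
                   free = .all_free, accelerate = TRUE) {
  free <- match.arg(free, .all_free, several.ok = TRUE)
  params <- init
  trace <- numeric(0)
  hist0 <- .param_vec(params, free)
  histories <- lapply(hist0, function(v) v)
  names(histories) <- names(hist0)
  converged <- FALSE
  n_iter <- 0L
  stats <- NULL

  cats_of <- function(p)
    discretize_rate_model(p$nu, p$lambda_eta, p$lambda_theta,
                          config$k_eta, config$k_theta)
  record <- function(p) {
    pv <- .param_vec(p, free)
    for (nm in names(pv))
      histories[[nm]] <<- c(histories[[nm]], pv[[nm]])
  }
  # appends ll to the trace, enforces monotonicity, returns TRUE on
  # convergence relative to the previous trace entry
  note_ll <- function(ll) {
    n <- length(trace)
    if (n > 0L) {
      prev <- trace[n]
      if (ll < prev - 1e-8 * max(1, abs(prev)))
        stop("internal error: EM log-likelihood decreased from ",
             prev, " to ", ll)
    }
    trace <<- c(trace, ll)
    if (is.infinite(config$rel_tol)) return(TRUE)
    n > 0L && abs(ll - trace[n]) < config$rel_tol * (abs(trace[n]) + 1e-12)
  }

  direct_ok <- accelerate &&
    length(intersect(free, c("pi0", "nu", "lambda_eta", "lambda_theta",
                             "eta", "theta"))) > 0L
  cycle <- 0L

  repeat {
  repeat {
    stats <- e_step(dataset, params, cats = cats_of(params))
    if (note_ll(stats$loglik)) { converged <- TRUE; break }
    if (n_iter >= config$max_iter) break
    p0_vec <- .free_vec(params, free)
    p1 <- m_step(stats, params, config, free)
    n_iter <- n_iter + 1L
    if (!accelerate) { record(p1); params <- p1; next }

    stats1 <- e_step(dataset, p1, cats = cats_of(p1))
    params <- p1
    stats <- stats1
    if (note_ll(stats1$loglik)) { record(p1); converged <- TRUE; break }
    if (n_iter >= config$max_iter) { record(p1); break }
    record(p1)
    p2 <- m_step(stats1, p1, config, free)
    n_iter <- n_iter + 1L

    # squared extrapolation through (p0, p1, p2), clamped into bounds
    v0 <- p0_vec
    v1 <- .free_vec(p1, free)
    v2 <- .free_vec(p2, free)
    r <- v1 - v0
    v <- v2 - 2 * v1 + v0
    vv <- sum(v * v)
    accepted <- FALSE
    if (vv > 0 && sum(r * r) > 0) {
      alpha <- -max(1, sqrt(sum(r * r) / vv))
      cand <- .free_set(params, free, v0 - 2 * alpha * r + alpha^2 * v,
                        config)
      ll_cand <- suppressWarnings(
        data_loglikelihood(dataset, cand, cats = cats_of(cand)))
      if (is.finite(ll_cand) && ll_cand >= trace[length(trace)]) {
        params <- cand
        accepted <- TRUE
      }
    }
    if (!accepted) params <- p2
    record(params)
    cycle <- cycle + 1L
    # periodic ridge-traversal step on the true likelihood
    if (direct_ok && cycle %% 20L == 0L && n_iter < config$max_iter) {
      cur <- trace[length(trace)]
      ds <- .direct_step(dataset, params, config, free, cur)
      if (ds$ll > cur) {
        params <- ds$params
        n_iter <- n_iter + 1L
        record(params)
      }
    }
  }
  # on convergence, make sure no ridge remains: try a direct step and,
  # if it still improves the likelihood materially, resume the EM
  if (!converged || !direct_ok || n_iter >= config$max_iter ||
      is.infinite(config$rel_tol)) break
  cur <- trace[length(trace)]
  ds <- .direct_step(dataset, params, config, free, cur)
  if (ds$ll <= cur + config$rel_tol * (abs(cur) + 1e-12)) break
  params <- ds$params
  n_iter <- n_iter + 1L
  record(params)
  converged <- FALSE
  }
  structure(
    list(params = params, loglik_trace = trace, loglik = trace[length(trace)],
         converged = converged, n_iter = n_iter, histories = histories,
         stats = stats, free = free, config = config),
    class = "gl_fit")
}

#' @export
print.gl_fit <- function(x, ...) {
  cat("gl_fit: loglik = ", format(x$loglik), " after ", x$n_iter,
      " iteration(s); ", if (x$converged) "converged" else "not converged",
      "\n", sep = "")
  invisible(x)
}

#' Two-phase estimation: homogeneous supergene, then per-gene rates
#'
#' Phase 1 (*homogeneous*): all genes are concatenated into one
#' supergene (summing pattern counts over genes) and the resulting
#' `2 + 4S`-parameter model — branch coefficients, the four globals and
#' one shared (eta, theta) pair — is fitted by [run_em()].  Phase 2
#' (*heterogeneous*): every parameter estimated in phase 1 is frozen
#' and only the gene-specific rates `(eta_g, theta_g)` are re-estimated,
#' independently per gene, starting from the shared phase-1 values.
#' Genes with no sites keep the phase-1 rates and are flagged.
#'
#' @param dataset a [gl_patterns()] with `G >= 1` genes.
#' @param tree a [gl_tree()].
#' @param config a [em_config()].
#' @param homogeneous_only skip phase 2 (all genes keep the shared
#'   rates).
#' @return an object of class `gl_fit2`: `params` (full `gl_model` with
#'   per-gene rates), `phase1` (the supergene `gl_fit`), `phase2` (list
#'   of per-gene `gl_fit`s, `NULL` for empty genes), `empty_genes`,
#'   `histories` (phase-1 histories plus per-gene rate histories),
#'   `stats` (final `gl_stats` of the full dataset at the fitted
#'   parameters), `loglik`, `n_params`.
#' @export
fit_two_phase <- function(dataset, tree, config = em_config(),
                          homogeneous_only = FALSE) {
  stopifnot(inherits(dataset, "gl_patterns"), dataset$G >= 1L)
  super <- gl_patterns(dataset$patterns,
                       matrix(colSums(dataset$counts), 1L),
                       gene_ids = "supergene", species = dataset$species)
  init1 <- init_params(super, tree, config)
  fit1 <- run_em(super, init1, config, free = .all_free)
  p1 <- fit1$params

  params <- gl_model(tree, p1$xi, p1$phi,
                     rep(p1$eta[1L], dataset$G),
                     rep(p1$theta[1L], dataset$G),
                     p1$pi0, p1$nu, p1$lambda_eta, p1$lambda_theta,
                     gene_ids = dataset$gene_ids)
  histories <- fit1$histories
  phase2 <- vector("list", dataset$G)
  names(phase2) <- dataset$gene_ids
  empty <- rowSums(dataset$counts) == 0

  if (!homogeneous_only) {
    for (g in seq_len(dataset$G)) {
      if (empty[g]) next
      keep <- dataset$counts[g, ] > 0
      dg <- gl_patterns(dataset$patterns[keep],
                        dataset$counts[g, keep, drop = FALSE],
                        gene_ids = dataset$gene_ids[g],
                        species = dataset$species)
      initg <- gl_model(tree, p1$xi, p1$phi, p1$eta[1L], p1$theta[1L],
                        p1$pi0, p1$nu, p1$lambda_eta, p1$lambda_theta,
                        gene_ids = dataset$gene_ids[g])
      fitg <- run_em(dg, initg, config, free = c("eta", "theta"))
      phase2[[g]] <- fitg
      params$eta[g] <- fitg$params$eta[1L]
      params$theta[g] <- fitg$params$theta[1L]
      histories <- c(histories, fitg$histories)
    }
  }
  stats <- e_step(dataset, params,
                  cats = discretize_rate_model(params$nu, params$lambda_eta,
                                               params$lambda_theta,
                                               config$k_eta, config$k_theta))
  structure(
    list(params = params, phase1 = fit1, phase2 = phase2,
         empty_genes = dataset$gene_ids[empty], histories = histories,
         stats = stats, loglik = stats$loglik,
         n_params = n_free_params(params),
         n_params_phase1 = n_free_params(tree$S, G = 1L),
         homogeneous_only = homogeneous_only, config = config),
    class = "gl_fit2")
}

#' @export
print.gl_fit2 <- function(x, ...) {
  cat("gl_fit2: two-phase fit, loglik = ", format(x$loglik), "\n", sep = "")
  cat("  phase 1 (supergene): ", x$n_params_phase1, " free parameters, ",
      x$phase1$n_iter, " iteration(s)\n", sep = "")
  cat("  full model: ", x$n_params, " free parameters\n", sep = "")
  if (length(x$empty_genes))
    cat("  empty gene(s) kept at phase-1 rates: ",
        paste(x$empty_genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}
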