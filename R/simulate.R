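# run code with a locally seeded RNG, restoring the caller's state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate an ultrametric random tree
#'
#' Draws a bifurcating topology with branching times from a Yule
#' (pure-birth) process conditioned on the number of leaves, then
#' rescales node depths so that every root-to-leaf path has total
#' length `time_span`.
#'
#' @param num_leaves number of terminal nodes (>= 2).
#' @param time_span total root-to-leaf time (> 0).
#' @param seed optional integer seed (deterministic output given seed).
#' @return a [gl_tree()] with leaves labelled `t1, t2, ...`.
#' @export
simulate_tree <- function(num_leaves, time_span = 1, seed = NULL) {
  if (num_leaves < 2L) stop("num_leaves must be >= 2")
  if (time_span <= 0) stop("time_span must be > 0")
  .with_seed(seed, {
    phy <- ape::rphylo(num_leaves, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * (time_span / depth)
    as_gl_tree(phy)
  })
}

#' Draw a random model from uniform parameter ranges
#'
#' Every parameter is drawn independently and uniformly from its
#' configured `[lo, hi]` range (a collapsed range `lo == hi` fixes the
#' value).  Branch coefficients are drawn per branch, gene rates per
#' gene, globals once.
#'
#' @param tree a [gl_tree()].
#' @param G number of genes.
#' @param ranges named list of length-2 ranges for `xi`, `phi`, `eta`,
#'   `theta`, `pi0`, `nu`, `lambda_eta`, `lambda_theta`; unnamed
#'   entries fall back to the defaults (moderate gain/loss coefficients,
#'   unit-scale rates, shapes near 1).
#' @param seed optional integer seed.
#' @param gene_ids optional gene names.
#' @return a [gl_model()].
#' @export
random_model <- function(tree, G = 1L, ranges = list(), seed = NULL,
                         gene_ids = NULL) {
  defaults <- list(xi = c(0.2, 0.8), phi = c(0.05, 0.3),
                   eta = c(0.5, 2), theta = c(0.5, 2),
                   pi0 = c(0.3, 0.9), nu = c(0, 0.4),
                   lambda_eta = c(0.5, 2), lambda_theta = c(0.5, 2))
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown))
    stop("unknown parameter range(s): ", paste(unknown, collapse = ", "))
  defaults[names(ranges)] <- ranges
  dom <- list(xi = c(0, 1), phi = c(0, 1), eta = c(0, Inf),
              theta = c(0, Inf), pi0 = c(0, 1), nu = c(0, 1),
              lambda_eta = c(1e-12, Inf), lambda_theta = c(1e-12, Inf))
  for (nm in names(defaults)) {
    r <- defaults[[nm]]
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < dom[[nm]][1L] ||
        r[2L] > dom[[nm]][2L])
      stop("range for '", nm, "' outside parameter domain")
  }
  .with_seed(seed, {
    draw <- function(r, n = 1L) stats::runif(n, r[1L], r[2L])
    nb <- tree$n_branch
    gl_model(tree,
             xi = draw(defaults$xi, nb), phi = draw(defaults$phi, nb),
             eta = draw(defaults$eta, G), theta = draw(defaults$theta, G),
             pi0 = draw(defaults$pi0), nu = draw(defaults$nu),
             lambda_eta = draw(defaults$lambda_eta),
             lambda_theta = draw(defaults$lambda_theta),
             gene_ids = gene_ids)
  })
}

#' Simulate presence/absence data with full ground-truth logging
#'
#' For every site of every gene: draw a rate category from the
#' discretized mixture of [discretize_rate_model()] (the zero-site
#' indicator is the category's gain-zero atom), draw the root state
#' from `(pi0, 1 - pi0)`, propagate states down every branch with the
#' transition matrices of [transition_matrix()], and record the state
#' of every node.  Leaf entries are then masked to `*` independently
#' with probability `missing_rate` before compression into the
#' unique-pattern form; the truth record keeps the unmasked states.
#'
#' @param tree a [gl_tree()].
#' @param model a [gl_model()] on `tree` (its gene count determines `G`
#'   unless `sites_per_gene` is longer).
#' @param sites_per_gene integer vector (recycled to `G`) of site
#'   counts per gene.
#' @param missing_rate probability in `[0, 1]` that a leaf entry is
#'   masked to `*` (missing completely at random).
#' @param seed optional integer seed.
#' @param k_eta,k_theta discretization of the simulated rate mixture
#'   (same grid the estimator integrates over).
#' @return a list with
#' * `dataset` — the [gl_patterns()] built from the masked leaf data,
#' * `truth` — a `gl_truth` object: per gene the `sites x n_nodes`
#'   0/1 state matrix `states`, the per-site category index `cat` and
#'   zero-site flag `zero`, per-node totals `occupancy`, per-branch
#'   totals `gains`/`losses`/`retentions`, plus the category grid and
#'   overall totals.
#' @export
simulate_dataset <- function(tree, model, sites_per_gene,
                             missing_rate = 0, seed = NULL,
                             k_eta = 4L, k_theta = 4L) {
  stopifnot(inherits(tree, "gl_tree"), inherits(model, "gl_model"))
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  G <- length(model$eta)
  n <- rep_len(as.integer(sites_per_gene), G)
  cats <- discretize_rate_model(model$nu, model$lambda_eta,
                                model$lambda_theta, k_eta, k_theta)
  .with_seed(seed, {
    per_gene <- vector("list", G)
    mats <- vector("list", G)
    leaf_ids <- tree$leaves
    for (g in seq_len(G)) {
      ns <- n[g]
      cat_idx <- sample.int(nrow(cats), ns, replace = TRUE,
                            prob = cats$weight)
      states <- matrix(0L, ns, tree$n_nodes)
      states[, 1L] <- stats::rbinom(ns, 1L, 1 - model$pi0)
      for (id in tree$preorder) {
        if (id == 0L) next
        d <- tree$brlen[id + 1L]
        gainp <- model$xi[id] *
          (1 - exp(-cats$r_eta * model$eta[g] * d))
        retp <- (1 - model$phi[id]) *
          exp(-cats$r_theta * model$theta[g] * d)
        par <- states[, tree$parent[id + 1L] + 1L]
        p1 <- ifelse(par == 1L, retp[cat_idx], gainp[cat_idx])
        states[, id + 1L] <- stats::rbinom(ns, 1L, p1)
      }
      parents <- states[, tree$parent[-1L] + 1L, drop = FALSE]
      childs <- states[, -1L, drop = FALSE]
      per_gene[[g]] <- list(
        states = states, cat = cat_idx, zero = cats$zero[cat_idx],
        occupancy = colSums(states),
        gains = colSums(parents == 0L & childs == 1L),
        losses = colSums(parents == 1L & childs == 0L),
        retentions = colSums(parents == 1L & childs == 1L))
      leafm <- matrix(as.character(t(states[, leaf_ids + 1L,
                                            drop = FALSE])),
                      nrow = length(leaf_ids))
      if (missing_rate > 0) {
        mask <- matrix(stats::runif(length(leafm)) < missing_rate,
                       nrow = nrow(leafm))
        leafm[mask] <- "*"
      }
      rownames(leafm) <- tree$labels[leaf_ids + 1L]
      mats[[g]] <- leafm
    }
    names(mats) <- model$gene_ids
    dataset <- compress_alignment(mats, gene_ids = model$gene_ids,
                                  species = tree$labels[leaf_ids + 1L])
    truth <- structure(
      list(per_gene = per_gene, gene_ids = model$gene_ids, cats = cats,
           tree = tree, n_sites = n,
           occupancy = Reduce(`+`, lapply(per_gene, `[[`, "occupancy")),
           gains = Reduce(`+`, lapply(per_gene, `[[`, "gains")),
           losses = Reduce(`+`, lapply(per_gene, `[[`, "losses")),
           retentions = Reduce(`+`, lapply(per_gene, `[[`, "retentions"))),
      class = "gl_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' @export
print.gl_truth <- function(x, ...) {
  cat("gl_truth: ", length(x$per_gene), " gene(s), ", sum(x$n_sites),
      " sites\n  total gains = ", sum(x$gains), ", losses = ",
      sum(x$losses), "\n", sep = "")
  invisible(x)
}

#' Write the simulation truth record as TSV
#'
#' Long format, one row per (gene, site, node): columns `gene`, `site`,
#' `node`, `state`, `category`, `zero_site`.  Intended for comparison
#' with the ancestral reconstruction.
#'
#' @param truth a `gl_truth` from [simulate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "gl_truth"))
  rows <- lapply(seq_along(truth$per_gene), function(g) {
    pg <- truth$per_gene[[g]]
    ns <- nrow(pg$states)
    nn <- ncol(pg$states)
    data.frame(gene = truth$gene_ids[g],
               site = rep(seq_len(ns), nn),
               node = rep(seq_len(nn) - 1L, each = ns),
               state = as.vector(pg$states),
               category = rep(pg$cat, nn),
               zero_site = rep(pg$zero, nn))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Marginal per-branch gain and loss probabilities of a model
#'
#' The compound, per-site marginal probabilities that make the model
#' identifiable even when individual coefficients are not:
#' `gain[t] = xi_t * E[1 - exp(-r_eta * eta * Delta_t)]` and
#' `loss[t] = 1 - (1 - phi_t) * E[exp(-r_theta * theta * Delta_t)]`,
#' the expectations running over the discretized rate mixture.
#'
#' @param model a [gl_model()].
#' @param g gene index.
#' @param k_eta,k_theta discretization bin counts.
#' @return data.frame with columns `branch`, `gain`, `loss`.
#' @export
compound_branch_probs <- function(model, g = 1L, k_eta = 4L, k_theta = 4L) {
  cats <- discretize_rate_model(model$nu, model$lambda_eta,
                                model$lambda_theta, k_eta, k_theta)
  delta <- model$tree$brlen[-1L]
  A <- 1 - exp(-outer(delta, cats$r_eta) * model$eta[g])
  B <- exp(-outer(delta, cats$r_theta) * model$theta[g])
  data.frame(branch = seq_along(delta),
             gain = model$xi * as.vector(A %*% cats$weight),
             loss = 1 - (1 - model$phi) * as.vector(B %*% cats$weight))
}
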