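#' Posterior expected occupancy per node
#'
#' Occupancy of gene `g` at node `v` is the expected number of sites in
#' state 1 at that node given the data and the model:
#' `sum over sites of Pr(q_v = 1 | data)`.  At a fully observed leaf it
#' equals the observed count of 1s.  The fraction divides by the gene's
#' total site count `n_g` (including missing entries).
#'
#' @param stats a `gl_stats` from [e_step()] computed at the fitted
#'   parameters.
#' @return a data.frame with columns `gene`, `node` (id), `occupancy`
#'   (expected count) and `fraction`.
#' @export
node_occupancy <- function(stats) {
  stopifnot(inherits(stats, "gl_stats"))
  G <- length(stats$per_gene)
  n_nodes <- stats$tree$n_nodes
  out <- do.call(rbind, lapply(seq_len(G), function(g) {
    occ <- stats$per_gene[[g]]$node_post[, 2L]
    ng <- stats$n_sites[g]
    data.frame(gene = stats$gene_ids[g], node = seq_len(n_nodes) - 1L,
               occupancy = occ,
               fraction = if (ng > 0) occ / ng else 0)
  }))
  rownames(out) <- NULL
  out
}

#' Posterior expected events per branch
#'
#' For each gene and branch `t` (the branch into node `t`), the expected
#' numbers of gains (0 to 1), losses (1 to 0) and retentions (1 to 1)
#' are the site-summed posterior joint probabilities of the
#' corresponding parent/child state pairs, with rate categories
#' marginalized.
#'
#' @inheritParams node_occupancy
#' @return a data.frame with columns `gene`, `branch`, `gains`,
#'   `losses`, `retentions`.
#' @export
branch_events <- function(stats) {
  stopifnot(inherits(stats, "gl_stats"))
  G <- length(stats$per_gene)
  nb <- stats$tree$n_branch
  out <- do.call(rbind, lapply(seq_len(G), function(g) {
    tr <- stats$per_gene[[g]]$trans        # 4 x n_nodes x ncat
    data.frame(gene = stats$gene_ids[g], branch = seq_len(nb),
               gains = apply(tr[2L, -1L, , drop = FALSE], 2L, sum),
               losses = apply(tr[3L, -1L, , drop = FALSE], 2L, sum),
               retentions = apply(tr[4L, -1L, , drop = FALSE], 2L, sum))
  }))
  rownames(out) <- NULL
  out
}

#' Full ancestral reconstruction report
#'
#' Combines [node_occupancy()] and [branch_events()] for each gene and
#' adds the overall (gene-summed) tables.  Reconstruction is reported as
#' posterior expectations ("soft" counts), not hard state assignments.
#'
#' @param x a `gl_stats`, or a `gl_fit`/`gl_fit2` whose final `stats`
#'   are used.
#' @return an object of class `gl_recon`: list with `occupancy`,
#'   `events` (per-gene data.frames), `overall` (list with the two
#'   gene-summed data.frames) and `n_sites`.
#' @export
reconstruct <- function(x) {
  stats <- if (inherits(x, "gl_stats")) x else x$stats
  occ <- node_occupancy(stats)
  ev <- branch_events(stats)
  structure(list(occupancy = occ, events = ev,
                 overall = overall_reconstruction(occ, ev,
                                                  n_total = sum(stats$n_sites)),
                 n_sites = stats$n_sites),
            class = "gl_recon")
}

#' Sum a per-gene reconstruction over genes
#'
#' @param occupancy,events the per-gene tables of [node_occupancy()]
#'   and [branch_events()] (or a `gl_recon` as first argument).
#' @param n_total total number of sites over all genes; when supplied,
#'   the overall occupancy fraction is `occupancy / n_total`, otherwise
#'   `NA`.
#' @return list with gene-summed `occupancy` and `events` data.frames
#'   (gene column set to `"overall"`).
#' @export
overall_reconstruction <- function(occupancy, events = NULL,
                                   n_total = NULL) {
  if (inherits(occupancy, "gl_recon")) {
    if (is.null(n_total)) n_total <- sum(occupancy$n_sites)
    events <- occupancy$events
    occupancy <- occupancy$occupancy
  }
  occ <- stats::aggregate(occupancy ~ node, data = occupancy, FUN = sum)
  occ <- occ[order(occ$node), ]
  occ <- data.frame(gene = "overall", node = occ$node,
                    occupancy = occ$occupancy,
                    fraction = if (!is.null(n_total) && n_total > 0)
                      occ$occupancy / n_total else NA_real_)
  ev <- stats::aggregate(cbind(gains, losses, retentions) ~ branch,
                         data = events, FUN = sum)
  ev <- data.frame(gene = "overall", ev[order(ev$branch), ])
  rownames(occ) <- rownames(ev) <- NULL
  list(occupancy = occ, events = ev)
}

#' @export
print.gl_recon <- function(x, ...) {
  cat("gl_recon: ", length(unique(x$occupancy$gene)), " gene(s), ",
      nrow(x$overall$occupancy), " nodes\n", sep = "")
  cat("  overall state-1 sites at root: ",
      format(x$overall$occupancy$occupancy[1L]), "\n", sep = "")
  cat("  overall gains = ", format(sum(x$overall$events$gains)),
      ", losses = ", format(sum(x$overall$events$losses)), "\n", sep = "")
  invisible(x)
}
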