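.fmt <- function(x) formatC(x, digits = 6L, format = "g")

#' Serialize / read a fitted parameter set as a text file
#'
#' A simple `key = value` format (one parameter per line; vectors
#' whitespace-separated) plus the tree in newick on a `tree = ` line,
#' so that estimation and reconstruction can be run as separate steps.
#'
#' @param model a [gl_model()].
#' @param path file path.
#' @return `read_params()` returns a `gl_model`; `write_params()`
#'   returns `path` invisibly.
#' @export
write_params <- function(model, path) {
  stopifnot(inherits(model, "gl_model"))
  num <- function(x) paste(format(x, digits = 17L), collapse = " ")
  lines <- c(
    paste0("tree = ", .newick_string(model$tree)),
    paste0("gene_ids = ", paste(model$gene_ids, collapse = " ")),
    paste0("pi0 = ", num(model$pi0)),
    paste0("nu = ", num(model$nu)),
    paste0("lambda_eta = ", num(model$lambda_eta)),
    paste0("lambda_theta = ", num(model$lambda_theta)),
    paste0("xi = ", num(model$xi)),
    paste0("phi = ", num(model$phi)),
    paste0("eta = ", num(model$eta)),
    paste0("theta = ", num(model$theta)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path)
  kv <- list()
  for (ln in lines[nzchar(lines)]) {
    m <- regmatches(ln, regexec("^([a-z0-9_]+)[ \t]*=[ \t]*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("malformed parameter line: ", ln)
    kv[[m[2L]]] <- m[3L]
  }
  need <- c("tree", "pi0", "nu", "lambda_eta", "lambda_theta",
            "xi", "phi", "eta", "theta")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop("parameter file missing: ", paste(miss, collapse = ", "))
  tf <- tempfile(fileext = ".nwk")
  on.exit(unlink(tf))
  writeLines(kv$tree, tf)
  tree <- read_tree(tf)
  nums <- function(k) as.numeric(strsplit(trimws(kv[[k]]), "[ \t]+")[[1L]])
  gene_ids <- if (!is.null(kv$gene_ids))
    strsplit(trimws(kv$gene_ids), "[ \t]+")[[1L]] else NULL
  gl_model(tree, nums("xi"), nums("phi"), nums("eta"), nums("theta"),
           nums("pi0"), nums("nu"), nums("lambda_eta"),
           nums("lambda_theta"), gene_ids = gene_ids)
}

#' Write the run summary file
#'
#' A human-readable text file summarizing the input, the estimated
#' parameters and the overall ancestral reconstruction.  The parameter
#' block uses machine-parseable `key = value` lines (6 significant
#' digits).
#'
#' @param fit a `gl_fit` or `gl_fit2`.
#' @param recon a [reconstruct()] report (optional; computed from the
#'   fit's stats when omitted).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(fit, recon = NULL, path) {
  model <- fit$params
  if (is.null(recon)) recon <- reconstruct(fit)
  two_phase <- inherits(fit, "gl_fit2")
  S <- model$tree$S; G <- length(model$eta)
  lines <- c(
    "# gain/loss model fit summary",
    "",
    "[input]",
    paste0("n_species = ", S),
    paste0("n_genes = ", G),
    paste0("n_sites = ", sum(recon$n_sites)),
    paste0("species = ",
           paste(model$tree$labels[model$tree$leaves + 1L],
                 collapse = " ")),
    "",
    "[fit]",
    paste0("procedure = ",
           if (two_phase) "two-phase" else "single-phase"),
    paste0("n_params = ", n_free_params(model)),
    if (two_phase)
      paste0("n_params_phase1 = ", fit$n_params_phase1),
    paste0("loglik = ", format(fit$loglik, digits = 12L)),
    if (!two_phase) paste0("converged = ", fit$converged),
    if (!two_phase) paste0("n_iter = ", fit$n_iter),
    "",
    "[parameters]",
    paste0("pi0 = ", .fmt(model$pi0)),
    paste0("nu = ", .fmt(model$nu)),
    paste0("lambda_eta = ", .fmt(model$lambda_eta)),
    paste0("lambda_theta = ", .fmt(model$lambda_theta)),
    paste0("xi_", seq_len(model$tree$n_branch), " = ", .fmt(model$xi)),
    paste0("phi_", seq_len(model$tree$n_branch), " = ", .fmt(model$phi)),
    paste0("eta_", model$gene_ids, " = ", .fmt(model$eta)),
    paste0("theta_", model$gene_ids, " = ", .fmt(model$theta)),
    "",
    "[overall reconstruction]",
    "# node\toccupancy\tfraction",
    paste0(recon$overall$occupancy$node, "\t",
           .fmt(recon$overall$occupancy$occupancy), "\t",
           .fmt(recon$overall$occupancy$fraction)),
    "# branch\tgains\tlosses\tretentions",
    paste0(recon$overall$events$branch, "\t",
           .fmt(recon$overall$events$gains), "\t",
           .fmt(recon$overall$events$losses), "\t",
           .fmt(recon$overall$events$retentions)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-parameter iteration history
#'
#' Two tab-separated columns, `iteration` and `value`; iteration 0 is
#' the initial value, so a fit with `n` iterations yields `n + 1`
#' data lines.
#'
#' @param param_name parameter name (used in the header).
#' @param trace numeric vector of values, initial value first.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_history <- function(param_name, trace, path) {
  lines <- c(paste0("iteration\t", param_name),
             paste0(seq_along(trace) - 1L, "\t",
                    format(trace, digits = 10L)))
  writeLines(lines, path)
  invisible(path)
}

#' Write one history file per estimated parameter
#'
#' Files are named `<param>.history` inside `dir`.
#'
#' @param fit a `gl_fit` or `gl_fit2` (its `histories` entry is used).
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_histories <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(fit$histories)) {
    p <- file.path(dir, paste0(nm, ".history"))
    write_history(nm, fit$histories[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write the ancestral reconstruction report as TSV
#'
#' One row per (gene, node) with the expected occupancy, and one row
#' per (gene, branch) with the expected gains, losses and retentions;
#' the `record` column distinguishes the two.  The overall (gene-
#' summed) rows use gene id `overall`; with `per_gene = FALSE` only
#' those are written.
#'
#' @param recon a [reconstruct()] report.
#' @param path output path.
#' @param per_gene include the per-gene rows (default TRUE).
#' @return `path`, invisibly.
#' @export
write_reconstruction_report <- function(recon, path, per_gene = TRUE) {
  stopifnot(inherits(recon, "gl_recon"))
  occ <- recon$overall$occupancy
  ev <- recon$overall$events
  if (per_gene) {
    occ <- rbind(recon$occupancy, occ)
    ev <- rbind(recon$events, ev)
  }
  lines <- c(
    "record\tgene\tid\toccupancy\tfraction\tgains\tlosses\tretentions",
    paste0("node\t", occ$gene, "\t", occ$node, "\t", .fmt(occ$occupancy),
           "\t", .fmt(occ$fraction), "\tNA\tNA\tNA"),
    paste0("branch\t", ev$gene, "\t", ev$branch, "\tNA\tNA\t",
           .fmt(ev$gains), "\t", .fmt(ev$losses), "\t",
           .fmt(ev$retentions)))
  writeLines(lines, path)
  invisible(path)
}
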