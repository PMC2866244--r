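#' Rooted bifurcating phylogeny with the branch-into-node convention
#'
#' A `gl_tree` indexes the `2S - 1` nodes of a rooted bifurcating tree
#' with `S` leaves as `0, 1, ..., 2S - 2`, where node 0 is the root and
#' branch `t` is the branch leading *into* node `t` (so there are
#' `2S - 2` branches, `t = 1, ..., 2S - 2`).  Indices are assigned by
#' preorder traversal with children visited in input order, which makes
#' the numbering a deterministic function of the newick file.
#'
#' Internally, per-node quantities are stored in vectors of length
#' `2S - 1` whose position `k` refers to node id `k - 1`.
#'
#' @param parent integer vector of length `2S - 1`; `parent[k]` is the
#'   node id of the parent of node `k - 1` (`NA` for the root).
#' @param brlen numeric vector of length `2S - 1`; `brlen[k]` is the
#'   length of the branch leading into node `k - 1` (`NA` for the root).
#' @param labels character vector of node labels; leaves must be
#'   labelled, internal labels may be empty strings.
#' @param allow_zero_brlen permit zero-length branches (default FALSE:
#'   all branch lengths must be strictly positive).
#'
#' @return an object of class `gl_tree` with elements `S` (leaf count),
#'   `n_nodes`, `n_branch`, `parent`, `children` (list of child node
#'   ids), `brlen`, `labels`, `leaves` (leaf node ids in declared
#'   species order), `preorder` (node ids, root first).
#' @export
gl_tree <- function(parent, brlen, labels, allow_zero_brlen = FALSE) {
  n_nodes <- length(parent)
  if (n_nodes < 3L || n_nodes %% 2L == 0L)
    stop("a rooted bifurcating tree has an odd number of nodes >= 3, got ",
         n_nodes)
  if (length(brlen) != n_nodes || length(labels) != n_nodes)
    stop("parent, brlen and labels must have equal length")
  if (!is.na(parent[1L]))
    stop("node 0 must be the root (parent[1] must be NA)")
  if (anyNA(parent[-1L]))
    stop("every non-root node needs exactly one parent")

  children <- vector("list", n_nodes)
  for (k in seq_len(n_nodes)) children[[k]] <- integer(0)
  for (k in 2L:n_nodes) {
    p <- parent[k]
    if (p < 0L || p > n_nodes - 1L)
      stop("parent id out of range for node ", k - 1L)
    children[[p + 1L]] <- c(children[[p + 1L]], k - 1L)
  }
  deg <- lengths(children)
  if (!all(deg %in% c(0L, 2L)))
    stop("tree is not bifurcating: node(s) ",
         paste(which(!deg %in% c(0L, 2L)) - 1L, collapse = ", "),
         " have ", paste(deg[!deg %in% c(0L, 2L)], collapse = ", "),
         " children")

  bl <- brlen[-1L]
  if (anyNA(bl) || any(!is.finite(bl)))
    stop("every non-root node needs a finite branch length")
  if (any(bl < 0)) stop("negative branch length")
  if (!allow_zero_brlen && any(bl == 0))
    stop("zero branch length (set allow_zero_brlen = TRUE to permit)")

  preorder <- integer(n_nodes)
  stack <- 0L
  i <- 0L
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    i <- i + 1L
    preorder[i] <- v
    stack <- c(children[[v + 1L]], stack)
  }
  if (i != n_nodes) stop("tree is not connected")

  leaves <- preorder[deg[preorder + 1L] == 0L]
  if (any(labels[leaves + 1L] == "" | is.na(labels[leaves + 1L])))
    stop("all leaves must be labelled")
  if (anyDuplicated(labels[leaves + 1L]))
    stop("duplicated leaf labels")

  structure(
    list(S = length(leaves), n_nodes = n_nodes, n_branch = n_nodes - 1L,
         parent = parent, children = children, brlen = brlen,
         labels = labels, leaves = leaves, preorder = preorder),
    class = "gl_tree")
}

#' @export
print.gl_tree <- function(x, ...) {
  cat("gl_tree: ", x$S, " leaves, ", x$n_nodes, " nodes, ",
      x$n_branch, " branches\n", sep = "")
  cat("  species: ", paste(x$labels[x$leaves + 1L], collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# child columns for fast traversal: matrix 2 x n_internal is overkill;
# expose the two children of an internal node id
.children_of <- function(tree, id) tree$children[[id + 1L]]

.is_leaf <- function(tree, id) length(tree$children[[id + 1L]]) == 0L

#' Convert an ape "phylo" object to a gl_tree
#'
#' Node ids follow preorder with children in the order stored in the
#' `phylo` edge matrix (file order for trees read by [ape::read.tree()]).
#'
#' @param phy an [ape::read.tree()] style `phylo` object, rooted and
#'   bifurcating, with branch lengths.
#' @inheritParams gl_tree
#' @return a `gl_tree`.
#' @export
as_gl_tree <- function(phy, allow_zero_brlen = FALSE) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape 'phylo' object")
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop("need at least 2 leaves")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  n_ape <- ntip + phy$Nnode
  kids <- vector("list", n_ape)
  elen <- rep(NA_real_, n_ape)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; c_ <- phy$edge[e, 2L]
    kids[[p]] <- c(kids[[p]], c_)
    elen[c_] <- phy$edge.length[e]
  }
  root_ape <- ntip + 1L
  n_nodes <- n_ape
  parent <- rep(NA_integer_, n_nodes)
  brlen <- rep(NA_real_, n_nodes)
  labels <- rep("", n_nodes)
  newid <- rep(NA_integer_, n_ape)
  nxt <- 0L
  stack <- root_ape
  par_of <- rep(NA_integer_, n_ape)
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    id <- nxt; nxt <- nxt + 1L
    newid[v] <- id
    if (!is.na(par_of[v])) {
      parent[id + 1L] <- newid[par_of[v]]
      brlen[id + 1L] <- elen[v]
    }
    if (v <= ntip) labels[id + 1L] <- phy$tip.label[v]
    ch <- kids[[v]]
    if (length(ch)) {
      par_of[ch] <- v
      stack <- c(ch, stack)
    }
  }
  gl_tree(parent, brlen, labels, allow_zero_brlen = allow_zero_brlen)
}

#' Convert a gl_tree back to an ape "phylo" object
#' @param tree a `gl_tree`.
#' @return an ape `phylo` object.
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = .newick_string(tree))
}

.newick_string <- function(tree) {
  rec <- function(id) {
    ch <- tree$children[[id + 1L]]
    lab <- tree$labels[id + 1L]
    if (length(ch) == 0L) {
      core <- lab
    } else {
      core <- paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")",
                     lab)
    }
    if (id == 0L) paste0(core, ";")
    else paste0(core, ":", format(tree$brlen[id + 1L], digits = 15L,
                                  scientific = FALSE))
  }
  rec(0L)
}

#' Read / write a rooted bifurcating newick tree
#'
#' `read_tree()` parses a newick file into a [gl_tree()]; node ids are
#' assigned root = 0, then preorder with children in file order.
#' `write_tree()` writes a `gl_tree` as newick; `write_tree()` followed
#' by `read_tree()` reproduces topology, labels and branch lengths to
#' better than 1e-9.
#'
#' @param path file path.
#' @inheritParams gl_tree
#' @return `read_tree()` returns a `gl_tree`; `write_tree()` returns
#'   `path` invisibly.
#' @export
read_tree <- function(path, allow_zero_brlen = FALSE) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("newick parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(phy)) stop("newick parse error in '", path,
                         "': no tree could be read")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  as_gl_tree(phy, allow_zero_brlen = allow_zero_brlen)
}

#' @rdname read_tree
#' @param tree a `gl_tree`.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "gl_tree"))
  writeLines(.newick_string(tree), path)
  invisible(path)
}

# depth of every node (sum of branch lengths from the root)
.node_depths <- function(tree) {
  d <- numeric(tree$n_nodes)
  for (id in tree$preorder) {
    if (id == 0L) next
    d[id + 1L] <- d[tree$parent[id + 1L] + 1L] + tree$brlen[id + 1L]
  }
  d
}
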