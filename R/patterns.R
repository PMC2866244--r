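#' Unique-pattern dataset
#'
#' A *pattern* is the length-`S` column of presence/absence states of
#' one site across species, over the alphabet `{0, 1, *}` (`*` =
#' missing).  A `gl_patterns` object stores the `P` distinct patterns of
#' a data set once, plus a `G x P` matrix counting how many sites of
#' each gene show each pattern.  This is the compressed representation
#' the estimator works on: the likelihood only ever needs each distinct
#' pattern once, weighted by its count.
#'
#' @param patterns character vector of `P` distinct strings of length
#'   `S` over `0`, `1`, `*`.
#' @param counts `G x P` matrix of nonnegative integers; `counts[g, p]`
#'   is the number of sites of gene `g` with pattern `p`.
#' @param gene_ids character vector of `G` gene names.
#' @param species optional character vector of the `S` species names in
#'   pattern row order (matching the tree's declared leaf order).
#' @return an object of class `gl_patterns` with fields `patterns`,
#'   `counts`, `gene_ids`, `species`, `S`, `P`, `G`, and `states`
#'   (a `P x S` integer matrix, 0/1 with `NA` for `*`).
#' @export
gl_patterns <- function(patterns, counts, gene_ids = NULL, species = NULL) {
  patterns <- as.character(patterns)
  P <- length(patterns)
  if (P == 0L) {
    S <- if (!is.null(species)) length(species) else 0L
    counts <- matrix(0L, nrow = NROW(counts), ncol = 0L)
  } else {
    S <- unique(nchar(patterns))
    if (length(S) != 1L)
      stop("all patterns must have the same length")
    if (anyDuplicated(patterns)) stop("patterns must be pairwise distinct")
    if (grepl("[^01*]", paste(patterns, collapse = "")))
      stop("patterns may only contain characters 0, 1, *")
  }
  counts <- as.matrix(counts)
  if (ncol(counts) != P) stop("counts must have one column per pattern")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  G <- nrow(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(G))
  if (length(gene_ids) != G) stop("gene_ids must have length G")
  states <- .pattern_states(patterns, S)
  structure(
    list(patterns = patterns, counts = counts,
         gene_ids = as.character(gene_ids), species = species,
         S = as.integer(S), P = as.integer(P), G = as.integer(G),
         states = states),
    class = "gl_patterns")
}

.pattern_states <- function(patterns, S) {
  if (length(patterns) == 0L)
    return(matrix(NA_integer_, 0L, S))
  ch <- matrix(unlist(strsplit(patterns, "", fixed = TRUE), use.names = FALSE),
               nrow = length(patterns), ncol = S, byrow = TRUE)
  st <- matrix(NA_integer_, nrow(ch), ncol(ch))
  st[ch == "0"] <- 0L
  st[ch == "1"] <- 1L
  st
}

#' @export
print.gl_patterns <- function(x, ...) {
  cat("gl_patterns: S = ", x$S, ", G = ", x$G, ", P = ", x$P,
      " unique patterns, ", sum(x$counts), " sites\n", sep = "")
  invisible(x)
}

#' Total sites per gene
#' @param dataset a `gl_patterns`.
#' @return named integer vector of per-gene site counts `n_g`.
#' @export
gene_sites <- function(dataset) {
  n <- rowSums(dataset$counts)
  names(n) <- dataset$gene_ids
  n
}

#' Compress raw alignment matrices into the unique-pattern form
#'
#' Each gene is an `S x n_g` matrix over `{0, 1, *}` whose rows follow
#' the declared species order.  Columns (sites) are collapsed to the
#' distinct patterns across *all* genes, in order of first appearance,
#' and per-gene multiplicities are recorded.  Patterns containing `*`
#' are distinct from their resolved versions even when they agree on
#' every observed entry.
#'
#' @param matrices list of `G` character matrices (entries `"0"`, `"1"`,
#'   `"*"`), all with the same number of rows `S`; 0/1 numeric matrices
#'   with `NA` for missing are also accepted.
#' @param gene_ids optional gene names (defaults to list names or
#'   `gene1, ...`).
#' @param species optional species names (defaults to shared rownames).
#' @return a [gl_patterns()] dataset with
#'   `sum(counts[g, ]) == ncol(matrices[[g]])`.
#' @export
compress_alignment <- function(matrices, gene_ids = NULL, species = NULL) {
  if (!is.list(matrices)) matrices <- list(matrices)
  G <- length(matrices)
  if (is.null(gene_ids)) {
    gene_ids <- names(matrices)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(G))
  }
  if (G == 0L)
    return(gl_patterns(character(0), matrix(0L, 0L, 0L), character(0),
                       species))
  mats <- lapply(matrices, .as_char_alignment)
  S <- unique(vapply(mats, nrow, 1L))
  if (length(S) != 1L)
    stop("all alignment matrices must have the same number of rows (species)")
  if (is.null(species)) species <- rownames(mats[[1L]])
  col_strings <- lapply(mats, function(m) {
    if (ncol(m) == 0L) return(character(0))
    do.call(paste0, lapply(seq_len(nrow(m)), function(i) m[i, ]))
  })
  all_str <- unlist(col_strings, use.names = FALSE)
  pats <- unique(all_str)             # first-appearance order
  P <- length(pats)
  counts <- matrix(0L, G, P)
  for (g in seq_len(G)) {
    idx <- match(col_strings[[g]], pats)
    if (length(idx))
      counts[g, ] <- tabulate(idx, nbins = P)
  }
  gl_patterns(pats, counts, gene_ids, species)
}

.as_char_alignment <- function(m) {
  m <- as.matrix(m)
  if (is.numeric(m) || is.logical(m)) {
    ch <- matrix("*", nrow(m), ncol(m), dimnames = dimnames(m))
    ch[!is.na(m) & m == 0] <- "0"
    ch[!is.na(m) & m == 1] <- "1"
    if (any(!is.na(m) & m != 0 & m != 1))
      stop("alignment entries must be 0, 1 or missing")
    return(ch)
  }
  m <- matrix(as.character(m), nrow(m), ncol(m), dimnames = dimnames(m))
  if (any(!m %in% c("0", "1", "*")))
    stop("alignment entries must be '0', '1' or '*'")
  m
}

#' Expand a pattern dataset back into per-gene alignment matrices
#'
#' Inverse of [compress_alignment()] up to column order: each pattern is
#' repeated by its count, so the multiset of columns per gene is
#' preserved.
#'
#' @param dataset a `gl_patterns`.
#' @return list of `G` character matrices.
#' @export
expand_patterns <- function(dataset) {
  ch <- t(vapply(dataset$patterns,
                 function(p) strsplit(p, "", fixed = TRUE)[[1L]],
                 character(dataset$S), USE.NAMES = FALSE))
  out <- vector("list", dataset$G)
  names(out) <- dataset$gene_ids
  for (g in seq_len(dataset$G)) {
    idx <- rep(seq_len(dataset$P), dataset$counts[g, ])
    m <- t(ch[idx, , drop = FALSE])
    rownames(m) <- dataset$species
    out[[g]] <- m
  }
  out
}

#' Read / write the unique-pattern and pattern-count files
#'
#' The pattern file has one pattern per line: `S` characters over
#' `{0, 1, *}`, no separators.  The count file has a header line
#' `gene` followed by the pattern indices `1..P`, then one line per
#' gene: the gene id followed by `P` whitespace-separated counts.
#' `read_patterns()` + `read_counts()` invert `write_patterns()` +
#' `write_counts()` exactly.
#'
#' @param dataset a [gl_patterns()].
#' @param path file path.
#' @return `read_patterns()` returns the character vector of patterns;
#'   `read_counts()` returns a list with `gene_ids` and the `G x P`
#'   `counts` matrix; writers return `path` invisibly.
#' @seealso [read_pattern_dataset()] to assemble both into a dataset.
#' @export
write_patterns <- function(dataset, path) {
  stopifnot(inherits(dataset, "gl_patterns"))
  writeLines(dataset$patterns, path)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  if (!file.exists(path)) stop("pattern file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    bad <- grepl("[^01*]", lines)
    if (any(bad))
      stop("pattern file '", path, "': illegal character on line ",
           which(bad)[1L])
    if (length(unique(nchar(lines))) > 1L)
      stop("pattern file '", path, "': patterns of unequal length")
    if (anyDuplicated(lines))
      stop("pattern file '", path, "': duplicated pattern on line ",
           anyDuplicated(lines))
  }
  lines
}

#' @rdname write_patterns
#' @export
write_counts <- function(dataset, path) {
  stopifnot(inherits(dataset, "gl_patterns"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", seq_len(dataset$P)), collapse = "\t"), con)
  for (g in seq_len(dataset$G))
    writeLines(paste(c(dataset$gene_ids[g], dataset$counts[g, ]),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("count file '", path, "' is empty")
  header <- strsplit(lines[1L], "[\t ]+")[[1L]]
  P <- length(header) - 1L
  if (P < 0L || header[1L] != "gene")
    stop("count file '", path, "': malformed header")
  G <- length(lines) - 1L
  counts <- matrix(0L, G, P)
  gene_ids <- character(G)
  for (g in seq_len(G)) {
    f <- strsplit(lines[g + 1L], "[\t ]+")[[1L]]
    if (length(f) != P + 1L)
      stop("count file '", path, "': line ", g + 1L, " has ",
           length(f) - 1L, " counts, expected ", P)
    gene_ids[g] <- f[1L]
    v <- suppressWarnings(as.integer(f[-1L]))
    if (anyNA(v) || any(v < 0))
      stop("count file '", path, "': invalid count on line ", g + 1L)
    counts[g, ] <- v
  }
  list(gene_ids = gene_ids, counts = counts)
}

#' Assemble a dataset from a pattern file and a count file
#'
#' @param patterns_path,counts_path paths of the two files.
#' @param species optional species names in pattern row order.
#' @return a [gl_patterns()].
#' @export
read_pattern_dataset <- function(patterns_path, counts_path, species = NULL) {
  pats <- read_patterns(patterns_path)
  cc <- read_counts(counts_path)
  if (ncol(cc$counts) != length(pats))
    stop("count file references ", ncol(cc$counts),
         " patterns but pattern file has ", length(pats))
  gl_patterns(pats, cc$counts, cc$gene_ids, species)
}

#' Write both pattern and count files of a dataset
#' @param dataset a `gl_patterns`.
#' @param patterns_path,counts_path output paths.
#' @return invisibly, the two paths.
#' @export
write_pattern_dataset <- function(dataset, patterns_path, counts_path) {
  write_patterns(dataset, patterns_path)
  write_counts(dataset, counts_path)
  invisible(c(patterns_path, counts_path))
}

# reorder pattern columns from the dataset's species order to the
# tree's leaf order; returns P x S integer matrix (NA = missing) whose
# column j corresponds to tree$leaves[j].
.states_for_tree <- function(dataset, tree) {
  if (dataset$S != tree$S)
    stop("dataset has ", dataset$S, " species but tree has ", tree$S)
  st <- dataset$states
  if (!is.null(dataset$species)) {
    leaf_labels <- tree$labels[tree$leaves + 1L]
    idx <- match(leaf_labels, dataset$species)
    if (anyNA(idx))
      stop("species missing from dataset: ",
           paste(leaf_labels[is.na(idx)], collapse = ", "))
    st <- st[, idx, drop = FALSE]
  }
  st
}
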