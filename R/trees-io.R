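#' Parse a single newick tree
#'
#' Parses one newick statement into an [ape::phylo] object. Labels are runs of
#' characters excluding `( ) , : ;` and whitespace; single-quoted labels are
#' accepted. Branch lengths and internal node labels, if present, are stored
#' but never used by the scoring functions (all distances here are purely
#' topological). Polytomies are preserved.
#'
#' @param text A character scalar holding one newick statement terminated by
#'   `";"`.
#' @return A `phylo` object (a single-leaf tree is returned as a valid
#'   one-tip `phylo`).
#' @examples
#' tr <- read_newick("((A,B),(C,D));")
#' leaf_labels(tr)
#' @seealso [write_newick()], [read_tree_file()]
#' @export
read_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single character string")
  check_newick_syntax(text)
  txt <- trimws(text)
  # single-leaf degenerate statement: "A;" has no parentheses
  if (!grepl("(", txt, fixed = TRUE)) {
    lab <- sub(";\\s*$", "", txt)
    lab <- unquote_label(lab)
    if (!nzchar(lab)) stop("newick parse error: empty leaf label")
    return(single_tip_tree(lab))
  }
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) stop("newick parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop("newick parse error: could not read tree")
  validate_tree(phy)
  phy
}

# fast structural checks with character offsets, ahead of ape's parser
check_newick_syntax <- function(text) {
  txt <- trimws(text)
  if (!grepl(";\\s*$", txt))
    stop("newick parse error: missing ';' terminator at offset ", nchar(txt))
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unbalanced ')' at offset ", i)
    }
  }
  if (depth != 0L)
    stop("newick parse error: ", depth, " unclosed '(' (first at offset ",
         which(chars == "(")[1L], ")")
  invisible(TRUE)
}

unquote_label <- function(x) gsub("^'|'$", "", x)

single_tip_tree <- function(label) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                 tip.label = label, Nnode = 1L),
            class = "phylo", order = "cladewise")
}

validate_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object")
  labs <- phy$tip.label
  if (any(is.na(labs) | !nzchar(labs)))
    stop("newick parse error: empty leaf label")
  if (anyDuplicated(labs))
    stop("newick parse error: duplicate leaf label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  invisible(phy)
}

#' Write a tree as newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @param digits Number of significant digits for branch lengths.
#' @return The newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) == 1L) {
    out <- paste0(tree$tip.label, ";")
  } else {
    out <- ape::write.tree(tree, digits = digits)
  }
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Read a file of trees
#'
#' Reads a tree file into a `multiPhylo` list, preserving file order. The
#' newick dialect is one tree per line (blank lines ignored); the nexus
#' dialect is a `TREES` block, with `TRANSLATE` tables resolved to full
#' labels.
#'
#' @param path Path to the tree file.
#' @param format `"newick"` (default) or `"nexus"`.
#' @return A `multiPhylo` object in file order.
#' @examples
#' f <- tempfile(fileext = ".nwk")
#' writeLines(c("((A,B),(C,D));", "((A,C),D);"), f)
#' trees <- read_tree_file(f)
#' length(trees)
#' @export
read_tree_file <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "nexus") {
    trees <- tryCatch(ape::read.nexus(path),
                      error = function(e) stop("nexus parse error in '", path,
                                               "': ", conditionMessage(e)))
    if (inherits(trees, "phylo")) trees <- c(trees)
    if (length(trees) == 0L) stop("no trees found in nexus file: ", path)
    for (t in trees) validate_tree(t)
    class(trees) <- "multiPhylo"
    return(trees)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("empty tree file: ", path)
  trees <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    trees[[i]] <- tryCatch(read_newick(lines[keep[i]]),
                           error = function(e)
                             stop("line ", keep[i], " of '", path, "': ",
                                  conditionMessage(e)))
  }
  class(trees) <- "multiPhylo"
  trees
}

#' Leaf labels of a tree
#'
#' @param tree A `phylo` object.
#' @return Character vector of tip labels.
#' @export
leaf_labels <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree$tip.label
}

#' Union taxon set of a collection of trees
#'
#' @param trees A `multiPhylo` object or list of `phylo` trees.
#' @return Sorted character vector of the union of all leaf labels.
#' @export
union_taxa <- function(trees) {
  trees <- as_treelist(trees)
  sort(unique(unlist(lapply(trees, leaf_labels))))
}

as_treelist <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo"))  # uncompress shared tip labels
    trees <- lapply(seq_along(trees), function(i) trees[[i]])
  if (!length(trees)) stop("empty tree set")
  ok <- vapply(trees, inherits, logical(1), what = "phylo")
  if (!all(ok)) stop("all elements must be 'phylo' objects")
  trees
}

#' Prune a tree to a taxon subset
#'
#' Restricts a tree to `keep` (intersected with its leaves), suppressing all
#' resulting degree-2 internal nodes so that every split of the result is the
#' restriction of a split of the input.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of labels to retain.
#' @return A `phylo` on exactly `intersect(keep, leaf_labels(tree))`.
#' @examples
#' tr <- read_newick("((A,B),(C,(D,E)));")
#' write_newick(prune_to_taxa(tr, c("A", "B", "C", "D")))
#' @export
prune_to_taxa <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- intersect(leaf_labels(tree), keep)
  if (length(keep) == 0L)
    stop("no overlap between 'keep' and the tree's leaves")
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1L) return(single_tip_tree(keep))
  ape::keep.tip(tree, keep)
}

#' Remove the root of a tree
#'
#' Suppresses a degree-2 root by merging its two child edges; the unrooted
#' split set is unchanged. Already-unrooted trees are returned as is.
#'
#' @param tree A `phylo` with at least 3 leaves.
#' @return An unrooted `phylo`.
#' @export
deroot <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3L)
    stop("cannot deroot a tree with fewer than 3 leaves")
  ape::unroot(tree)
}

#' Reroot a tree on an outgroup
#'
#' Places the root on the edge separating `outgroup` from the remaining taxa.
#' The outgroup must correspond to one side of an edge of the unrooted tree
#' (a single leaf always qualifies); the unrooted split set is unchanged.
#'
#' @param tree A `phylo` object.
#' @param outgroup Character vector of leaf labels, a proper subset of the
#'   tree's leaves.
#' @return A rooted `phylo` whose root separates `outgroup` from the rest.
#' @export
reroot_on <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  labs <- leaf_labels(tree)
  bad <- setdiff(outgroup, labs)
  if (length(bad))
    stop("outgroup taxa not in tree: ", paste(bad, collapse = ", "))
  if (length(outgroup) == 0L) stop("empty outgroup")
  if (setequal(outgroup, labs))
    stop("outgroup cannot be the full leaf set")
  u <- if (length(labs) >= 3L) deroot(tree) else tree
  if (!is_edge_side(u, outgroup))
    stop("outgroup not monophyletic: {", paste(sort(outgroup), collapse = ","),
         "} is not a split of the unrooted tree")
  ape::root(u, outgroup = outgroup, resolve.root = TRUE)
}

# is 'side' one side of some edge of the (unrooted) tree?
is_edge_side <- function(tree, side) {
  labs <- leaf_labels(tree)
  k <- length(side)
  if (k == 1L || k == length(labs) - 1L) return(TRUE)  # trivial split
  ss <- tree_splits(tree)
  key <- canonical_split_key(side, labs)
  key %in% ss$keys
}
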