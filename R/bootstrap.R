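#' Bootstrap replicates of an input tree set
#'
#' Resamples the input trees (the resampling unit is the whole tree, not
#' characters): each replicate draws `length(inputs)` trees uniformly with
#' replacement from the input set. Deterministic given `seed`.
#'
#' @param inputs Input trees (`multiPhylo` or list of `phylo`).
#' @param n_reps Positive number of replicates.
#' @param seed Optional integer seed.
#' @return A list of `n_reps` `multiPhylo` objects, each of `length(inputs)`
#'   trees.
#' @export
bootstrap_replicates <- function(inputs, n_reps, seed = NULL) {
  inputs <- as_treelist(inputs)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps <= 0L) stop("'n_reps' must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- length(inputs)
  lapply(seq_len(n_reps), function(r) {
    idx <- sample.int(n, n, replace = TRUE)
    rep <- inputs[idx]
    class(rep) <- "multiPhylo"
    rep
  })
}

#' Split support across a collection of trees
#'
#' Counts, for every non-trivial split occurring in a collection of trees on
#' one shared leaf set, the percentage of trees containing it.
#'
#' @param trees A `multiPhylo` or list of `phylo` on identical leaf sets.
#' @return A data.frame with columns `key` (canonical split key), `side`
#'   (display form of the smaller side), `count` and `percent`, sorted by
#'   decreasing support.
#' @export
split_support <- function(trees) {
  trees <- as_treelist(trees)
  labs <- sort(leaf_labels(trees[[1]]))
  for (t in trees[-1]) {
    if (!setequal(leaf_labels(t), labs))
      stop("all trees must share one leaf set")
  }
  counts <- list()
  sides <- list()
  for (t in trees) {
    ss <- tree_splits(t)
    for (i in seq_along(ss$keys)) {
      k <- ss$keys[i]
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      sides[[k]] <- ss$sides[[i]]
    }
  }
  keys <- names(counts)
  cnt <- vapply(keys, function(k) counts[[k]], integer(1))
  disp <- vapply(keys, function(k) {
    side <- labs[sides[[k]]]
    other <- setdiff(labs, side)
    if (length(other) < length(side)) side <- other
    paste(sort(side), collapse = ",")
  }, "")
  df <- data.frame(key = keys, side = disp, count = cnt,
                   percent = round(100 * cnt / length(trees), 1),
                   row.names = NULL)
  df[order(-df$count, df$key), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Majority-rule consensus with split support
#'
#' Builds the consensus tree containing exactly the non-trivial splits that
#' occur in strictly more than `threshold` percent of the trees; at any
#' threshold of at least 50 the retained splits are pairwise compatible by
#' construction. Per-split support percentages are attached as internal node
#' labels.
#'
#' @param trees A `multiPhylo` or list of `phylo` on identical leaf sets.
#' @param threshold Percentage cutoff (default 50); splits are kept when
#'   support is strictly greater.
#' @return An object of class `support_tree`: list with `tree` (a `phylo`
#'   whose internal node labels carry support percentages), `support`
#'   (the full [split_support()] table), `n_trees` and `threshold`.
#' @examples
#' trees <- c(read_newick("((A,B),(C,D));"), read_newick("((A,B),(C,D));"),
#'            read_newick("((A,C),(B,D));"))
#' majority_rule_consensus(trees)
#' @export
majority_rule_consensus <- function(trees, threshold = 50) {
  trees <- as_treelist(trees)
  if (threshold < 50)
    warning("thresholds below 50 can retain incompatible splits")
  supp <- split_support(trees)
  keep <- supp[supp$percent > threshold, , drop = FALSE]
  labs <- sort(leaf_labels(trees[[1]]))
  sides <- lapply(keep$key, function(k)
    as.integer(strsplit(k, ",", fixed = TRUE)[[1]]))
  tree <- build_tree_from_splits(labs, sides,
                                 clade_labels = format_support(keep$percent))
  structure(list(tree = tree, support = supp, n_trees = length(trees),
                 threshold = threshold),
            class = "support_tree")
}

format_support <- function(p) {
  ifelse(p == round(p), sprintf("%d", as.integer(round(p))),
         sprintf("%.1f", p))
}

#' @export
print.support_tree <- function(x, ...) {
  cat("Consensus/support tree over", x$n_trees, "trees (threshold >",
      x$threshold, "%)\n")
  cat("  ", write_newick(x$tree), "\n")
  shown <- x$support[x$support$percent > x$threshold, , drop = FALSE]
  if (nrow(shown)) print(shown, row.names = FALSE)
  invisible(x)
}

#' Bootstrap support analysis for the ML supertree
#'
#' The full support-estimation protocol: draw bootstrap replicates of the
#' input tree set, run the heuristic ML search on each replicate, summarise
#' the replicate-optimal supertrees by majority-rule consensus, and annotate
#' the ML supertree found on the original inputs with the percentage of
#' replicate optima containing each of its splits. Replicate searches reuse
#' `config` with derived seeds (`seed + replicate index`) and are carried
#' out over the original union taxon set, so all replicate optima share one
#' leaf set.
#'
#' @param inputs Input trees (`multiPhylo` or list of `phylo`).
#' @param model An [sr_model()].
#' @param config A [search_config()] used for the main and replicate
#'   searches.
#' @param n_reps Number of bootstrap replicates (default 20).
#' @param seed Integer seed governing resampling and replicate searches
#'   (default: `config$seed`, or drawn if both are `NULL`).
#' @param threshold Consensus threshold percentage (default 50).
#' @return A list with `consensus` (a `support_tree` summarising the
#'   replicate optima), `ml` (a `support_tree`: the original-data ML tree
#'   annotated with replicate support), `ml_result` (the original-data
#'   [run_search()] result), `replicate_best` (`multiPhylo` of replicate
#'   optima) and `seed_used`.
#' @export
bootstrap_support_analysis <- function(inputs, model = sr_model(),
                                       config = search_config(),
                                       n_reps = 20, seed = NULL,
                                       threshold = 50) {
  inputs <- as_treelist(inputs)
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  taxa <- union_taxa(inputs)
  reps <- bootstrap_replicates(inputs, n_reps, seed = seed)
  rep_best <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- seed + r
    res <- run_search(reps[[r]], model, cfg, taxa = taxa)
    rep_best[[r]] <- res$best_tree
  }
  class(rep_best) <- "multiPhylo"
  consensus <- majority_rule_consensus(rep_best, threshold = threshold)

  cfg <- config
  if (is.null(cfg$seed)) cfg$seed <- seed
  ml_result <- run_search(inputs, model, cfg, taxa = taxa)
  ml <- annotate_with_support(ml_result$best_tree, rep_best)

  list(consensus = consensus, ml = ml, ml_result = ml_result,
       replicate_best = rep_best, seed_used = seed)
}

# annotate a tree's splits with the percentage of 'pool' trees containing
# each of them
annotate_with_support <- function(tree, pool) {
  pool <- as_treelist(pool)
  supp <- split_support(pool)
  ss <- tree_splits(tree)
  pct <- vapply(ss$keys, function(k) {
    hit <- supp$percent[supp$key == k]
    if (length(hit)) hit else 0
  }, 0)
  annotated <- build_tree_from_splits(ss$labels, ss$sides,
                                      clade_labels = format_support(pct))
  structure(list(tree = annotated,
                 support = data.frame(key = ss$keys, percent = pct,
                                      row.names = NULL),
                 n_trees = length(pool), threshold = NA_real_),
            class = "support_tree")
}
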