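#' Search configuration
#'
#' Settings for the heuristic supertree search. The defaults (strategy 4,
#' ten iterations, one start) correspond to the fastest search mode.
#'
#' @param strategy Integer in 1..4 selecting the hill-climbing strategy
#'   (see [run_search()]).
#' @param max_iterations Maximum number of iterations (default 10).
#' @param n_restarts Number of independent stepwise-addition starts
#'   (default 1); the best result over restarts is returned.
#' @param seed Integer seed for all randomness in the search; if `NULL` a
#'   seed is drawn and recorded in the result.
#' @param start_tree Optional starting supertree (`phylo`); must span the
#'   full taxon set. Polytomies are resolved randomly (with a warning).
#' @return An object of class `search_config`.
#' @export
search_config <- function(strategy = 4, max_iterations = 10, n_restarts = 1,
                          seed = NULL, start_tree = NULL) {
  strategy <- as.integer(strategy)
  if (!(strategy %in% 1:4)) stop("'strategy' must be 1, 2, 3 or 4")
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 1L) stop("'max_iterations' must be positive")
  n_restarts <- as.integer(n_restarts)
  if (n_restarts < 1L) stop("'n_restarts' must be positive")
  if (!is.null(start_tree) && !inherits(start_tree, "phylo"))
    stop("'start_tree' must be a 'phylo' object")
  structure(list(strategy = strategy, max_iterations = max_iterations,
                 n_restarts = n_restarts, seed = seed,
                 start_tree = start_tree),
            class = "search_config")
}

#' Stepwise-addition starting supertree
#'
#' Builds a random starting supertree by stepwise addition: the taxon order
#' is shuffled, the first three taxa form the unique unrooted 3-leaf tree,
#' and each subsequent taxon is attached to the edge that maximises the
#' likelihood score against the input trees (restricted to the taxa placed
#' so far); ties are broken at random. Deterministic given `seed`.
#'
#' @param taxa Character vector of at least 3 taxon labels.
#' @param inputs Input trees (`multiPhylo` or list of `phylo`).
#' @param model An [sr_model()].
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return A binary unrooted `phylo` on exactly `taxa`.
#' @export
stepwise_addition_start <- function(taxa, inputs, model = sr_model(),
                                    seed = NULL) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) < 3L) stop("need at least 3 taxa for stepwise addition")
  if (!is.null(seed)) set.seed(seed)
  scorer <- make_scorer(inputs, model, taxa = sort(union(taxa,
                                                         union_taxa(inputs))),
                        warn_small = FALSE)
  tg <- stepwise_addition_tg(taxa, scorer)
  tg_to_phylo(tg)
}

# internal: stepwise addition on the tg representation, using the caller's
# RNG stream
stepwise_addition_tg <- function(taxa, scorer) {
  ord <- sample(taxa)
  bm <- scorer$bm
  # seed tree: star on first three taxa (nodes 1..3 leaves, 4 internal)
  tg <- list(adj = list(4L, 4L, 4L, c(1L, 2L, 3L)),
             labels = c(ord[1:3], NA))
  for (t in ord[-(1:3)]) {
    # attach leaf 't' on each edge; pick the best-scoring placement
    edges <- list()
    for (x in seq_along(tg$adj)) {
      for (y in tg$adj[[x]]) if (y > x) edges[[length(edges) + 1L]] <- c(x, y)
    }
    nleaf <- length(tg$adj) + 1L
    nnode <- length(tg$adj) + 2L
    cands <- vector("list", length(edges))
    scores <- numeric(length(edges))
    present <- NULL
    for (k in seq_along(edges)) {
      x <- edges[[k]][1]; y <- edges[[k]][2]
      adj2 <- tg$adj
      adj2[[x]][adj2[[x]] == y] <- nnode
      adj2[[y]][adj2[[y]] == x] <- nnode
      adj2[[nleaf]] <- nnode
      adj2[[nnode]] <- c(x, y, nleaf)
      cand <- list(adj = adj2, labels = c(tg$labels, t, NA))
      sm <- tg_split_masks(cand, bm)
      if (is.null(present)) present <- sm$present
      cands[[k]] <- cand
      scores[k] <- scorer$total_partial(sm$masks, sm$present)
    }
    best <- which(scores == max(scores))
    pick <- if (length(best) > 1L) sample(best, 1L) else best
    tg <- cands[[pick]]
  }
  tg
}

#' SPR neighborhood of a binary unrooted tree
#'
#' Enumerates every distinct topology obtainable by one subtree prune and
#' regraft move: each edge defines a candidate subtree, which is detached
#' (the resulting degree-2 node suppressed) and reattached onto every other
#' edge of the remaining tree. The original topology and duplicate
#' rearrangements are removed.
#'
#' @param tree A binary `phylo` with at least 4 leaves (a rooted tree is
#'   derooted first).
#' @return A `multiPhylo` of distinct neighbor topologies, all on the same
#'   leaf set.
#' @examples
#' length(spr_neighbors(read_newick("((A,B),(C,D));")))  # the 2 other quartets
#' @export
spr_neighbors <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 4L) stop("need at least 4 leaves")
  u <- deroot(tree)
  if (!ape::is.binary(u)) stop("SPR neighborhoods are defined for binary trees")
  bm <- make_bitmap(leaf_labels(u))
  nb <- tg_spr_neighborhood(phylo_to_tg(u), bm)
  out <- lapply(nb, function(x) tg_to_phylo(x$tg))
  class(out) <- "multiPhylo"
  out
}

#' Heuristic maximum-likelihood supertree search
#'
#' Hill-climbs from a starting supertree (user-supplied or built by
#' [stepwise_addition_start()]) through SPR rearrangements, keeping the
#' candidate of highest total log-likelihood. Four strategies are available,
#' trading exhaustiveness for speed:
#' \describe{
#'   \item{1 — steepest ascent}{score the full SPR neighborhood each
#'     iteration and move to the best strictly improving neighbor;}
#'   \item{2 — first improvement}{scan the neighborhood in random order and
#'     accept the first strictly better neighbor;}
#'   \item{3 — radius-limited steepest ascent}{as strategy 1, but regraft
#'     destinations are confined to within 3 edges of the pruning point;}
#'   \item{4 — greedy subtree sweep}{a single pass over the subtrees in
#'     random order, each immediately regrafted to its best destination when
#'     strictly improving (the fastest, least exhaustive mode).}
#' }
#' An iteration is one full neighborhood pass (strategies 1-3) or one sweep
#' (strategy 4); the search stops at `max_iterations` or when an iteration
#' yields no improvement. Acceptance is strictly improving, so the score
#' trajectory is non-decreasing and the search always terminates. With
#' `n_restarts > 1` the whole procedure is repeated from fresh
#' stepwise-addition starts and the best result is returned.
#'
#' @param inputs Input trees (`multiPhylo` or list of `phylo`).
#' @param model An [sr_model()].
#' @param config A [search_config()].
#' @param taxa Optional taxon set the supertree must span (default: the
#'   union of the input trees' taxa; must be a superset of it).
#' @return An object of class `search_result`: list with `best_tree`,
#'   `best_score` (a `score_breakdown`), `trajectory` (data.frame of
#'   iteration and total log-likelihood for the best restart),
#'   `n_trees_evaluated`, `seed_used` and `config`.
#' @export
run_search <- function(inputs, model = sr_model(), config = search_config(),
                       taxa = NULL) {
  stopifnot(inherits(model, "sr_model"), inherits(config, "search_config"))
  inputs <- as_treelist(inputs)
  u <- union_taxa(inputs)
  if (is.null(taxa)) taxa <- u
  taxa <- sort(unique(as.character(taxa)))
  if (length(setdiff(u, taxa)))
    stop("'taxa' must contain every input-tree taxon")
  seed <- config$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  scorer <- make_scorer(inputs, model, taxa = taxa, warn_small = FALSE)
  n_eval <- 0L

  start_tg <- NULL
  if (!is.null(config$start_tree)) {
    st <- config$start_tree
    missing <- setdiff(taxa, leaf_labels(st))
    if (length(missing))
      stop("start tree lacks taxa: ", paste(missing, collapse = ", "))
    extra <- setdiff(leaf_labels(st), taxa)
    if (length(extra)) st <- prune_to_taxa(st, taxa)
    if (!ape::is.binary(ape::unroot(st))) {
      warning("start tree has polytomies; resolving randomly")
      st <- ape::multi2di(st, random = TRUE)
    }
    start_tg <- phylo_to_tg(deroot(st))
  }

  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    tg <- if (r == 1L && !is.null(start_tg)) start_tg
          else stepwise_addition_tg(taxa, scorer)
    res <- climb(tg, scorer, config)
    n_eval <- n_eval + res$n_eval
    if (is.null(best) || res$total > best$total) best <- res
  }

  best_tree <- tg_to_phylo(best$tg)
  structure(list(best_tree = best_tree,
                 best_score = suppressWarnings(
                   score_supertree(best_tree, inputs, model)),
                 trajectory = best$trajectory,
                 n_trees_evaluated = n_eval,
                 seed_used = seed,
                 config = config),
            class = "search_result")
}

# one hill-climb from a starting tg
climb <- function(tg, scorer, config) {
  bm <- scorer$bm
  cur_masks <- tg_split_masks(tg, bm)
  cur_total <- scorer$total(cur_masks$masks)
  n_eval <- 1L
  traj_it <- 0L
  traj_tot <- cur_total
  max_dist <- if (config$strategy == 3L) 3L else Inf

  for (it in seq_len(config$max_iterations)) {
    improved <- FALSE
    if (config$strategy %in% c(1L, 2L, 3L)) {
      nb <- tg_spr_neighborhood(tg, bm, max_dist = max_dist)
      if (length(nb) == 0L) break
      if (config$strategy == 2L) nb <- nb[sample.int(length(nb))]
      if (config$strategy == 2L) {
        for (cand in nb) {
          tot <- scorer$total(cand$masks$masks)
          n_eval <- n_eval + 1L
          if (tot > cur_total) {
            tg <- cand$tg; cur_total <- tot; improved <- TRUE
            break
          }
        }
      } else {
        tots <- vapply(nb, function(cand) scorer$total(cand$masks$masks), 0)
        n_eval <- n_eval + length(nb)
        best <- which(tots == max(tots))
        if (max(tots) > cur_total) {
          pick <- if (length(best) > 1L) sample(best, 1L) else best
          tg <- nb[[pick]]$tg
          cur_total <- max(tots)
          improved <- TRUE
        }
      }
    } else {
      # strategy 4: greedy sweep over subtrees in random order
      subs <- sweep_subtrees(tg)
      subs <- subs[sample.int(length(subs))]
      for (sig in subs) {
        mv <- find_subtree_edge(tg, sig)
        if (is.null(mv)) next
        cands <- tg_spr_regrafts(tg, mv[1], mv[2])
        if (length(cands) == 0L) next
        cur_sig <- tg_split_masks(tg, bm)$sig
        tots <- numeric(0)
        keep <- list()
        for (cand in cands) {
          sm <- tg_split_masks(cand$tg, bm)
          if (sm$sig == cur_sig) next
          tots <- c(tots, scorer$total(sm$masks))
          keep[[length(keep) + 1L]] <- cand$tg
          n_eval <- n_eval + 1L
        }
        if (length(tots) && max(tots) > cur_total) {
          best <- which(tots == max(tots))
          pick <- if (length(best) > 1L) sample(best, 1L) else best
          tg <- keep[[pick]]
          cur_total <- max(tots)
          improved <- TRUE
        }
      }
    }
    traj_it <- c(traj_it, it)
    traj_tot <- c(traj_tot, cur_total)
    if (!improved) break
  }
  list(tg = tg, total = cur_total, n_eval = n_eval,
       trajectory = data.frame(iteration = traj_it,
                               total_log_likelihood = traj_tot))
}

# stable identities for the subtrees of a sweep: the sorted leaf sets
# hanging off each directed edge at sweep start
sweep_subtrees <- function(tg) {
  sigs <- character(0)
  for (e in tg_directed_edges(tg)) {
    if (length(tg$adj[[e[1]]]) != 3L) next
    sigs <- c(sigs, paste(sort(tg_component_leaves(tg, e[1], e[2])),
                          collapse = ","))
  }
  unique(sigs)
}

# directed edge of the current tree whose pruned side carries exactly the
# given leaf set, or NULL if the subtree no longer exists
find_subtree_edge <- function(tg, sig) {
  for (e in tg_directed_edges(tg)) {
    if (length(tg$adj[[e[1]]]) != 3L) next
    s <- paste(sort(tg_component_leaves(tg, e[1], e[2])), collapse = ",")
    if (s == sig) return(e)
  }
  NULL
}

#' @export
print.search_result <- function(x, ...) {
  cat("ML supertree search (strategy", x$config$strategy, ", seed",
      x$seed_used, ")\n")
  cat("  best total log-likelihood:", format(x$best_score$total_log_likelihood),
      "\n")
  cat("  trees evaluated:", x$n_trees_evaluated, "\n")
  cat("  iterations used:", max(x$trajectory$iteration), "\n")
  cat("  best tree:", write_newick(x$best_tree), "\n")
  invisible(x)
}

#' Exhaustive maximum-likelihood supertree (small taxon sets)
#'
#' Enumerates every binary unrooted topology on the union taxon set (there
#' are `(2n-5)!!` of them), scores each against the input trees, and returns
#' a global optimum. Intended as an exact reference for small problems; for
#' more than 8 taxa use [run_search()].
#'
#' @param inputs Input trees (`multiPhylo` or list of `phylo`).
#' @param model An [sr_model()].
#' @return A list with `best_tree`, `best_score` (a `score_breakdown`),
#'   `co_optima` (a `multiPhylo` of all topologies attaining the optimum, in
#'   enumeration order) and `n_topologies`.
#' @export
exhaustive_ml_supertree <- function(inputs, model = sr_model()) {
  inputs <- as_treelist(inputs)
  labs <- union_taxa(inputs)
  n <- length(labs)
  if (n < 4L) stop("need at least 4 taxa")
  if (n > 8L)
    stop("exhaustive enumeration is limited to 8 taxa (",
         "use run_search() for larger problems)")
  all_trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  scorer <- make_scorer(inputs, model, warn_small = FALSE)
  tots <- vapply(all_trees, function(t)
    scorer$total(phylo_split_masks(t, scorer$bm)$masks), 0)
  best <- which(tots == max(tots))
  co <- all_trees[best]
  class(co) <- "multiPhylo"
  best_tree <- all_trees[[best[1]]]
  list(best_tree = best_tree,
       best_score = suppressWarnings(score_supertree(best_tree, inputs, model)),
       co_optima = co,
       n_topologies = length(all_trees))
}
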