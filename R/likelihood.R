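#' Exponential supertree likelihood model
#'
#' Parameters of the exponential model of topological error: the probability
#' of observing input tree `T'` given supertree `T` restricted to the input
#' tree's taxa is `alpha * exp(-beta * d)`, where `d` is the Robinson-Foulds
#' distance between the input tree and the pruned supertree. `alpha` is a
#' normalising constant and `beta` weights the quantity/quality of the data
#' behind the input trees. The defaults `alpha = 1, beta = 1` follow the
#' small-beta approximation of Bryant and Steel under which the per-tree
#' normalising constants reduce to one irrespective of input-tree size;
#' changing `alpha` shifts every total log-likelihood by a constant and can
#' never change the ranking of candidate supertrees.
#'
#' @param alpha Positive normalising constant (default 1).
#' @param beta Positive error-rate weight (default 1).
#' @return An object of class `sr_model`.
#' @examples
#' sr_model()
#' @export
sr_model <- function(alpha = 1, beta = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a positive number")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a positive number")
  structure(list(alpha = alpha, beta = beta), class = "sr_model")
}

#' @export
print.sr_model <- function(x, ...) {
  cat("Exponential supertree likelihood model: alpha =", x$alpha,
      ", beta =", x$beta, "\n")
  invisible(x)
}

#' Log-likelihood of one input tree given a supertree
#'
#' Prunes the supertree to the input tree's taxa and returns
#' `ln(alpha) - beta * d`, where `d` is the Robinson-Foulds distance between
#' the pruned supertree and the input tree. Under the default model this is
#' exactly `-d`.
#'
#' @param supertree A `phylo` whose leaves cover the input tree's taxa.
#' @param input_tree A `phylo`.
#' @param model An [sr_model()].
#' @return A single numeric log-likelihood.
#' @examples
#' st <- read_newick("((A,B),(C,(D,E)));")
#' tree_wise_log_likelihood(st, read_newick("((A,C),(B,D));"))
#' @export
tree_wise_log_likelihood <- function(supertree, input_tree, model = sr_model()) {
  stopifnot(inherits(model, "sr_model"))
  orphans <- setdiff(leaf_labels(input_tree), leaf_labels(supertree))
  if (length(orphans))
    stop("input tree contains taxa absent from the supertree: ",
         paste(sort(orphans), collapse = ", "))
  labs <- leaf_labels(input_tree)
  if (length(labs) < 4L)
    warning("input tree has fewer than 4 taxa; it carries no informative ",
            "splits and contributes ln(alpha) to the score")
  pruned <- prune_to_taxa(supertree, labs)
  d <- robinson_foulds(pruned, input_tree)
  log(model$alpha) - model$beta * d
}

# ---- internal scorer -------------------------------------------------------

# Precomputes, for an input tree set, everything needed to score candidate
# supertrees repeatedly: a bit assignment over 'taxa' (a superset of the
# union taxon set), each input tree's taxon mask and canonical split masks.
# score_masks() then evaluates a candidate from its own split masks by
# restricting them to each input tree's taxa.
make_scorer <- function(inputs, model = sr_model(), taxa = NULL,
                        warn_small = TRUE) {
  inputs <- as_treelist(inputs)
  u <- union_taxa(inputs)
  if (is.null(taxa)) taxa <- u
  missing <- setdiff(u, taxa)
  if (length(missing))
    stop("scoring taxon set lacks input-tree taxa: ",
         paste(missing, collapse = ", "))
  bm <- make_bitmap(taxa)
  n_in <- length(inputs)
  tmask <- vector("list", n_in)    # taxon mask per input tree
  skeys <- vector("list", n_in)    # canonical split keys within tmask
  sraw <- vector("list", n_in)     # raw split masks (for re-restriction)
  ovl <- integer(n_in)
  for (i in seq_len(n_in)) {
    sm <- phylo_split_masks(inputs[[i]], bm)
    tmask[[i]] <- leaf_mask(bm, leaf_labels(inputs[[i]]))
    sraw[[i]] <- sm$masks
    skeys[[i]] <- vapply(sm$masks, mask_key, "")
    ovl[i] <- length(inputs[[i]]$tip.label)
  }
  if (warn_small && any(ovl < 4L))
    warning("input tree(s) ", paste(which(ovl < 4L), collapse = ", "),
            " have fewer than 4 taxa and contribute no informative splits")
  scorer <- list(bm = bm, n_inputs = n_in, model = model, tmask = tmask,
                 skeys = skeys, sraw = sraw, overlap = ovl,
                 union_mask = leaf_mask(bm, u))

  # distances of a candidate (given its canonical split masks over bm) to
  # every input tree; the candidate must span all input taxa
  scorer$distances <- function(cand_masks) {
    d <- integer(n_in)
    for (i in seq_len(n_in)) {
      M <- tmask[[i]]
      tot <- ovl[i]
      keys_in <- skeys[[i]]
      seen <- character(0)
      for (m in cand_masks) {
        r <- bitwAnd(m, M)
        p <- sum(popcount32(r))
        if (p < 2L || tot - p < 2L) next
        k <- mask_key(mask_canonical(r, M))
        if (k %in% seen) next
        seen <- c(seen, k)
      }
      d[i] <- length(keys_in) + length(seen) -
        2L * length(intersect(keys_in, seen))
    }
    d
  }

  scorer$total <- function(cand_masks) {
    d <- scorer$distances(cand_masks)
    n_in * log(model$alpha) - model$beta * sum(d)
  }

  # partial scoring against inputs restricted to the candidate's own taxa
  # (used during stepwise addition, where the candidate spans a subset)
  scorer$total_partial <- function(cand_masks, present) {
    tot <- 0
    for (i in seq_len(n_in)) {
      S <- bitwAnd(tmask[[i]], present)
      ns <- sum(popcount32(S))
      if (ns < 4L) next
      restrict <- function(masks) {
        seen <- character(0)
        for (m in masks) {
          r <- bitwAnd(m, S)
          p <- sum(popcount32(r))
          if (p < 2L || ns - p < 2L) next
          k <- mask_key(mask_canonical(r, S))
          if (!(k %in% seen)) seen <- c(seen, k)
        }
        seen
      }
      a <- restrict(sraw[[i]])
      b <- restrict(cand_masks)
      d <- length(a) + length(b) - 2L * length(intersect(a, b))
      tot <- tot - model$beta * d
    }
    tot + n_in * log(model$alpha)
  }
  scorer
}

#' Score a candidate supertree against a set of input trees
#'
#' Computes, for each input tree, the Robinson-Foulds distance between the
#' input tree and the supertree pruned to that tree's taxa, together with the
#' corresponding log-likelihood `ln(alpha) - beta * d`; the supertree's total
#' log-likelihood is the sum over input trees. Under the default model the
#' total is exactly minus the sum of the distances.
#'
#' @param supertree A `phylo` spanning (at least) the union of the input
#'   trees' taxa.
#' @param inputs A `multiPhylo` or list of `phylo` input trees.
#' @param model An [sr_model()].
#' @return An object of class `score_breakdown`: list with `per_tree` (a
#'   data.frame with columns `tree`, `overlap`, `rf`, `log_likelihood`, in
#'   input order) and `total_log_likelihood`.
#' @examples
#' st <- read_newick("((A,B),(C,(D,E)));")
#' inputs <- c(read_newick("((A,B),(C,D));"), read_newick("((A,C),(D,E));"))
#' score_supertree(st, inputs)
#' @export
score_supertree <- function(supertree, inputs, model = sr_model()) {
  stopifnot(inherits(supertree, "phylo"), inherits(model, "sr_model"))
  inputs <- as_treelist(inputs)
  u <- union_taxa(inputs)
  missing <- setdiff(u, leaf_labels(supertree))
  if (length(missing)) {
    offender <- which(vapply(inputs, function(t)
      any(missing %in% leaf_labels(t)), logical(1)))[1]
    stop("supertree lacks input taxa ", paste(missing, collapse = ", "),
         " (first offending input tree: index ", offender, ")")
  }
  scorer <- make_scorer(inputs, model, taxa = sort(leaf_labels(supertree)))
  masks <- phylo_split_masks(supertree, scorer$bm)$masks
  d <- scorer$distances(masks)
  ll <- log(model$alpha) - model$beta * d
  per <- data.frame(tree = seq_along(inputs), overlap = scorer$overlap,
                    rf = d, log_likelihood = ll)
  structure(list(per_tree = per, total_log_likelihood = sum(ll),
                 model = model),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat("Supertree score over", nrow(x$per_tree), "input trees\n")
  cat("  total log-likelihood:", format(x$total_log_likelihood), "\n")
  cat("  total RF distance:   ", sum(x$per_tree$rf), "\n")
  if (nrow(x$per_tree) <= 20L) print(x$per_tree, row.names = FALSE)
  invisible(x)
}
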