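#' Specification for synthetic input-tree generation
#'
#' Describes a simulated supertree study: a known true supertree, a number
#' of input trees to sample, the taxon-subset sizes of the input trees, and
#' a distortion rate. Each input tree is the true supertree restricted to a
#' random taxon subset, then perturbed by a Poisson-distributed number of
#' random NNI rearrangements — matching the exponential error model under
#' which the probability of an input tree decays with its distance from the
#' restricted truth. `distortion_rate = 0` gives the conflict-free regime in
#' which the true supertree scores 0.
#'
#' @param true_supertree A binary `phylo`, the generating supertree.
#' @param n_trees Number of input trees to generate.
#' @param subset_size Length-2 integer vector `(min, max)` of taxa per input
#'   tree; `min >= 4` and `max <=` the number of leaves of the truth.
#' @param distortion_rate Non-negative expected number of NNI edits per
#'   input tree.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(true_supertree, n_trees = 100,
                           subset_size = c(4, 7), distortion_rate = 0,
                           seed = 1) {
  stopifnot(inherits(true_supertree, "phylo"))
  if (!ape::is.binary(ape::unroot(true_supertree)))
    stop("the true supertree must be binary")
  subset_size <- as.integer(subset_size)
  if (length(subset_size) != 2L || subset_size[1] < 4L)
    stop("'subset_size' must be (min, max) with min >= 4")
  n_leaves <- length(true_supertree$tip.label)
  if (subset_size[2] > n_leaves)
    stop("'subset_size' max exceeds the number of taxa in the truth")
  if (subset_size[1] > subset_size[2]) stop("subset_size min > max")
  if (distortion_rate < 0) stop("'distortion_rate' must be non-negative")
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) stop("'n_trees' must be positive")
  structure(list(true_supertree = ape::unroot(true_supertree),
                 n_trees = n_trees, subset_size = subset_size,
                 distortion_rate = distortion_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate synthetic input trees from a known supertree
#'
#' Draws input trees per [synthetic_spec()]: a uniform random taxon subset
#' of the specified size, the truth restricted to it, and `k ~
#' Poisson(distortion_rate)` random NNI rearrangements. The realized
#' Robinson-Foulds distance of every input tree to the restricted truth is
#' recorded. Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `trees` (`multiPhylo`, in generation order), `truth`
#'   (data.frame with columns `tree`, `size`, `k_nni`, `rf_to_truth`),
#'   `true_supertree` and `spec`.
#' @examples
#' truth <- random_supertree(letters[1:7], seed = 1)
#' sim <- generate_input_trees(synthetic_spec(truth, n_trees = 10, seed = 1))
#' sim$truth
#' @export
generate_input_trees <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  truth <- spec$true_supertree
  labs <- leaf_labels(truth)
  sizes <- integer(spec$n_trees)
  ks <- integer(spec$n_trees)
  rfs <- integer(spec$n_trees)
  trees <- vector("list", spec$n_trees)
  for (i in seq_len(spec$n_trees)) {
    sz <- if (spec$subset_size[1] == spec$subset_size[2]) spec$subset_size[1]
          else sample(spec$subset_size[1]:spec$subset_size[2], 1L)
    taxa <- sample(labs, sz)
    restricted <- ape::unroot(prune_to_taxa(truth, taxa))
    k <- stats::rpois(1L, spec$distortion_rate)
    distorted <- restricted
    if (k > 0L) distorted <- phangorn::rNNI(restricted, moves = k)
    sizes[i] <- sz
    ks[i] <- k
    rfs[i] <- robinson_foulds(distorted, restricted)
    trees[[i]] <- distorted
  }
  class(trees) <- "multiPhylo"
  list(trees = trees,
       truth = data.frame(tree = seq_len(spec$n_trees), size = sizes,
                          k_nni = ks, rf_to_truth = rfs),
       true_supertree = truth, spec = spec)
}

#' Random binary unrooted supertree
#'
#' Draws a uniform random binary unrooted topology on the given labels.
#'
#' @param labels Character vector of taxon labels (at least 4).
#' @param seed Optional integer seed.
#' @return A binary unrooted `phylo`.
#' @export
random_supertree <- function(labels, seed = NULL) {
  labels <- unique(as.character(labels))
  if (length(labels) < 4L) stop("need at least 4 labels")
  if (!is.null(seed)) set.seed(seed)
  t <- ape::unroot(ape::rtopology(length(labels), rooted = FALSE,
                                  tip.label = labels))
  t$edge.length <- NULL
  t
}
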