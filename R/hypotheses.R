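#' Score a set of supertree hypotheses
#'
#' Scores each a-priori hypothesis supertree against the same input tree set
#' and model, keeping names, trees and score breakdowns index-aligned.
#'
#' @param trees Hypothesis supertrees (`multiPhylo` or list of `phylo`),
#'   each spanning at least the union of the input trees' taxa.
#' @param inputs Input trees.
#' @param model An [sr_model()].
#' @param names Optional character vector of hypothesis names (default:
#'   names of `trees`, or `H1`, `H2`, ...).
#' @return An object of class `hypothesis_set`: list with `names`, `trees`,
#'   `scores` (list of `score_breakdown`) and `totals`.
#' @export
score_hypotheses <- function(trees, inputs, model = sr_model(), names = NULL) {
  trees <- as_treelist(trees)
  if (is.null(names)) names <- base::names(trees)
  if (is.null(names)) names <- paste0("H", seq_along(trees))
  if (length(names) != length(trees))
    stop("'names' must match the number of hypothesis trees")
  scores <- lapply(trees, function(t)
    suppressWarnings(score_supertree(t, inputs, model)))
  structure(list(names = as.character(names), trees = trees, scores = scores,
                 totals = vapply(scores, `[[`, 0, "total_log_likelihood"),
                 model = model, n_inputs = length(as_treelist(inputs))),
            class = "hypothesis_set")
}

#' @export
print.hypothesis_set <- function(x, ...) {
  cat("Hypothesis set:", length(x$trees), "supertrees scored against",
      x$n_inputs, "input trees\n")
  print(rank_hypotheses(x), row.names = FALSE)
  invisible(x)
}

#' Rank scored hypotheses by likelihood
#'
#' Sorts hypotheses by total log-likelihood, best first. Tied hypotheses
#' share the smaller rank and are flagged.
#'
#' @param hyps A `hypothesis_set` from [score_hypotheses()].
#' @return A data.frame with columns `name`, `total_log_likelihood`, `rank`
#'   and `tied`, ordered by rank.
#' @export
rank_hypotheses <- function(hyps) {
  stopifnot(inherits(hyps, "hypothesis_set"))
  tot <- hyps$totals
  rk <- rank(-tot, ties.method = "min")
  tied <- duplicated(tot) | duplicated(tot, fromLast = TRUE)
  out <- data.frame(name = hyps$names, total_log_likelihood = tot,
                    rank = as.integer(rk), tied = tied, row.names = NULL)
  out[order(out$rank, out$name), , drop = FALSE]
}

#' Winning-sites test between two supertree hypotheses
#'
#' A sign test on the input trees: each input tree is a "site" won by the
#' hypothesis with the strictly higher tree-wise log-likelihood (under the
#' default model, the smaller Robinson-Foulds distance), or tied. The
#' p-value is the exact two-sided binomial probability of a win split at
#' least as extreme under `Binomial(wins_a + wins_b, 1/2)`; ties are
#' excluded from the trial count, and the all-ties case returns `p = 1` by
#' convention.
#'
#' @param hyp_a,hyp_b Hypothesis supertrees (`phylo`), each spanning the
#'   union of the input trees' taxa.
#' @param inputs Input trees.
#' @param model An [sr_model()].
#' @return An object of class `winning_sites`: list with `wins_a`, `wins_b`,
#'   `ties`, `n_informative` and `p_value`.
#' @export
winning_sites_test <- function(hyp_a, hyp_b, inputs, model = sr_model()) {
  sa <- suppressWarnings(score_supertree(hyp_a, inputs, model))
  sb <- suppressWarnings(score_supertree(hyp_b, inputs, model))
  la <- sa$per_tree$log_likelihood
  lb <- sb$per_tree$log_likelihood
  wins_a <- sum(la > lb)
  wins_b <- sum(lb > la)
  ties <- sum(la == lb)
  n <- wins_a + wins_b
  p <- if (n == 0L) 1 else stats::binom.test(wins_a, n, p = 0.5)$p.value
  structure(list(wins_a = wins_a, wins_b = wins_b, ties = ties,
                 n_informative = n, p_value = min(1, p)),
            class = "winning_sites")
}

#' @export
print.winning_sites <- function(x, ...) {
  cat("Winning-sites test: ", x$wins_a, " wins vs ", x$wins_b,
      " (", x$ties, " ties)\n", sep = "")
  cat("  exact two-sided binomial p =", format(x$p_value), "\n")
  invisible(x)
}

#' Winning-sites tests of all hypotheses against the best one
#'
#' Convenience wrapper running [winning_sites_test()] of every hypothesis
#' against the rank-1 hypothesis of the set.
#'
#' @param hyps A `hypothesis_set`.
#' @param inputs Input trees.
#' @param model An [sr_model()].
#' @return A data.frame with one row per non-reference hypothesis: `name`,
#'   `reference`, `wins`, `losses`, `ties`, `p_value`.
#' @export
winning_sites_vs_best <- function(hyps, inputs, model = sr_model()) {
  stopifnot(inherits(hyps, "hypothesis_set"))
  ranking <- rank_hypotheses(hyps)
  ref_name <- ranking$name[1]
  ref <- hyps$trees[[match(ref_name, hyps$names)]]
  others <- setdiff(hyps$names, ref_name)
  rows <- lapply(others, function(nm) {
    ws <- winning_sites_test(hyps$trees[[match(nm, hyps$names)]], ref,
                             inputs, model)
    data.frame(name = nm, reference = ref_name, wins = ws$wins_a,
               losses = ws$wins_b, ties = ws$ties, p_value = ws$p_value)
  })
  do.call(rbind, rows)
}

#' Export input-tree-wise log-likelihoods for CONSEL
#'
#' Writes the CONSEL `.mt` text format: a header line with the number of
#' hypotheses and the number of sites, then one row per hypothesis of
#' whitespace-separated per-input-tree log-likelihoods in input order. The
#' input trees play the role of sites, so CONSEL's RELL bootstrap resamples
#' whole trees; the exported matrix feeds the KH, SH and AU tests, which
#' are deliberately not reimplemented here. A sidecar file
#' `<path>.names` maps row indices to hypothesis names.
#'
#' @param hyps A `hypothesis_set` of at least 2 hypotheses.
#' @param path Output path (conventionally ending in `.mt`).
#' @return Invisibly, the matrix of per-tree log-likelihoods (hypotheses in
#'   rows).
#' @export
export_consel_matrix <- function(hyps, path) {
  stopifnot(inherits(hyps, "hypothesis_set"))
  k <- length(hyps$trees)
  if (k < 2L) stop("need at least 2 hypotheses for CONSEL export")
  mat <- t(vapply(hyps$scores, function(s) s$per_tree$log_likelihood,
                  numeric(hyps$n_inputs)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(k, ncol(mat)), con)
  for (i in seq_len(k)) {
    writeLines(paste(sprintf("%.6f", mat[i, ]), collapse = " "), con)
  }
  writeLines(paste(seq_len(k), hyps$names, sep = "\t"),
             paste0(path, ".names"))
  invisible(mat)
}

#' Read a CONSEL .mt matrix
#'
#' Structural re-reader for files written by [export_consel_matrix()] (or by
#' other tools using the same format).
#'
#' @param path Path to a `.mt` file.
#' @return A list with `n_hypotheses`, `n_sites` and `matrix`.
#' @export
read_consel_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr))
    stop("malformed .mt header: ", lines[1])
  k <- hdr[1]; n <- hdr[2]
  if (length(lines) - 1L != k)
    stop("expected ", k, " rows, found ", length(lines) - 1L)
  mat <- matrix(NA_real_, k, n)
  for (i in seq_len(k)) {
    vals <- as.numeric(strsplit(trimws(lines[i + 1L]), "\\s+")[[1]])
    if (length(vals) != n)
      stop("row ", i, " has ", length(vals), " values, expected ", n)
    mat[i, ] <- vals
  }
  list(n_hypotheses = k, n_sites = n, matrix = mat)
}
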