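# Internal adjacency-list tree engine used by the SPR search.
#
# A 'tg' is a list(adj = list of integer neighbor vectors, labels = character
# vector with NA for internal nodes). Leaves have degree 1. Topologies are
# compared through split bitmasks: taxa are assigned bits in words of 30 bits
# (integer arithmetic stays exact), so any number of taxa is supported; the
# common single-word case uses plain integer vectors.

local_pkg_env <- new.env(parent = emptyenv())

pc16_table <- function() {
  tbl <- get0("pc16", envir = local_pkg_env)
  if (is.null(tbl)) {
    b <- 0:65535
    tbl <- Reduce(`+`, lapply(0:15, function(k) bitwAnd(bitwShiftR(b, k), 1L)))
    assign("pc16", tbl, envir = local_pkg_env)
  }
  tbl
}

popcount32 <- function(x) {
  tbl <- pc16_table()
  tbl[bitwAnd(x, 65535L) + 1L] + tbl[bitwShiftR(x, 16L) + 1L]
}

# bit assignment for a taxon set: word index and in-word bit per label
make_bitmap <- function(labels) {
  labels <- sort(labels)
  n <- length(labels)
  nw <- max(1L, as.integer(ceiling(n / 30)))
  word <- (seq_len(n) - 1L) %/% 30L + 1L
  bit <- bitwShiftL(1L, (seq_len(n) - 1L) %% 30L)
  full <- integer(nw)
  for (i in seq_len(n)) full[word[i]] <- bitwOr(full[word[i]], bit[i])
  list(labels = labels, n = n, nw = nw,
       word = stats::setNames(word, labels),
       bit = stats::setNames(bit, labels),
       full = full)
}

leaf_mask <- function(bm, labels) {
  m <- integer(bm$nw)
  w <- bm$word[labels]
  b <- bm$bit[labels]
  if (anyNA(w)) stop("labels outside the bitmap: ",
                     paste(labels[is.na(w)], collapse = ", "))
  for (i in seq_along(w)) m[w[i]] <- bitwOr(m[w[i]], b[i])
  m
}

mask_popcount <- function(m) sum(popcount32(m))

mask_and <- function(a, b) bitwAnd(a, b)
mask_xor <- function(a, b) bitwXor(a, b)

# canonical orientation: lexicographically smaller of mask and its
# complement within 'within'
mask_canonical <- function(m, within) {
  comp <- bitwAnd(within, bitwNot(m))
  for (k in seq_along(m)) {
    if (m[k] < comp[k]) return(m)
    if (m[k] > comp[k]) return(comp)
  }
  m
}

mask_key <- function(m) paste(m, collapse = "_")

# ---- phylo <-> tg ----------------------------------------------------------

phylo_to_tg <- function(phy) {
  nt <- length(phy$tip.label)
  N <- nt + phy$Nnode
  from <- c(phy$edge[, 1], phy$edge[, 2])
  to <- c(phy$edge[, 2], phy$edge[, 1])
  adj <- unname(split(to, factor(from, levels = seq_len(N))))
  labels <- c(phy$tip.label, rep(NA_character_, phy$Nnode))
  list(adj = adj, labels = labels)
}

tg_newick <- function(tg) {
  deg <- lengths(tg$adj)
  root <- which(deg >= 2L)[1]
  if (is.na(root)) {  # two-leaf tree
    return(paste0("(", tg$labels[1], ",", tg$labels[2], ");"))
  }
  rec <- function(v, parent) {
    nbrs <- setdiff(tg$adj[[v]], parent)
    if (length(nbrs) == 0L) return(tg$labels[v])
    paste0("(", paste(vapply(nbrs, rec, "", parent = v), collapse = ","), ")")
  }
  paste0(rec(root, 0L), ";")
}

tg_to_phylo <- function(tg) ape::read.tree(text = tg_newick(tg))

# leaf mask of every node's subtree away from 'root'; returns list(mask =
# list per node, order = preorder vector of (node,parent))
tg_node_masks <- function(tg, bm) {
  deg <- lengths(tg$adj)
  root <- which(deg >= 2L)[1]
  if (is.na(root)) root <- 1L
  n_nodes <- length(tg$adj)
  parent <- integer(n_nodes)
  order <- integer(0)
  stack <- root
  parent[root] <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, v)
    kids <- setdiff(tg$adj[[v]], parent[v])
    parent[kids] <- v
    stack <- c(stack, kids)
  }
  masks <- vector("list", n_nodes)
  for (v in rev(order)) {
    if (!is.na(tg$labels[v])) {
      masks[[v]] <- leaf_mask(bm, tg$labels[v])
    } else {
      m <- integer(bm$nw)
      for (k in setdiff(tg$adj[[v]], parent[v])) m <- bitwOr(m, masks[[k]])
      masks[[v]] <- m
    }
  }
  list(masks = masks, parent = parent, root = root, order = order)
}

# canonical non-trivial split masks of a tg over bitmap bm (within 'present',
# the mask of leaves actually in the tree); returns list of masks, deduped
tg_split_masks <- function(tg, bm) {
  nm <- tg_node_masks(tg, bm)
  present <- nm$masks[[nm$root]]
  total <- mask_popcount(present)
  out <- list()
  seen <- character(0)
  for (v in nm$order) {
    if (v == nm$root) next
    m <- nm$masks[[v]]
    p <- mask_popcount(m)
    if (p < 2L || total - p < 2L) next
    cm <- mask_canonical(m, present)
    k <- mask_key(cm)
    if (k %in% seen) next
    seen <- c(seen, k)
    out[[length(out) + 1L]] <- cm
  }
  list(masks = out, present = present, sig = paste(sort(seen), collapse = ";"))
}

# split masks of a phylo over bitmap bm (same encoding as tg_split_masks)
phylo_split_masks <- function(phy, bm) {
  if (length(phy$tip.label) < 2L) {
    present <- leaf_mask(bm, phy$tip.label)
    return(list(masks = list(), present = present, sig = ""))
  }
  tg <- phylo_to_tg(phy)
  tg_split_masks(tg, bm)
}

# ---- SPR moves -------------------------------------------------------------

# All directed edges (u, v) of a binary unrooted tg with u internal; pruning
# the component containing v and regrafting it elsewhere defines the SPR
# neighborhood. Returns a data.frame-like list of move descriptors.
tg_directed_edges <- function(tg) {
  deg <- lengths(tg$adj)
  res <- list()
  for (u in seq_along(tg$adj)) {
    if (deg[u] < 2L) next
    for (v in tg$adj[[u]]) {
      res[[length(res) + 1L]] <- c(u, v)
    }
  }
  res
}

# leaf labels of the component containing v when edge u-v is cut
tg_component_leaves <- function(tg, u, v) {
  seen <- v
  stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nxt <- setdiff(tg$adj[[x]], c(seen, u))
    seen <- c(seen, nxt)
    stack <- c(stack, nxt)
  }
  tg$labels[seen][!is.na(tg$labels[seen])]
}

# Regraft candidates for pruning the subtree at directed edge (u, v).
# Returns list of list(tg, dist) where dist is the number of edges between
# the original attachment edge and the destination edge in the pruned tree.
tg_spr_regrafts <- function(tg, u, v) {
  nbrs <- setdiff(tg$adj[[u]], v)
  if (length(nbrs) != 2L) stop("SPR requires a binary tree")
  a <- nbrs[1]
  b <- nbrs[2]
  # suppress u in the remaining component: connect a-b
  base <- tg$adj
  base[[a]][base[[a]] == u] <- b
  base[[b]][base[[b]] == u] <- a
  base[[u]] <- v  # u kept as the future regraft node, still tied to v
  # remaining component: BFS from a avoiding the pruned side
  comp <- a
  stack <- a
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nxt <- setdiff(base[[x]], c(comp, u, v))
    comp <- c(comp, nxt)
    stack <- c(stack, nxt)
  }
  if (length(comp) < 2L) return(list())
  # node distances from the original attachment edge {a, b}
  dist <- rep(NA_integer_, length(tg$adj))
  dist[a] <- 0L
  dist[b] <- 0L
  frontier <- c(a, b)
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- integer(0)
    for (x in frontier) {
      for (y in base[[x]]) {
        if (y %in% comp && is.na(dist[y])) {
          dist[y] <- d
          nxt <- c(nxt, y)
        }
      }
    }
    frontier <- nxt
  }
  # destination edges within the remaining component, excluding {a,b}
  out <- list()
  for (x in comp) {
    for (y in base[[x]]) {
      if (y < x || !(y %in% comp)) next
      if ((x == a && y == b) || (x == b && y == a)) next
      adj2 <- base
      adj2[[x]][adj2[[x]] == y] <- u
      adj2[[y]][adj2[[y]] == x] <- u
      adj2[[u]] <- c(v, x, y)
      out[[length(out) + 1L]] <-
        list(tg = list(adj = adj2, labels = tg$labels),
             dist = min(dist[x], dist[y]))
    }
  }
  out
}

# full SPR neighborhood, deduplicated by split signature; drops the original
# topology. Each element: list(tg, masks, sig, dist, subtree_sig).
tg_spr_neighborhood <- function(tg, bm, max_dist = Inf) {
  orig <- tg_split_masks(tg, bm)
  seen <- orig$sig
  out <- list()
  for (e in tg_directed_edges(tg)) {
    u <- e[1]; v <- e[2]
    if (length(tg$adj[[u]]) != 3L) next  # only internal u can be suppressed
    sub_leaves <- tg_component_leaves(tg, u, v)
    sub_sig <- paste(sort(sub_leaves), collapse = ",")
    for (cand in tg_spr_regrafts(tg, u, v)) {
      if (cand$dist > max_dist) next
      sm <- tg_split_masks(cand$tg, bm)
      if (sm$sig %in% seen) next
      seen <- c(seen, sm$sig)
      out[[length(out) + 1L]] <-
        list(tg = cand$tg, masks = sm, sig = sm$sig,
             dist = cand$dist, subtree = sub_sig)
    }
  }
  out
}
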