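## Hierarchical density-based clustering on a precomputed distance matrix -----
##
## The classic HDBSCAN construction: per-point core distances, the mutual
## reachability transform, a single-linkage hierarchy over the minimum
## spanning tree, condensation of the dendrogram by a minimum cluster size,
## and excess-of-mass cluster selection on the condensed tree.  Points not
## absorbed by any selected cluster are noise.
##
## Implemented here because the installed R stack has no density-based
## clusterer; validated against planted-partition benchmarks in the tests.

## Minimum spanning tree of a symmetric weight matrix (Prim, O(n^2)).
## Returns a data.frame of edges (i, j, w).
mst_edges <- function(w) {
  n <- nrow(w)
  in_tree <- logical(n)
  in_tree[1L] <- TRUE
  best_w <- w[, 1L]
  best_from <- rep(1L, n)
  edges <- data.frame(i = integer(n - 1L), j = integer(n - 1L),
                      w = numeric(n - 1L))
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_w[cand])]
    edges$i[e] <- best_from[v]; edges$j[e] <- v; edges$w[e] <- best_w[v]
    in_tree[v] <- TRUE
    upd <- !in_tree & w[, v] < best_w
    best_from[upd] <- v
    best_w[upd] <- w[upd, v]
  }
  edges
}

#' Hierarchical density-based clustering (precomputed distances)
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param min_cluster_size Smallest group reported as a cluster (>= 2).
#' @param min_samples Neighbourhood size for the core-distance estimate;
#'   defaults to `min_cluster_size`.
#' @return Integer vector of labels: `1..k` for clusters (numbered by first
#'   member), `0` for noise.
#' @export
hdbscan_precomputed <- function(d, min_cluster_size = 2L,
                                min_samples = min_cluster_size) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (min_cluster_size < 2L) stop("min_cluster_size must be >= 2")
  n <- nrow(d)
  if (n == 1L) return(1L)
  mcs <- as.integer(min_cluster_size)

  # core distance: distance to the min_samples-th nearest neighbour,
  # the point itself counting as its own first neighbour
  k <- min(as.integer(min_samples), n)
  core <- vapply(seq_len(n), function(i) {
    sort(d[i, ])[k]  # row includes d[i,i] = 0, i.e. the point itself
  }, numeric(1))
  mr <- pmax(d, outer(core, core, pmax))
  diag(mr) <- 0

  edges <- mst_edges(mr)
  edges <- edges[order(edges$w, edges$i, edges$j), , drop = FALSE]

  ## single-linkage hierarchy via union-find; internal nodes n+1 .. 2n-1
  parent_uf <- seq_len(2L * n - 1L)
  find <- function(x) {
    while (parent_uf[x] != x) x <- parent_uf[x]
    x
  }
  children <- vector("list", 2L * n - 1L)
  height <- numeric(2L * n - 1L)
  npts <- c(rep(1L, n), integer(n - 1L))
  nxt <- n
  for (e in seq_len(nrow(edges))) {
    a <- find(edges$i[e]); b <- find(edges$j[e])
    nxt <- nxt + 1L
    children[[nxt]] <- c(a, b)
    height[nxt] <- edges$w[e]
    npts[nxt] <- npts[a] + npts[b]
    parent_uf[a] <- nxt; parent_uf[b] <- nxt
  }
  root <- 2L * n - 1L

  subtree_points <- function(h) {
    if (h <= n) return(h)
    out <- integer(0)
    stack <- h
    while (length(stack) > 0L) {
      x <- stack[[1L]]; stack <- stack[-1L]
      if (x <= n) out <- c(out, x) else stack <- c(stack, children[[x]])
    }
    out
  }

  ## condensed tree: rows (parent cluster, child id, lambda, size);
  ## child id > 0 is a point, < 0 is a child cluster (-id)
  cond <- list()
  cluster_parent <- integer(0)  # condensed parent of each condensed cluster
  n_clusters <- 1L              # cluster 1 is the root cluster
  cluster_parent[1L] <- 0L
  add_row <- function(p, ch, lam, sz) {
    cond[[length(cond) + 1L]] <<- c(p, ch, lam, sz)
  }
  lam_of <- function(dist) 1 / max(dist, 1e-12)

  stack <- list(c(root, 1L))
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    h <- fr[1L]; cl <- fr[2L]
    if (h <= n) next
    lam <- lam_of(height[h])
    ch <- children[[h]]
    big <- ch[npts[ch] >= mcs]
    if (length(big) == 2L) {
      for (b in ch) {
        n_clusters <- n_clusters + 1L
        cluster_parent[n_clusters] <- cl
        add_row(cl, -n_clusters, lam, npts[b])
        stack[[length(stack) + 1L]] <- c(b, n_clusters)
      }
    } else {
      for (b in ch[npts[ch] < mcs]) {
        for (p in subtree_points(b)) add_row(cl, p, lam, 1L)
      }
      if (length(big) == 1L) stack[[length(stack) + 1L]] <- c(big, cl)
    }
  }
  cond <- do.call(rbind, cond)
  colnames(cond) <- c("parent", "child", "lambda", "size")

  ## stability: sum over member rows of (lambda - birth) * size
  birth <- numeric(n_clusters)
  for (r in seq_len(nrow(cond))) {
    if (cond[r, "child"] < 0) birth[-cond[r, "child"]] <- cond[r, "lambda"]
  }
  stability <- numeric(n_clusters)
  for (r in seq_len(nrow(cond))) {
    p <- cond[r, "parent"]
    stability[p] <- stability[p] +
      (cond[r, "lambda"] - birth[p]) * cond[r, "size"]
  }

  ## excess-of-mass selection, leaves first; the root is never selected
  kids <- lapply(seq_len(n_clusters), function(c) {
    which(cluster_parent == c)
  })
  selected <- logical(n_clusters)
  score <- numeric(n_clusters)
  for (c in rev(seq_len(n_clusters))) {
    child_sum <- sum(score[kids[[c]]])
    if (c == 1L) {
      score[c] <- child_sum
    } else if (length(kids[[c]]) == 0L || stability[c] >= child_sum) {
      selected[c] <- TRUE
      score[c] <- max(stability[c], child_sum)
      # deselect descendants
      desc <- kids[[c]]
      while (length(desc) > 0L) {
        selected[desc] <- FALSE
        desc <- unlist(kids[desc])
      }
    } else {
      score[c] <- child_sum
    }
  }
  if (!any(selected)) selected[1L] <- TRUE  # homogeneous data: one cluster

  ## label points: walk up from the cluster a point fell out of
  labels <- integer(n)
  pt_rows <- cond[cond[, "child"] > 0, , drop = FALSE]
  for (r in seq_len(nrow(pt_rows))) {
    c <- pt_rows[r, "parent"]
    lab <- 0L
    while (c != 0L) {
      if (selected[c]) { lab <- c; break }
      c <- cluster_parent[c]
    }
    labels[pt_rows[r, "child"]] <- lab
  }
  ## renumber clusters 1..k by first member
  out <- integer(n)
  seen <- integer(0)
  for (i in seq_len(n)) {
    if (labels[i] == 0L) next
    m <- match(labels[i], seen)
    if (is.na(m)) { seen <- c(seen, labels[i]); m <- length(seen) }
    out[i] <- m
  }
  out
}

#' Cluster attractor profiles by Jaccard-Needham dissimilarity
#'
#' Runs hierarchical density-based clustering on a precomputed
#' dissimilarity matrix (see [pairwise_distances()]).  Noise points are
#' labelled 0 and excluded from cluster means.
#'
#' @param dist Square dissimilarity matrix.
#' @param min_cluster_size Minimum cluster size (>= 2), default 2.
#' @return Integer label vector (`0` = noise).
#' @export
cluster_attractors <- function(dist, min_cluster_size = 2L) {
  hdbscan_precomputed(dist, min_cluster_size = min_cluster_size)
}
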