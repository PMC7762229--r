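## Jaccard-Needham similarity of binary attractor profiles --------------------
##
## For two binary vectors Z1, Z2 let S_ij be the number of positions where
## Z1 carries i and Z2 carries j.  Then
##   S = S11 / (S11 + S10 + S01)     (similarity)
##   D = (S10 + S01) / (S11 + S10 + S01)   (dissimilarity)
## and S + D = 1 whenever the denominator is nonzero.  When both vectors are
## all-zero the denominator vanishes; the pair is then treated as identical
## (S = 1, D = 0), consistent with D being the Jaccard distance.

#' Match counts of a binary vector pair
#'
#' @param z1,z2 Equal-length 0/1 vectors.
#' @return Named integer vector with `S11`, `S10`, `S01`, `S00`.
#' @export
match_counts <- function(z1, z2) {
  stopifnot(length(z1) == length(z2))
  z1 <- as.integer(z1); z2 <- as.integer(z2)
  stopifnot(all(z1 %in% c(0L, 1L)), all(z2 %in% c(0L, 1L)))
  c(S11 = sum(z1 == 1L & z2 == 1L),
    S10 = sum(z1 == 1L & z2 == 0L),
    S01 = sum(z1 == 0L & z2 == 1L),
    S00 = sum(z1 == 0L & z2 == 0L))
}

#' Jaccard-Needham similarity and dissimilarity
#'
#' @inheritParams match_counts
#' @return List with `similarity` and `dissimilarity`; they sum to 1.
#' @examples
#' jaccard_needham(c(1, 1, 0, 0), c(1, 0, 1, 0))  # S = 1/3, D = 2/3
#' @export
jaccard_needham <- function(z1, z2) {
  s <- match_counts(z1, z2)
  denom <- s[["S11"]] + s[["S10"]] + s[["S01"]]
  if (denom == 0L) {
    return(list(similarity = 1, dissimilarity = 0))
  }
  list(similarity = s[["S11"]] / denom,
       dissimilarity = (s[["S10"]] + s[["S01"]]) / denom)
}

#' Pairwise Jaccard-Needham dissimilarity matrix
#'
#' @param x A `profile_table` or a 0/1 matrix (rows = profiles).
#' @return Square symmetric matrix of dissimilarities in \[0, 1\] with zero
#'   diagonal.
#' @export
pairwise_distances <- function(x) {
  m <- if (inherits(x, "profile_table")) x$profiles else x
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  storage.mode(m) <- "double"
  s11 <- m %*% t(m)
  size <- rowSums(m)
  union <- outer(size, size, "+") - s11
  d <- ifelse(union == 0, 0, 1 - s11 / union)
  diag(d) <- 0
  rownames(d) <- colnames(d) <- rownames(m)
  d
}

#' Pearson correlation between category and cluster mean profiles
#'
#' @param category_means Matrix, one row per supervised category, columns =
#'   nodes.
#' @param cluster_means Matrix, one row per cluster, same node columns.
#' @return Matrix of Pearson r, rows = categories, columns = clusters.
#'   Pairs involving a zero-variance profile are `NA` (with a warning).
#' @export
category_cluster_correlation <- function(category_means, cluster_means) {
  stopifnot(identical(colnames(category_means), colnames(cluster_means)))
  r <- suppressWarnings(stats::cor(t(category_means), t(cluster_means)))
  if (anyNA(r)) warning("zero-variance profile: undefined correlation entries set to NA")
  dimnames(r) <- list(rownames(category_means), rownames(cluster_means))
  r
}

#' Mean profiles per cluster label
#'
#' Noise points (label 0) are excluded.
#'
#' @param profiles 0/1 matrix of profiles.
#' @param labels Integer cluster labels from [cluster_attractors()].
#' @return Matrix with one row per cluster, rownames `"cluster_<k>"`.
#' @export
cluster_means <- function(profiles, labels) {
  stopifnot(nrow(profiles) == length(labels))
  ks <- sort(unique(labels[labels > 0L]))
  out <- t(vapply(ks, function(k) {
    colMeans(profiles[labels == k, , drop = FALSE])
  }, numeric(ncol(profiles))))
  rownames(out) <- paste0("cluster_", ks)
  out
}
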