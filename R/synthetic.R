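## Seeded synthetic generators ------------------------------------------------
##
## Random Boolean networks validate the fixed-point solver against the
## exhaustive oracle; planted-cluster binary datasets emulate the structure
## the unsupervised attractor analysis assumes (small within-phenotype,
## large between-phenotype binary distance).  Every generator is a pure
## function of its spec, seed included.

#' Generate a seeded random Boolean network
#'
#' Input nodes get identity rules; every other node receives at most
#' `max_in_degree` regulators chosen uniformly and a rule in the requested
#' style.
#'
#' @param n_nodes Total node count.
#' @param n_inputs Number of input nodes (`< n_nodes`).
#' @param max_in_degree Maximum regulators per non-input node (>= 1).
#' @param expression_style `"random_and_or_not"` draws a random operator
#'   tree; `"random_truth_table"` draws a uniform truth table over the
#'   regulators and materializes it as a sum-of-products expression, so the
#'   whole pipeline exercises one expression representation.
#' @param seed Integer seed.
#' @return A [boolean_network()] with nodes `I1..` (inputs) and `N1..`.
#' @export
random_network <- function(n_nodes, n_inputs = 0L, max_in_degree = 3L,
                           expression_style = c("random_and_or_not",
                                                "random_truth_table"),
                           seed = 1L) {
  expression_style <- match.arg(expression_style)
  stopifnot(n_inputs < n_nodes, max_in_degree >= 1L)
  inputs <- if (n_inputs > 0L) paste0("I", seq_len(n_inputs)) else character(0)
  others <- paste0("N", seq_len(n_nodes - n_inputs))
  nodes <- c(inputs, others)
  with_seed(seed, {
    rules <- c(
      setNames(lapply(inputs, bool_var), inputs),
      setNames(lapply(others, function(n) {
        k <- sample.int(max_in_degree, 1L)
        regs <- sample(nodes, min(k, length(nodes)))
        if (expression_style == "random_and_or_not") {
          random_op_tree(regs)
        } else {
          truth_table_expr(regs, sample(c(0L, 1L), 2^length(regs),
                                        replace = TRUE))
        }
      }), others)
    )
  })
  boolean_network(rules, inputs = inputs)
}

## Random AND/OR/NOT tree over the given regulators (each used once).
random_op_tree <- function(regs) {
  leaves <- lapply(regs, function(r) {
    e <- bool_var(r)
    if (stats::runif(1) < 0.3) bool_not(e) else e
  })
  while (length(leaves) > 1L) {
    op <- sample(c("and", "or"), 1L)
    merged <- bool_nary(op, leaves[1:2])
    leaves <- c(list(merged), leaves[-(1:2)])
  }
  leaves[[1L]]
}

## Materialize a truth table as a canonical sum-of-products expression.
truth_table_expr <- function(regs, outputs) {
  k <- length(regs)
  stopifnot(length(outputs) == 2^k)
  ones <- which(outputs == 1L)
  if (length(ones) == 0L) return(bool_const(0L))
  if (length(ones) == 2^k) return(bool_const(1L))
  terms <- lapply(ones, function(row) {
    bits <- as.integer(intToBits(row - 1L))[seq_len(k)]
    lits <- lapply(seq_len(k), function(j) {
      if (bits[j] == 1L) bool_var(regs[j]) else bool_not(bool_var(regs[j]))
    })
    bool_nary("and", lits)
  })
  bool_nary("or", terms)
}

#' Random rule strings for parser fuzzing
#'
#' Generates flat, partly un-parenthesized rule text mixing OR chains with
#' trailing AND-NOT guards, the shape on which the two parsing dialects
#' diverge.
#'
#' @param n_vars Number of candidate identifiers.
#' @param seed Integer seed.
#' @return A single rule string.
#' @export
random_rule_string <- function(n_vars = 4L, seed = 1L) {
  with_seed(seed, {
    vars <- paste0("V", sample.int(n_vars + 2L, n_vars))
    k <- sample(2:max(2L, n_vars), 1L)
    head <- paste(vars[seq_len(min(k, n_vars) - 1L)], collapse = " or ")
    tail <- sprintf("%s and not (%s)", head, vars[min(k, n_vars)])
    if (stats::runif(1) < 0.5) tail else head
  })
}

#' Generate a planted-cluster binary dataset
#'
#' Draws `n_clusters` centroid vectors with pairwise Hamming distance at
#' least `vector_length / 3` (resampling until satisfied), then emits
#' `vectors_per_cluster` members per centroid by independent bit flips.
#'
#' @param n_clusters Number of planted clusters.
#' @param vectors_per_cluster Members per cluster.
#' @param vector_length Bits per vector.
#' @param bit_flip_probability Per-bit flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param max_retries Resampling bound for the centroid separation.
#' @return List with `vectors` (0/1 matrix) and `labels` (integer).
#' @export
planted_clusters <- function(n_clusters, vectors_per_cluster, vector_length,
                             bit_flip_probability = 0.02, seed = 1L,
                             max_retries = 1000L) {
  stopifnot(bit_flip_probability >= 0, bit_flip_probability < 0.5)
  with_seed(seed, {
    sep <- vector_length / 3
    centroids <- NULL
    for (try in seq_len(max_retries)) {
      cand <- matrix(sample(c(0L, 1L), n_clusters * vector_length,
                            replace = TRUE), nrow = n_clusters)
      dh <- as.matrix(stats::dist(cand, method = "manhattan"))
      diag(dh) <- Inf
      if (all(dh >= sep)) { centroids <- cand; break }
    }
    if (is.null(centroids)) {
      stop("could not draw ", n_clusters, " centroids with pairwise Hamming ",
           "distance >= ", sep, " in ", max_retries, " attempts")
    }
    n <- n_clusters * vectors_per_cluster
    labels <- rep(seq_len(n_clusters), each = vectors_per_cluster)
    vectors <- centroids[labels, , drop = FALSE]
    flips <- matrix(stats::runif(n * vector_length) < bit_flip_probability,
                    nrow = n)
    vectors[flips] <- 1L - vectors[flips]
  })
  list(vectors = vectors, labels = labels)
}
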