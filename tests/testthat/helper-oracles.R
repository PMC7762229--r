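# Independent oracles and small fixtures shared across test files.

# Reference rule evaluator: plain recursion over the expression tree,
# independent of the package's compiled-language evaluation path.
ref_eval <- function(expr, assignment) {
  switch(expr$type,
    var = as.integer(assignment[[expr$name]]),
    const = expr$value,
    not = 1L - ref_eval(expr$arg, assignment),
    and = as.integer(all(vapply(expr$args, ref_eval, integer(1), assignment) == 1L)),
    or = as.integer(any(vapply(expr$args, ref_eval, integer(1), assignment) == 1L))
  )
}

# Random expression generator for round-trip / equivalence properties.
random_expr <- function(vars, depth = 3L) {
  if (depth == 0L || stats::runif(1) < 0.3) {
    if (stats::runif(1) < 0.1) return(macpol:::bool_const(sample(0:1, 1)))
    return(macpol:::bool_var(sample(vars, 1)))
  }
  op <- sample(c("not", "and", "or"), 1, prob = c(0.2, 0.4, 0.4))
  if (op == "not") {
    macpol:::bool_not(random_expr(vars, depth - 1L))
  } else {
    k <- sample(2:3, 1)
    macpol:::bool_nary(op, lapply(seq_len(k), function(i) {
      random_expr(vars, depth - 1L)
    }))
  }
}

# Two-node flip-flop and one-node negation toys used throughout.
net_flipflop <- function() boolean_network(c(A = "B", B = "A"))
net_negation <- function() boolean_network(c(C = "not C"))

# All 2^k input assignments of a network, in enumeration order.
all_input_assignments <- function(network) {
  k <- length(network$inputs)
  if (k == 0L) return(list(setNames(integer(0), character(0))))
  lapply(seq_len(2^k), function(i) {
    bits <- as.integer(intToBits(i - 1L)[seq_len(k)])
    setNames(rev(bits), network$inputs)
  })
}

# Period-1 attractor states of the exhaustive oracle, restricted to one
# input assignment, as a sorted key vector for set comparison.
oracle_fixed_point_keys <- function(network, assignment) {
  atts <- brute_force_attractors(network)
  keys <- character(0)
  for (a in atts) {
    if (a$period != 1L) next
    st <- a$states[1L, ]
    if (length(assignment) > 0L && !all(st[names(assignment)] == assignment)) next
    keys <- c(keys, paste(st, collapse = ""))
  }
  sort(keys)
}

state_keys <- function(m) sort(apply(m, 1L, paste, collapse = ""))

# Do two label vectors describe the same partition (up to renaming)?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(apply(base::table(a, b) > 0L, 1L, sum) == 1L) &&
    all(apply(base::table(a, b) > 0L, 2L, sum) == 1L)
}
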