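## Fixed-point enumeration ----------------------------------------------------
##
## The solver never walks the 2^N state space.  For a given input assignment
## it (1) clamps the inputs and propagates constants to closure, (2) takes a
## feedback vertex set (FVS) of the remaining free core, (3) enumerates the
## 2^|FVS| assignments of the FVS, propagating all other free nodes in
## topological order, and (4) keeps the candidates whose FVS nodes are
## self-consistent.  Every state returned is re-checked against
## synchronous_step(), not assumed.

#' Enumerate the fixed points under one input assignment
#'
#' @param network A [boolean_network()].
#' @param input_assignment Named 0/1 vector covering all inputs of the
#'   network (clamping additional non-input nodes is allowed).
#' @param fvs Optional feedback vertex set of the conditioned free core to
#'   use instead of the greedy one; the result is independent of this
#'   choice (any cycle cover gives the same fixed points).
#' @return A 0/1 matrix with one row per fixed point and one column per
#'   network node, rows sorted lexicographically by bit pattern.  Zero rows
#'   is a valid result.
#' @export
enumerate_fixed_points <- function(network, input_assignment, fvs = NULL) {
  miss <- setdiff(network$inputs, names(input_assignment))
  if (length(miss) > 0L) {
    stop("input assignment must cover all inputs; missing: ",
         paste(miss, collapse = ", "))
  }
  cond <- condition_network(network, input_assignment)
  core <- cond$network
  nodes <- network$nodes

  if (is.null(core)) {
    # everything forced; the forced state is a fixed point by construction
    st <- cond$forced[nodes]
    m <- matrix(st, nrow = 1L, dimnames = list(NULL, nodes))
    stopifnot(identical(unname(synchronous_step(network, st)), unname(st)))
    return(m)
  }

  if (is.null(fvs)) {
    fvs <- feedback_vertex_set(core)
  } else {
    fvs <- intersect(fvs, core$nodes)
  }
  parents <- dependency_parents(core)
  rest <- topological_order(parents, setdiff(core$nodes, fvs))

  k <- length(fvs)
  ncand <- as.integer(2^k)
  cand <- matrix(0L, nrow = ncand, ncol = length(nodes),
                 dimnames = list(NULL, nodes))
  for (n in names(cond$forced)) cand[, n] <- cond$forced[[n]]
  for (j in seq_len(k)) {
    cand[, fvs[j]] <- rep(rep(c(0L, 1L), each = 2^(k - j)), length.out = ncand)
  }
  env <- lapply(seq_len(ncol(cand)), function(j) as.logical(cand[, j]))
  names(env) <- nodes
  for (n in rest) {
    v <- eval(core$compiled[[n]], envir = env)
    if (length(v) == 1L) v <- rep(v, ncand)
    env[[n]] <- v
    cand[, n] <- as.integer(v)
  }
  ok <- rep(TRUE, ncand)
  for (n in fvs) {
    v <- eval(core$compiled[[n]], envir = env)
    if (length(v) == 1L) v <- rep(v, ncand)
    ok <- ok & (as.integer(v) == cand[, n])
  }
  fp <- cand[ok, , drop = FALSE]
  if (nrow(fp) > 0L) {
    fp <- fp[order_states(fp), , drop = FALSE]
    nxt <- step_states(network, fp)
    stopifnot(all(nxt == fp))  # re-check F(x) == x
  }
  fp
}

## Deterministic lexicographic row order for a 0/1 matrix.
order_states <- function(m) {
  do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' Enumerate the fixed points over all input assignments
#'
#' Takes the union of [enumerate_fixed_points()] over all
#' `2^length(inputs)` input assignments, in lexicographic input order.
#' Each assignment's fixed points count separately, so the row count is the
#' total fixed-point tally of the model over the full stimulus space.
#'
#' @param network A [boolean_network()].
#' @param max_inputs Guard: refuse networks with more than this many inputs.
#' @return An object of class `fixed_points`: a 0/1 matrix (rows = fixed
#'   points, columns = nodes) with attribute `n_assignments`.
#' @export
enumerate_all_fixed_points <- function(network, max_inputs = 20L) {
  inputs <- network$inputs
  if (length(inputs) > max_inputs) {
    stop("network has ", length(inputs), " inputs; refusing to enumerate more than ",
         max_inputs, " (2^", length(inputs), " assignments)")
  }
  k <- length(inputs)
  nass <- as.integer(2^k)
  out <- vector("list", nass)
  for (i in seq_len(nass)) {
    bits <- as.integer(intToBits(i - 1L)[seq_len(max(k, 1L))])[seq_len(k)]
    assign <- setNames(rev(bits), inputs)  # first input = most significant
    out[[i]] <- enumerate_fixed_points(network, assign)
  }
  m <- do.call(rbind, out)
  structure(m, class = c("fixed_points", class(m)), n_assignments = nass)
}

#' @export
print.fixed_points <- function(x, ...) {
  cat(sprintf("%d fixed point(s) over %d input assignment(s), %d nodes\n",
              nrow(x), attr(x, "n_assignments"), ncol(x)))
  invisible(x)
}

#' Exhaustive attractor search (test oracle)
#'
#' Builds the full synchronous state-transition graph and returns every
#' terminal cycle, including the period-1 cycles (fixed points).  Exponential
#' in the node count; intended as an oracle for validating the fixed-point
#' solver and for small fixtures.
#'
#' @param network A [boolean_network()].
#' @param max_nodes Size guard (default 20).
#' @return List of attractors, each a list with `period` and `states`
#'   (0/1 matrix, one row per state; rows rotated so the lexicographically
#'   smallest state comes first).  Attractors are ordered by their smallest
#'   state.
#' @export
brute_force_attractors <- function(network, max_nodes = 20L) {
  n <- length(network$nodes)
  if (n > max_nodes) {
    stop("network has ", n, " nodes; oracle limited to ", max_nodes)
  }
  nstates <- as.integer(2^n)
  states <- matrix(0L, nrow = nstates, ncol = n,
                   dimnames = list(NULL, network$nodes))
  for (j in seq_len(n)) {
    states[, j] <- rep(rep(c(0L, 1L), each = 2^(n - j)), length.out = nstates)
  }
  nxt <- step_states(network, states)
  trans <- as.integer(nxt %*% (2^((n - 1L):0))) + 1L  # successor index

  color <- integer(nstates)  # 0 unvisited, 1 on current walk, 2 resolved
  attractors <- list()
  for (s in seq_len(nstates)) {
    if (color[s] != 0L) next
    walk <- integer(0)
    v <- s
    while (color[v] == 0L) {
      color[v] <- 1L
      walk <- c(walk, v)
      v <- trans[v]
    }
    if (color[v] == 1L) {  # new cycle closed within this walk
      i <- match(v, walk)
      cyc <- walk[i:length(walk)]
      rot <- which.min(cyc)
      cyc <- c(cyc[rot:length(cyc)], cyc[seq_len(rot - 1L)])
      attractors[[length(attractors) + 1L]] <- list(
        period = length(cyc),
        states = states[cyc, , drop = FALSE]
      )
    }
    color[walk] <- 2L
  }
  key <- vapply(attractors, function(a) {
    paste(a$states[1L, ], collapse = "")
  }, character(1))
  attractors[order(key)]
}

#' Simulate a synchronous trajectory
#'
#' Iterates [synchronous_step()] from an initial state until a state repeats,
#' reporting the attractor entered (its period and states).
#'
#' @param network A [boolean_network()].
#' @param initial_state Named 0/1 vector.
#' @param max_steps Maximum number of updates before giving up.
#' @return List with `trajectory` (matrix of visited states up to the first
#'   repeat), `period` (attractor length, NA if not converged within
#'   `max_steps`) and `attractor` (matrix of attractor states).
#' @export
simulate_network <- function(network, initial_state, max_steps = 1000L) {
  stopifnot(max_steps >= 1L)
  st <- check_state(network, initial_state)
  seen <- character(0)
  traj <- list()
  key <- paste(st, collapse = "")
  while (!(key %in% seen) && length(seen) <= max_steps) {
    seen <- c(seen, key)
    traj[[length(traj) + 1L]] <- st
    st <- synchronous_step(network, st)
    key <- paste(st, collapse = "")
  }
  traj_m <- do.call(rbind, traj)
  colnames(traj_m) <- network$nodes
  if (!(key %in% seen)) {
    return(list(trajectory = traj_m, period = NA_integer_, attractor = NULL))
  }
  i <- match(key, seen)
  list(
    trajectory = traj_m,
    period = nrow(traj_m) - i + 1L,
    attractor = traj_m[i:nrow(traj_m), , drop = FALSE]
  )
}

#' Attractor periods reached from random initial states
#'
#' Samples `n` random initial states (inputs included), advances all of them
#' `transient` synchronous steps in a single vectorized batch, and then
#' detects, for each trajectory, whether it has entered a cycle of period
#' `1..max_period`.  This is the sampling-based probe for the cyclic
#' attractors of the full model, whose exhaustive state-transition graph is
#' out of reach.
#'
#' @param network A [boolean_network()].
#' @param n Number of random initial states.
#' @param transient Steps to run before testing for periodicity.
#' @param max_period Largest period tested.
#' @param seed Integer seed.
#' @return Integer vector of per-trajectory periods (NA when no period
#'   `<= max_period` was detected after the transient).
#' @export
sample_attractor_periods <- function(network, n = 10000L, transient = 100L,
                                     max_period = 4L, seed = 1L) {
  nn <- length(network$nodes)
  with_seed(seed, {
    states <- matrix(sample(c(0L, 1L), n * nn, replace = TRUE), nrow = n,
                     dimnames = list(NULL, network$nodes))
  })
  for (t in seq_len(transient)) states <- step_states(network, states)
  ref <- states
  period <- rep(NA_integer_, n)
  for (p in seq_len(max_period)) {
    states <- step_states(network, states)
    hit <- is.na(period) & rowSums(states != ref) == 0L
    period[hit] <- p
  }
  period
}
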