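## Boolean networks -----------------------------------------------------------

#' Construct a Boolean network
#'
#' A network is an ordered set of nodes, one update rule per node, and a
#' designated input subset.  Inputs carry the identity rule on themselves
#' (`A, A`), which makes them constant along any trajectory; enumerating
#' "all combinations of stimuli" is then exactly enumerating the
#' `2^length(inputs)` input assignments.
#'
#' @param rules Named character vector or named list of rule strings /
#'   `bool_expr` objects.  Names give the node order, which is the
#'   state-vector convention for the lifetime of the network.
#' @param inputs Character vector of input nodes.  If `NULL`, every node
#'   whose rule is the identity on itself is taken as an input.
#' @param dialect Parsing dialect, see [parse_rule()].
#' @return An object of class `boolean_network`.
#' @examples
#' net <- boolean_network(c(A = "B", B = "A"))
#' synchronous_step(net, c(A = 0, B = 1))
#' @export
boolean_network <- function(rules, inputs = NULL,
                            dialect = c("standard", "grouped")) {
  dialect <- match.arg(dialect)
  nodes <- names(rules)
  if (is.null(nodes) || any(!nzchar(nodes)) || anyDuplicated(nodes)) {
    stop("rules must be uniquely named by node")
  }
  exprs <- lapply(rules, function(r) {
    if (inherits(r, "bool_expr")) r else parse_rule(r, dialect)
  })
  names(exprs) <- nodes
  referenced <- unique(unlist(lapply(exprs, free_variables)))
  unknown <- setdiff(referenced, nodes)
  if (length(unknown) > 0L) {
    stop("rule(s) reference undeclared node(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(inputs)) {
    inputs <- nodes[vapply(nodes, function(n) {
      e <- strip_attr(exprs[[n]])
      identical(e, bool_var(n))
    }, logical(1))]
  } else {
    stopifnot(all(inputs %in% nodes))
    for (n in inputs) {
      if (!identical(strip_attr(exprs[[n]]), bool_var(n))) {
        stop("input node '", n, "' must have the identity rule on itself")
      }
    }
  }
  structure(list(
    nodes = nodes,
    rules = exprs,
    inputs = inputs,
    compiled = lapply(exprs, expr_to_lang)
  ), class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d nodes (%d inputs)\n",
              length(x$nodes), length(x$inputs)))
  if (length(x$inputs)) cat("inputs:", paste(x$inputs, collapse = ", "), "\n")
  for (n in setdiff(x$nodes, x$inputs)) {
    cat(sprintf("  %s <- %s\n", n, serialize_rule(x$rules[[n]])))
  }
  invisible(x)
}

check_state <- function(network, state) {
  if (is.null(names(state))) {
    if (length(state) != length(network$nodes)) {
      stop("state length does not match node count")
    }
    names(state) <- network$nodes
  }
  if (!setequal(names(state), network$nodes)) {
    stop("state names do not match network nodes")
  }
  st <- as.integer(state[network$nodes])
  if (any(is.na(st)) || any(!st %in% c(0L, 1L))) stop("state must be 0/1")
  names(st) <- network$nodes
  st
}

#' Synchronous update of a network state
#'
#' All nodes are updated simultaneously: each node's next value is its rule
#' evaluated on the current state.  Input nodes never change.
#'
#' @param network A [boolean_network()].
#' @param state Named 0/1 vector over the network's nodes (or unnamed in
#'   node order).
#' @return The successor state, a named 0/1 integer vector in node order.
#' @export
synchronous_step <- function(network, state) {
  st <- check_state(network, state)
  env <- lapply(as.list(st), as.logical)
  out <- vapply(network$compiled, function(lang) {
    as.integer(eval(lang, envir = env))
  }, integer(1))
  names(out) <- network$nodes
  out
}

## Vectorized step: `states` is a 0/1 matrix with one column per node.
## Returns the matrix of successor states.
step_states <- function(network, states) {
  stopifnot(identical(colnames(states), network$nodes))
  env <- lapply(seq_along(network$nodes), function(j) as.logical(states[, j]))
  names(env) <- network$nodes
  nr <- nrow(states)
  out <- vapply(network$compiled, function(lang) {
    v <- eval(lang, envir = env)
    if (length(v) == 1L) v <- rep(v, nr)  # constant rule
    as.integer(v)
  }, integer(nr))
  if (nr == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- network$nodes
  out
}

## Dependency graph: edge u -> v iff u appears in v's rule.
## Returned as a named list: for each node, the character vector of its
## regulators (parents).
dependency_parents <- function(network) {
  lapply(network$rules, free_variables)
}

#' Condition a network on a partial assignment
#'
#' Clamps the assigned nodes to constants and propagates constants through
#' the rules until closure: a rule that simplifies to a constant makes its
#' node constant too.  The remaining free sub-network is returned together
#' with the record of forced values.
#'
#' @param network A [boolean_network()].
#' @param assignment Named 0/1 vector of nodes to clamp.
#' @return List with elements `network` (the free sub-network; no inputs)
#'   and `forced` (named integer vector of clamped and propagated values).
#' @export
condition_network <- function(network, assignment) {
  nms <- names(assignment)
  if (length(assignment) > 0L && is.null(nms)) {
    stop("assignment must be named")
  }
  assignment <- as.integer(assignment)
  names(assignment) <- nms
  unknown <- setdiff(names(assignment), network$nodes)
  if (length(unknown) > 0L) stop("unknown node(s): ", paste(unknown, collapse = ", "))
  for (n in names(assignment)) {
    e <- strip_attr(network$rules[[n]])
    if (e$type == "const" && e$value != assignment[[n]]) {
      stop("node '", n, "' is clamped to ", e$value,
           " and cannot be conditioned to ", assignment[[n]])
    }
  }
  known <- as.list(assignment)
  free <- setdiff(network$nodes, names(known))
  simplified <- network$rules[free]
  repeat {
    newly <- character(0)
    for (n in free) {
      s <- simplify_expr(strip_attr(simplified[[n]]), known)
      simplified[[n]] <- s
      if (s$type == "const") {
        known[[n]] <- s$value
        newly <- c(newly, n)
      }
    }
    if (length(newly) == 0L) break
    free <- setdiff(free, newly)
    simplified <- simplified[free]
  }
  forced <- unlist(known)
  if (is.null(forced)) forced <- integer(0)
  core <- if (length(free) > 0L) {
    boolean_network(simplified[free], inputs = character(0))
  } else {
    NULL
  }
  list(network = core, forced = forced[order(match(names(forced), network$nodes))])
}

## Does the digraph (parents list) contain a directed cycle among `nodes`?
## Returns NULL or one offending cycle as a character vector.
find_cycle <- function(parents, nodes) {
  color <- setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  stack <- character(0)
  cycle <- NULL
  visit <- function(v) {
    if (!is.null(cycle)) return(invisible(NULL))
    color[[v]] <<- 1L
    stack <<- c(stack, v)
    for (u in intersect(parents[[v]], nodes)) {
      if (!is.null(cycle)) break
      if (color[[u]] == 1L) {
        i <- match(u, stack)
        cycle <<- stack[i:length(stack)]
      } else if (color[[u]] == 0L) {
        visit(u)
      }
    }
    color[[v]] <<- 2L
    stack <<- stack[-length(stack)]
    invisible(NULL)
  }
  for (v in nodes) {
    if (color[[v]] == 0L) visit(v)
    if (!is.null(cycle)) break
  }
  cycle
}

#' Feedback vertex set of the dependency graph
#'
#' Returns a set of nodes touching every directed cycle of the network's
#' dependency digraph (edge `u -> v` iff `u` appears in `v`'s rule).  Fixing
#' the values of these nodes makes the remaining graph acyclic, which is the
#' basis of the exact fixed-point solver.  The set is found greedily
#' (repeatedly removing the highest-degree node on some cycle), so it is
#' correct but not guaranteed minimum.
#'
#' @param network A [boolean_network()].
#' @return Character vector of node names (possibly empty).
#' @export
feedback_vertex_set <- function(network) {
  parents <- dependency_parents(network)
  nodes <- network$nodes
  fvs <- character(0)
  repeat {
    cyc <- find_cycle(parents, nodes)
    if (is.null(cyc)) break
    # pick the cycle node with the largest in*out degree in the current graph
    indeg <- vapply(cyc, function(v) length(intersect(parents[[v]], nodes)),
                    integer(1))
    outdeg <- vapply(cyc, function(v) {
      sum(vapply(nodes, function(w) v %in% parents[[w]], logical(1)))
    }, integer(1))
    pick <- cyc[which.max(indeg * outdeg)]
    fvs <- c(fvs, pick)
    nodes <- setdiff(nodes, pick)
  }
  fvs[order(match(fvs, network$nodes))]
}

## Topological order of `nodes` under the parents relation restricted to
## `nodes`.  Assumes acyclicity (guaranteed after FVS removal).
topological_order <- function(parents, nodes) {
  order <- character(0)
  done <- character(0)
  remaining <- nodes
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(n) {
      length(setdiff(intersect(parents[[n]], nodes), done)) == 0L
    }, logical(1))]
    if (length(ready) == 0L) stop("dependency graph is not acyclic")
    order <- c(order, ready)
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}
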