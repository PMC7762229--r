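test_that("synchronous update evaluates every rule on the current state", {
  ff <- net_flipflop()
  expect_equal(unname(synchronous_step(ff, c(A = 0, B = 1))), c(1L, 0L))
  neg <- net_negation()
  expect_equal(unname(synchronous_step(neg, c(C = 0))), 1L)
  expect_equal(unname(synchronous_step(neg, c(C = 1))), 0L)
  # a fixed point maps to itself
  expect_equal(unname(synchronous_step(ff, c(A = 1, B = 1))), c(1L, 1L))
  expect_error(synchronous_step(ff, c(A = 1)), "state")
})

test_that("input nodes stay constant along trajectories", {
  net <- boolean_network(c(I = "I", A = "I or B", B = "A and not I"))
  for (iv in 0:1) {
    st <- c(I = iv, A = 0, B = 1)
    for (k in 1:6) {
      st <- synchronous_step(net, st)
      expect_equal(unname(st["I"]), iv)
    }
  }
})

test_that("conditioning clamps and propagates constants to closure", {
  # the bundled model with every signal off: the receptor layer collapses
  cond <- condition_network(bundled_model$network,
                            setNames(rep(0L, 10), bundled_model$network$inputs))
  forced0 <- names(which(cond$forced == 0L))
  expect_true(all(c("TLR4", "FCGR", "IL4RA", "MCSFR", "CSF2RA", "RAGE")
                  %in% forced0))
  expect_false("STAT3" %in% names(cond$forced))  # self-sustaining, stays free

  r <- condition_network(net_flipflop(), c(A = 1L))
  expect_null(r$network)
  expect_equal(r$forced, c(A = 1L, B = 1L))

  r <- condition_network(net_flipflop(), setNames(integer(0), character(0)))
  expect_equal(sort(r$network$nodes), c("A", "B"))
  expect_length(r$forced, 0)

  clamped <- boolean_network(list(A = macpol:::bool_const(1L), B = "A"))
  expect_error(condition_network(clamped, c(A = 0L)), "clamped")
})

test_that("feedback vertex sets touch every cycle", {
  acyclic <- boolean_network(c(A = "B", B = "C", C = "0"))
  expect_length(feedback_vertex_set(acyclic), 0)
  expect_length(feedback_vertex_set(net_flipflop()), 1)
  tri <- boolean_network(c(A = "B", B = "C", C = "A"))
  expect_length(feedback_vertex_set(tri), 1)
  # property: removing the FVS leaves the dependency graph acyclic
  for (sd in 1:20) {
    net <- random_network(10, 2, max_in_degree = 3, seed = sd)
    fvs <- feedback_vertex_set(net)
    remaining <- setdiff(net$nodes, fvs)
    expect_null(macpol:::find_cycle(macpol:::dependency_parents(net), remaining))
  }
})

test_that("fixed-point solver matches hand enumeration on toys", {
  fp <- enumerate_fixed_points(net_flipflop(), setNames(integer(0), character(0)))
  expect_equal(state_keys(fp), c("00", "11"))
  fp <- enumerate_fixed_points(net_negation(), setNames(integer(0), character(0)))
  expect_equal(nrow(fp), 0)
  one_input <- boolean_network(c(I = "I", A = "I"))
  all_fp <- enumerate_all_fixed_points(one_input)
  expect_equal(state_keys(all_fp), c("00", "11"))
  expect_error(enumerate_all_fixed_points(
    random_network(25, 21, seed = 1)), "refusing")
})

test_that("solver equals the exhaustive oracle on seeded random networks", {
  for (sd in 1:80) {
    n <- 6L + (sd %% 6L)
    k <- sd %% 3L
    style <- if (sd %% 2L == 0L) "random_and_or_not" else "random_truth_table"
    net <- random_network(n, k, max_in_degree = 3,
                          expression_style = style, seed = sd)
    for (assign in all_input_assignments(net)) {
      got <- state_keys(enumerate_fixed_points(net, assign))
      expect_identical(got, oracle_fixed_point_keys(net, assign))
    }
  }
})

test_that("fixed points are independent of the feedback vertex set used", {
  a <- enumerate_fixed_points(net_flipflop(), setNames(integer(0), character(0)),
                              fvs = "A")
  b <- enumerate_fixed_points(net_flipflop(), setNames(integer(0), character(0)),
                              fvs = "B")
  expect_identical(state_keys(a), state_keys(b))
  for (sd in 1:10) {
    net <- random_network(10, 2, max_in_degree = 3, seed = sd)
    assign <- all_input_assignments(net)[[2]]
    default_fvs <- state_keys(enumerate_fixed_points(net, assign))
    # a strictly larger cycle cover must give the same answer
    bigger <- union(feedback_vertex_set(net), setdiff(net$nodes, net$inputs)[1])
    expect_identical(state_keys(enumerate_fixed_points(net, assign, fvs = bigger)),
                     default_fvs)
  }
})

test_that("exhaustive oracle recovers cycles and is deterministic", {
  atts <- brute_force_attractors(net_negation())
  expect_length(atts, 1)
  expect_equal(atts[[1]]$period, 2)

  atts <- brute_force_attractors(net_flipflop())
  periods <- sort(vapply(atts, `[[`, integer(1), "period"))
  expect_equal(periods, c(1L, 1L, 2L))

  n1 <- brute_force_attractors(random_network(10, 0, seed = 3))
  n2 <- brute_force_attractors(random_network(10, 0, seed = 3))
  expect_identical(n1, n2)
  expect_error(brute_force_attractors(random_network(25, 0, seed = 1)), "oracle")
})

test_that("trajectory simulation reports the attractor entered", {
  ff <- net_flipflop()
  r <- simulate_network(ff, c(A = 1, B = 1))
  expect_equal(r$period, 1)
  expect_equal(nrow(r$trajectory), 1)

  r <- simulate_network(net_negation(), c(C = 0))
  expect_equal(r$period, 2)
  expect_equal(nrow(r$attractor), 2)

  r <- simulate_network(net_negation(), c(C = 0), max_steps = 1)
  expect_true(is.na(r$period) || r$period == 2)
})
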