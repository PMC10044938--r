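test_that("constraint mask applies pairing rules and minimum separation", {
  # A-A can never pair
  expect_true(all(build_constraint_mask(rna_sequence("AAAAAAA")) == 0))
  # GAAAC: only the G-C pair at separation 4 survives (checked over all cells)
  m <- build_constraint_mask(rna_sequence("GAAAC"))
  expect_identical(which(m == 1), c(5L, 21L))  # (5,1) and (1,5)
  # no admissible cell ever sits closer than 4
  set.seed(31)
  for (rep in 1:20) {
    s <- random_rna(sample(10:40, 1))
    m <- build_constraint_mask(s)
    expect_true(all(abs(row(m) - col(m))[m == 1] >= 4))
    expect_identical(m, t(m))
  }
})

test_that("relaxed solver honors trivial optima", {
  s <- random_rna(12L)
  mask <- build_constraint_mask(s)
  # all-negative scores: empty structure is optimal
  rel <- relaxed_primal_dual_solve(matrix(-1, 12, 12), mask)
  expect_true(all(rel == 0))
  # a single strongly positive admissible cell saturates to 1
  s2 <- rna_sequence("GAAAC")
  mask2 <- build_constraint_mask(s2)
  S2 <- matrix(0, 5, 5); S2[1, 5] <- S2[5, 1] <- 10
  rel2 <- relaxed_primal_dual_solve(S2, mask2)
  expect_equal(rel2[1, 5], 1)
  expect_error(relaxed_primal_dual_solve(matrix(rnorm(25), 5), mask2),
               "not symmetric")
})

test_that("relaxed objective tracks the integer optimum from above", {
  # weak duality: the relaxed program upper-bounds the integer one; the
  # finite-iteration iterate is allowed a small convergence slack
  set.seed(5)
  for (rep in 1:25) {
    s <- random_rna(10L)
    S <- random_score_map(10L)
    mask <- build_constraint_mask(s)
    rel <- relaxed_primal_dual_solve(S, mask)
    bf <- brute_force_optimum(S, mask, rho = 0.01)
    expect_gte(contact_objective(S, rel, rho = 0.01), bf$objective - 0.35)
  }
})

test_that("discretize rounds greedily and guarantees feasibility", {
  s <- random_rna(12L)
  mask <- matrix(1, 12, 12) - diag(12)
  expect_equal(sum(discretize(matrix(0, 12, 12), mask)), 0)
  # two cells fighting over base 1: the stronger wins
  rel <- matrix(0, 12, 12)
  rel[1, 6] <- rel[6, 1] <- 0.9
  rel[1, 9] <- rel[9, 1] <- 0.8
  P <- discretize(rel, mask, 0.5)
  expect_equal(P[1, 6], 1)
  expect_equal(P[1, 9], 0)
  # row sums stay <= 1 on arbitrary relaxed inputs
  set.seed(13)
  for (rep in 1:200) {
    L <- sample(6:20, 1)
    rel <- matrix(runif(L * L), L); rel <- (rel + t(rel)) / 2
    P <- discretize(rel, matrix(1, L, L) - diag(L), 0.3)
    expect_true(all(rowSums(P) <= 1))
    expect_identical(P, t(P))
  }
})

test_that("decoded structures are always feasible, even for adversarial scores", {
  set.seed(17)
  for (rep in 1:50) {
    L <- sample(20:60, 1)
    s <- random_rna(L)
    S <- random_score_map(L, sd = 5)
    P <- predict_structure(s, S)
    expect_true(is_feasible_structure(s, P))
  }
})

test_that("decoder reaches the brute-force optimum on small instances", {
  set.seed(42)
  ok <- 0
  n <- 60
  for (rep in seq_len(n)) {
    L <- sample(8:12, 1)
    s <- random_rna(L)
    S <- random_score_map(L)
    mask <- build_constraint_mask(s)
    cfg <- solver_config()
    P <- predict_structure(s, S, cfg)
    bf <- brute_force_optimum(S, mask, cfg$rho)
    if (contact_objective(S, P, cfg$rho) >= 0.99 * bf$objective - 1e-9)
      ok <- ok + 1
  }
  expect_gte(ok / n, 0.95)
})

test_that("branch-and-bound and bitmask-DP oracles agree", {
  set.seed(8)
  for (rep in 1:60) {
    L <- sample(6:11, 1)
    s <- random_rna(L)
    S <- random_score_map(L)
    mask <- build_constraint_mask(s)
    bf <- brute_force_optimum(S, mask, rho = 0.05)
    expect_equal(bf$objective, dp_matching_optimum(S, mask, rho = 0.05),
                 tolerance = 1e-10)
  }
  # trivial cases
  empty <- brute_force_optimum(matrix(0, 5, 5), matrix(0, 5, 5), 0)
  expect_equal(empty$objective, 0)
  expect_equal(sum(empty$contact_map), 0)
  one <- matrix(0, 6, 6); one[1, 6] <- one[6, 1] <- 1
  mask1 <- matrix(0, 6, 6); mask1[1, 6] <- mask1[6, 1] <- 1
  bf1 <- brute_force_optimum(one, mask1, 0)
  expect_equal(bf1$objective, 2)  # both symmetric cells counted
  expect_equal(bf1$contact_map[1, 6], 1)
  expect_error(brute_force_optimum(matrix(0, 20, 20), matrix(0, 20, 20), 0),
               "L <= 14")
})

test_that("crossing pairs are recovered when the scores favor them", {
  # A...G...U...C with strong scores on the crossing pairs (1,9) A-U and
  # (5,13) G-C; a nested-only decoder could keep at most one of them
  bases <- rep("A", 13)
  bases[5] <- "G"; bases[9] <- "U"; bases[13] <- "C"
  s <- rna_sequence(bases)
  S <- matrix(0, 13, 13)
  S[1, 9] <- S[9, 1] <- 5
  S[5, 13] <- S[13, 5] <- 5
  P <- predict_structure(s, S)
  expect_equal(P[1, 9], 1)
  expect_equal(P[5, 13], 1)
  pairs <- contact_pairs(P)
  expect_true(rnafoldnet:::has_crossing_pairs(pairs))
})

test_that("uniform zero scores with positive rho give an empty structure", {
  s <- random_rna(20L)
  P <- predict_structure(s, matrix(0, 20, 20), solver_config(rho = 0.1))
  expect_equal(sum(P), 0)
})

test_that("predicted pair count is non-increasing in rho", {
  # the exact program is provably monotone in rho; check it on the oracle
  set.seed(77)
  for (rep in 1:15) {
    s <- random_rna(11L)
    S <- random_score_map(11L)
    mask <- build_constraint_mask(s)
    np <- vapply(c(0, 0.2, 0.5, 1), function(r)
      sum(brute_force_optimum(S, mask, r)$contact_map) / 2, 0)
    expect_true(all(diff(np) <= 0))
  }
  # for the relaxed pipeline, a generous iteration budget isolates the rho
  # effect from finite-iteration rounding noise
  set.seed(23)
  for (rep in 1:5) {
    L <- 30
    s <- random_rna(L)
    S <- random_score_map(L)
    n_pairs <- vapply(c(0, 0.1, 0.3, 0.6, 1, 2), function(r) {
      sum(predict_structure(s, S, solver_config(rho = r,
                                                iterations = 1500L))) / 2
    }, 0)
    expect_true(all(diff(n_pairs) <= 0))
  }
})
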