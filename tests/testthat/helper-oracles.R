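# shared test helpers: random instances and independent exact oracles

random_rna <- function(L) {
  rna_sequence(paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                     collapse = ""))
}

random_score_map <- function(L, sd = 1) {
  S <- matrix(rnorm(L * L, sd = sd), L)
  (S + t(S)) / 2
}

# independent exact oracle for the decoding program: bitmask dynamic program
# over subsets of available bases (maximum-weight matching on admissible
# cells, weight 2*(s_ij - rho) per pair); a different algorithm from the
# package's branch-and-bound enumeration, so the two can cross-check
dp_matching_optimum <- function(S, mask, rho) {
  L <- nrow(S)
  stopifnot(L <= 14)
  memo <- rep(NA_real_, 2^L)
  solve <- function(s) {
    if (s == 0) return(0)
    if (!is.na(memo[s + 1])) return(memo[s + 1])
    i <- which(bitwAnd(s, 2^(0:(L - 1))) != 0)[1]
    best <- solve(s - 2^(i - 1))
    for (j in seq_len(L)) {
      if (j > i && bitwAnd(s, 2^(j - 1)) != 0 && mask[i, j] > 0) {
        w <- 2 * (S[i, j] - rho)
        if (w > 0) {
          cand <- w + solve(s - 2^(i - 1) - 2^(j - 1))
          if (cand > best) best <- cand
        }
      }
    }
    memo[s + 1] <<- best
    best
  }
  solve(2^L - 1)
}

# structure feasibility: pairing rule, separation >= 4, one partner each
is_feasible_structure <- function(seq, P) {
  mask <- build_constraint_mask(seq)
  all(P %in% c(0, 1)) &&
    all(P == t(P)) &&
    all(P[mask == 0] == 0) &&
    all(rowSums(P) <= 1)
}

tiny_net_config <- function() {
  network_config(feature_channels = 4L, dcm_layers = 2L, growth = 3L,
                 num_levels = 2L)
}
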