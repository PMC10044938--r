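# Pairs admissible under canonical Watson-Crick + wobble rules
.CANONICAL <- c("AU", "CG", "GU")

#' Solver configuration for constrained decoding
#'
#' @param rho L1 sparsity coefficient; larger values prune weak pairs. The
#'   decoding objective is \code{<S, P> - rho * ||P||_1}; a negative
#'   \code{rho} turns the penalty into the reward form of the same program.
#' @param step_primal projected-gradient step on the relaxed contact map
#' @param step_dual ascent step on the row-sum multipliers
#' @param iterations primal-dual sweeps; feasibility of the output never
#'   depends on convergence, only solution quality does
#' @param binarize_threshold relaxed values at or above this enter the
#'   greedy rounding stage, in (0, 1)
#' @param seed reserved for stochastic variants; the default solver is
#'   deterministic
#' @return list of class \code{solver_config}
#' @export
solver_config <- function(rho = 0.01, step_primal = 0.1, step_dual = 0.05,
                          iterations = 400L, binarize_threshold = 0.5,
                          seed = 1L) {
  stopifnot(iterations >= 1L,
            binarize_threshold > 0, binarize_threshold < 1,
            step_primal > 0, step_dual > 0)
  structure(list(rho = rho, step_primal = step_primal, step_dual = step_dual,
                 iterations = as.integer(iterations),
                 binarize_threshold = binarize_threshold,
                 seed = as.integer(seed)),
            class = "solver_config")
}

#' Hard-constraint mask for admissible base pairs
#'
#' Binary symmetric L x L matrix with 1 at (i, j) iff bases i and j may
#' pair: the pair is canonical or wobble (\{A,U\}, \{C,G\}, \{G,U\}) and the
#' separation satisfies |i - j| >= 4, which enforces the minimum hairpin
#' loop.
#'
#' @param seq an \code{\link{rna_sequence}}
#' @return binary L x L matrix
#' @export
build_constraint_mask <- function(seq) {
  L <- length(seq)
  b <- seq$bases
  sorted_pair <- function(x, y) paste0(pmin(x, y), pmax(x, y))
  pm <- matrix(sorted_pair(rep(b, times = L), rep(b, each = L)), L, L)
  mask <- matrix(as.numeric(pm %in% .CANONICAL), L, L)
  sep <- abs(row(mask) - col(mask))
  mask[sep < 4] <- 0
  mask
}

#' Relaxed primal-dual solve of the decoding program
#'
#' Maximizes \code{<S, P> - rho * ||P||_1} over relaxed contact maps
#' \code{P} in [0,1]^(L x L), supported on the constraint mask and symmetric,
#' subject to row sums (1/2)(P + P^T) 1 <= 1 enforced through non-negative
#' Lagrange multipliers. Projected gradient ascent on P alternates with
#' multiplier ascent on the row-sum violations; each primal iterate is
#' re-symmetrized, clipped to [0,1], and zeroed off-mask, so every iterate is
#' box-feasible even if the multipliers have not converged.
#'
#' @param S symmetric L x L score map
#' @param mask binary mask from \code{\link{build_constraint_mask}}
#' @param cfg a \code{\link{solver_config}}
#' @return relaxed L x L matrix with entries in [0, 1]
#' @export
relaxed_primal_dual_solve <- function(S, mask, cfg = solver_config()) {
  if (nrow(S) != ncol(S)) stop("score map must be square")
  if (max(abs(S - t(S))) > 1e-4) stop("score map is not symmetric")
  if (!all(dim(S) == dim(mask))) stop("score map and mask shapes disagree")
  L <- nrow(S)
  P <- matrix(0, L, L)
  lambda <- numeric(L)
  G0 <- S - cfg$rho
  for (it in seq_len(cfg$iterations)) {
    grad <- G0 - outer(lambda, lambda, "+")
    P <- P + cfg$step_primal * grad
    P <- (P + t(P)) / 2
    P[mask == 0] <- 0
    P[P < 0] <- 0
    P[P > 1] <- 1
    lambda <- pmax(0, lambda + cfg$step_dual * (rowSums(P) - 1))
  }
  P
}

#' Round a relaxed contact map to a feasible structure
#'
#' Candidate cells are the upper-triangle cells on the mask whose relaxed
#' value reaches the threshold; they are accepted greedily in descending
#' relaxed value (ties broken by smallest (i, j)), skipping any cell whose
#' row or column already holds an accepted pair. The output therefore
#' satisfies the one-partner constraint unconditionally.
#'
#' @param relaxed L x L matrix in [0, 1]
#' @param mask binary constraint mask
#' @param threshold acceptance threshold in (0, 1)
#' @return binary symmetric L x L contact map
#' @export
discretize <- function(relaxed, mask, threshold = 0.5) {
  L <- nrow(relaxed)
  P <- matrix(0, L, L)
  idx <- which(upper.tri(relaxed) & mask > 0 & relaxed >= threshold)
  if (length(idx) == 0L) return(P)
  ii <- ((idx - 1L) %% L) + 1L
  jj <- ((idx - 1L) %/% L) + 1L
  vv <- relaxed[idx]
  ord <- order(-vv, ii, jj)
  used <- logical(L)
  for (k in ord) {
    i <- ii[k]; j <- jj[k]
    if (!used[i] && !used[j]) {
      used[i] <- used[j] <- TRUE
      P[i, j] <- P[j, i] <- 1
    }
  }
  P
}

#' Decode a score map into a predicted structure
#'
#' Full decoding pipeline: build the hard-constraint mask for the sequence,
#' run the relaxed primal-dual solver, and round to a feasible contact map.
#' Crossing (pseudoknotted) pairs are permitted: nothing in the program
#' forbids i1 < i2 < j1 < j2 with pairs (i1, j1), (i2, j2).
#'
#' @param seq an \code{\link{rna_sequence}}
#' @param S symmetric L x L score map (used as produced by the network; any
#'   affine shift interacts with \code{rho})
#' @param cfg a \code{\link{solver_config}}
#' @return binary symmetric L x L contact map
#' @export
predict_structure <- function(seq, S, cfg = solver_config()) {
  if (length(seq) != nrow(S)) stop("sequence length and score map size disagree")
  mask <- build_constraint_mask(seq)
  relaxed <- relaxed_primal_dual_solve(S, mask, cfg)
  discretize(relaxed, mask, cfg$binarize_threshold)
}

#' Integer objective of a contact map
#'
#' \code{<S, P> - rho * ||P||_1} over the full (symmetric) matrices; each
#' selected pair i < j contributes \code{2 * (S[i,j] - rho)}.
#'
#' @param S score map
#' @param P binary contact map
#' @param rho sparsity coefficient
#' @return scalar objective value
#' @export
contact_objective <- function(S, P, rho = 0) {
  sum(S * P) - rho * sum(P)
}

#' Pair-set view of a contact map
#'
#' @param P binary symmetric contact map
#' @return integer matrix with columns i, j (1-based, i < j)
#' @export
contact_pairs <- function(P) {
  idx <- which(upper.tri(P) & P > 0)
  L <- nrow(P)
  cbind(i = ((idx - 1L) %% L) + 1L, j = ((idx - 1L) %/% L) + 1L)
}

#' Contact map from a pair list
#'
#' @param pairs two-column matrix of 1-based (i, j)
#' @param L sequence length
#' @return binary symmetric L x L matrix with zero diagonal
#' @export
pairs_to_contact <- function(pairs, L) {
  P <- matrix(0, L, L)
  if (length(pairs) == 0L) return(P)
  pairs <- as.matrix(pairs)
  if (any(pairs < 1L) || any(pairs > L)) stop("pair index out of range")
  P[pairs] <- 1
  P[pairs[, c(2, 1), drop = FALSE]] <- 1
  diag(P) <- 0
  P
}

# exact optimum by branch-and-bound over positive-weight admissible edges;
# edges with weight <= 0 never belong to an optimum (dropping one keeps
# feasibility and cannot lower the objective)
#' Exhaustive optimum of the decoding program (testing oracle)
#'
#' Exact solution of the integer program the decoder relaxes: a maximum-weight
#' matching over admissible cells with weight \code{2 * (S[i,j] - rho)} per
#' pair, found by branch-and-bound enumeration. Only practical for small L.
#'
#' @param S symmetric score map
#' @param mask binary constraint mask
#' @param rho sparsity coefficient
#' @param max_L refuse instances larger than this (enumeration guard)
#' @return list with \code{objective} and binary \code{contact_map}
#' @export
brute_force_optimum <- function(S, mask, rho = 0, max_L = 14L) {
  L <- nrow(S)
  if (L > max_L) stop(sprintf("brute force limited to L <= %d", max_L))
  idx <- which(upper.tri(S) & mask > 0)
  ii <- ((idx - 1L) %% L) + 1L
  jj <- ((idx - 1L) %/% L) + 1L
  w <- 2 * (S[idx] - rho)
  keep <- w > 0
  ii <- ii[keep]; jj <- jj[keep]; w <- w[keep]
  ord <- order(-w)
  ii <- ii[ord]; jj <- jj[ord]; w <- w[ord]
  n <- length(w)
  suffix <- rev(cumsum(rev(c(w, 0))))  # upper bound on remaining gain
  best <- list(objective = 0, sel = integer(0))
  used <- logical(L)
  sel <- integer(0)
  recurse <- function(k, acc) {
    if (acc + suffix[k] <= best$objective + 1e-12) return()
    if (k > n) {
      if (acc > best$objective) best <<- list(objective = acc, sel = sel)
      return()
    }
    i <- ii[k]; j <- jj[k]
    if (!used[i] && !used[j]) {
      used[i] <<- used[j] <<- TRUE
      sel <<- c(sel, k)
      recurse(k + 1L, acc + w[k])
      sel <<- sel[-length(sel)]
      used[i] <<- used[j] <<- FALSE
    }
    recurse(k + 1L, acc)
  }
  if (n > 0L) recurse(1L, 0) else best <- list(objective = 0, sel = integer(0))
  P <- matrix(0, L, L)
  if (length(best$sel) > 0L) {
    for (k in best$sel) {
      P[ii[k], jj[k]] <- P[jj[k], ii[k]] <- 1
    }
  }
  list(objective = best$objective, contact_map = P)
}
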