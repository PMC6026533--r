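#' Exact Markov chain specification for a tiny population
#'
#' For very small N the full Wright-Fisher chain on haplotype-count states
#' is tractable: the state space is every composition of 2N gametes into the
#' four haplotypes, of size choose(2N + 3, 3) (35 states for N = 2, 165 for
#' N = 4). This gives exact absorption probabilities and expected fixation
#' times against which the stochastic simulator can be validated.
#'
#' @param N Diploid individuals, at most 4 (the state space grows as N^3).
#' @param scheme A fitness scheme.
#' @param r Recombination fraction in [0, 0.5].
#' @return A `chain_spec` list with the enumerated `states` matrix
#'   (one row per state, columns in `HAPLOTYPES` order).
#' @export
chain_spec <- function(N, scheme, r) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N) || N > 4)
    stop("`N` must be an integer in 1..4 (state space blows up beyond that)",
         call. = FALSE)
  if (!inherits(scheme, "fitness_scheme"))
    stop("`scheme` must be a fitness scheme", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 0.5)
    stop("`r` must be in [0, 0.5]", call. = FALSE)
  twoN <- 2L * as.integer(N)
  grid <- expand.grid(n1 = 0:twoN, n2 = 0:twoN, n3 = 0:twoN)
  grid <- grid[grid$n1 + grid$n2 + grid$n3 <= twoN, ]
  states <- cbind(grid$n1, grid$n2, grid$n3, twoN - grid$n1 - grid$n2 - grid$n3)
  colnames(states) <- HAPLOTYPES
  states <- states[order(-states[, 1], -states[, 2], -states[, 3]), , drop = FALSE]
  structure(list(N = as.integer(N), twoN = twoN, scheme = scheme, r = r,
                 states = states), class = "chain_spec")
}

#' Index of a count state within a chain's state enumeration
#' @param spec A [chain_spec()].
#' @param counts Integer vector of 4 haplotype counts summing to 2N.
#' @return The row index of `counts` in `spec$states`.
#' @export
state_index <- function(spec, counts) {
  stopifnot(inherits(spec, "chain_spec"))
  if (length(counts) != 4L || any(counts < 0) || sum(counts) != spec$twoN)
    stop("`counts` must be 4 non-negative counts summing to 2N", call. = FALSE)
  idx <- which(spec$states[, 1] == counts[1] & spec$states[, 2] == counts[2] &
                 spec$states[, 3] == counts[3])
  idx[1]
}

#' Exact one-generation transition matrix
#'
#' Entry (u, v) is the multinomial probability of sampling count state v
#' from 2N gametes with the expected gamete frequencies of state u (the same
#' deterministic recursion the simulator uses). Rows sum to 1; the four
#' single-haplotype corner states are absorbing.
#'
#' @param spec A [chain_spec()].
#' @return A row-stochastic matrix over `spec$states`.
#' @export
build_transition_matrix <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  S <- spec$states
  ns <- nrow(S)
  P <- matrix(0, ns, ns)
  for (u in seq_len(ns)) {
    xp <- expected_gamete_frequencies(S[u, ] / spec$twoN, spec$scheme, spec$r)
    for (v in seq_len(ns))
      P[u, v] <- stats::dmultinom(S[v, ], size = spec$twoN, prob = xp)
  }
  P
}

.corner_indices <- function(spec) {
  vapply(1:4, function(h) {
    counts <- integer(4); counts[h] <- spec$twoN
    state_index(spec, counts)
  }, integer(1))
}

.locus1_fixed <- function(spec) {
  cA <- spec$states[, 1] + spec$states[, 2]
  cA == 0L | cA == spec$twoN
}

#' Exact absorption probabilities and expected fixation times
#'
#' Solves the standard absorbing-chain linear systems: (i) the probability
#' of ultimate fixation of each of the four haplotypes (the corner states
#' are the only recurrent states of the mutation-free chain), and (ii) the
#' expected number of generations until locus 1 fixes, treating all states
#' with the locus-1 allele count at 0 or 2N as one lumped absorbing class
#' (matching what the simulator records), together with the probability that
#' locus 1 fixes on allele A.
#'
#' @param spec A [chain_spec()].
#' @param start Integer vector of 4 starting haplotype counts (sum 2N).
#' @param P Optional precomputed transition matrix from
#'   [build_transition_matrix()].
#' @return A list: `fixation_prob` (named, one per haplotype),
#'   `locus1_fix_A_prob`, `locus1_mean_fix_time`.
#' @export
absorption_summary <- function(spec, start, P = NULL) {
  stopifnot(inherits(spec, "chain_spec"))
  if (is.null(P)) P <- build_transition_matrix(spec)
  i0 <- state_index(spec, start)
  ns <- nrow(P)
  corners <- .corner_indices(spec)

  # (i) absorption into each corner
  transient <- setdiff(seq_len(ns), corners)
  fix_prob <- numeric(4); names(fix_prob) <- HAPLOTYPES
  if (i0 %in% corners) {
    fix_prob[match(i0, corners)] <- 1
  } else {
    Q <- P[transient, transient, drop = FALSE]
    R <- P[transient, corners, drop = FALSE]
    B <- solve(diag(length(transient)) - Q, R)
    fix_prob[] <- B[match(i0, transient), ]
  }

  # (ii) locus-1 fixation: lump all locus-1-fixed states as absorbing
  fixed1 <- .locus1_fixed(spec)
  t1 <- which(!fixed1)
  if (i0 %in% which(fixed1)) {
    mean_time <- 0
    pA <- as.numeric((spec$states[i0, 1] + spec$states[i0, 2]) == spec$twoN)
  } else {
    Q1 <- P[t1, t1, drop = FALSE]
    I1 <- diag(length(t1))
    row <- match(i0, t1)
    mean_time <- solve(I1 - Q1, rep(1, length(t1)))[row]
    # probability of hitting "A fixed" (cA = 2N) rather than "a fixed"
    RA <- P[t1, which(fixed1 & (spec$states[, 1] + spec$states[, 2]) == spec$twoN),
            drop = FALSE]
    pA <- solve(I1 - Q1, rowSums(RA))[row]
  }

  list(fixation_prob = fix_prob,
       locus1_fix_A_prob = pA,
       locus1_mean_fix_time = mean_time)
}

#' Probability that locus 1 is still polymorphic after g generations
#'
#' Propagates the exact state distribution g steps from a point mass on the
#' start state and sums the mass on states with both locus-1 alleles present.
#'
#' @inheritParams absorption_summary
#' @param g Number of generations (>= 0).
#' @return A probability.
#' @export
locus_polymorphic_prob <- function(spec, start, g, P = NULL) {
  stopifnot(inherits(spec, "chain_spec"))
  if (is.null(P)) P <- build_transition_matrix(spec)
  v <- numeric(nrow(P))
  v[state_index(spec, start)] <- 1
  for (i in seq_len(g)) v <- as.vector(v %*% P)
  sum(v[!.locus1_fixed(spec)])
}
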