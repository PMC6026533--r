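#' Convert a population-scaled recombination rate to a per-generation fraction
#'
#' rho = 4 * N_e * r, with N_e = 2N for a Wright-Fisher diploid population of
#' N individuals. The per-generation recombination fraction between two loci
#' is a probability bounded by 1/2 (free recombination), so values of rho
#' above 4 * N_e * 0.5 are clamped to r = 0.5 with a warning.
#'
#' @param rho Population-scaled recombination rate (>= 0).
#' @param N_e Effective population size (> 0).
#' @return Per-generation recombination fraction in [0, 0.5].
#' @examples
#' rho_to_r(4000, 2000) # 0.5: half of all gametes recombinant
#' rho_to_r(1, 2000)    # 1.25e-4
#' @export
rho_to_r <- function(rho, N_e) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0)
    stop("`rho` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(N_e) || length(N_e) != 1L || is.na(N_e) || N_e <= 0)
    stop("`N_e` must be a single positive number", call. = FALSE)
  r <- rho / (4 * N_e)
  if (r > 0.5) {
    warning(sprintf("rho = %g exceeds 4*N_e*0.5; clamping r to 0.5", rho),
            call. = FALSE)
    r <- 0.5
  }
  r
}

#' Deterministic two-locus selection-recombination recursion
#'
#' Expected gamete frequencies in the next generation under random mating,
#' viability selection and recombination. With haplotype frequencies
#' x = (x_AB, x_Ab, x_aB, x_ab), marginal fitnesses w_i = sum_j W[i,j] x_j,
#' mean fitness wbar = sum_i x_i w_i, the recursion is
#'
#'   x_AB' = (x_AB w_AB - r (W_AB,ab x_AB x_ab - W_Ab,aB x_Ab x_aB)) / wbar
#'
#' and symmetrically for the other haplotypes (coupling haplotypes AB, ab
#' lose recombinant gametes; repulsion haplotypes Ab, aB gain them). For both
#' fitness schemes here the two double-heterozygote fitnesses are equal, so
#' the correction reduces to the familiar -r * w_dh * D with
#' D = x_AB x_ab - x_Ab x_aB. Allele frequencies at each locus are unchanged
#' by the recombination term.
#'
#' @param x Numeric vector of 4 haplotype frequencies (order `HAPLOTYPES`),
#'   summing to 1.
#' @param scheme A fitness scheme.
#' @param r Recombination fraction in [0, 0.5].
#' @return Numeric vector of 4 expected gamete frequencies summing to 1.
#' @examples
#' expected_gamete_frequencies(c(0.5, 0, 0, 0.5), additive_scheme(0), 0.5)
#' @export
expected_gamete_frequencies <- function(x, scheme, r) {
  if (!is.numeric(x) || length(x) != 4L || anyNA(x) || any(x < 0))
    stop("`x` must be 4 non-negative haplotype frequencies", call. = FALSE)
  if (abs(sum(x) - 1) > 1e-8)
    stop("haplotype frequencies must sum to 1", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 0.5)
    stop("`r` must be in [0, 0.5]", call. = FALSE)
  W <- fitness_matrix(scheme)
  w <- as.vector(W %*% x)
  wbar <- sum(x * w)
  adj <- r * (W[1, 4] * x[1] * x[4] - W[2, 3] * x[2] * x[3])
  xp <- (x * w + c(-adj, adj, adj, -adj)) / wbar
  xp[xp < 0] <- 0 # guard float roundoff at boundaries
  xp / sum(xp)
}

#' One generation of multinomial drift
#'
#' Draws the 2N gametes of the next generation from a multinomial
#' distribution over the four haplotypes with the given expected frequencies.
#'
#' @param expected Numeric vector of 4 probabilities summing to 1.
#' @param N Number of diploid individuals (>= 1).
#' @return Integer vector of 4 haplotype counts summing to 2N.
#' @export
sample_next_generation <- function(expected, N) {
  if (!is.numeric(expected) || length(expected) != 4L || anyNA(expected) ||
      any(expected < 0) || abs(sum(expected) - 1) > 1e-8)
    stop("`expected` must be 4 probabilities summing to 1", call. = FALSE)
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1 || N != round(N))
    stop("`N` must be a positive integer", call. = FALSE)
  counts <- as.integer(stats::rmultinom(1, 2 * N, expected))
  names(counts) <- HAPLOTYPES
  counts
}

#' Initial haplotype counts
#'
#' `exact_quarters` puts each haplotype at exactly 25% of the 2N gametes
#' (allele frequencies 0.5 at both loci, linkage disequilibrium exactly 0);
#' requires 2N divisible by 4. `random_half` mimics mutating a uniformly
#' random half of the 2N genomes at locus 1 and, independently, another
#' random half at locus 2: allele frequencies are exactly 0.5 at both loci
#' while D is random with mean 0 (the AB count is hypergeometric).
#'
#' @param init_mode `"exact_quarters"` or `"random_half"`.
#' @param N Number of diploid individuals.
#' @param n Number of independent initializations to draw.
#' @return Integer matrix with `n` rows and 4 columns (counts out of 2N).
#' @export
initialize_state <- function(init_mode = c("exact_quarters", "random_half"),
                             N, n = 1L) {
  init_mode <- match.arg(init_mode)
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 2 || N != round(N))
    stop("`N` must be an integer >= 2", call. = FALSE)
  if (init_mode == "exact_quarters") {
    if ((2 * N) %% 4 != 0)
      stop("exact_quarters requires 2N divisible by 4 (even N)", call. = FALSE)
    counts <- matrix(as.integer(N / 2), nrow = n, ncol = 4)
  } else {
    k <- stats::rhyper(n, N, N, N) # overlap of the two mutated halves
    counts <- cbind(k, N - k, N - k, k)
    storage.mode(counts) <- "integer"
  }
  colnames(counts) <- HAPLOTYPES
  counts
}

#' Simulation parameters for one cell
#'
#' Bundles everything needed to simulate one parameter combination:
#' fitness scheme, diploid population size N (so N_e = 2N), population-scaled
#' recombination rate rho (r = min(rho / (4 N_e), 0.5)), maximum number of
#' generations G, initialization mode, replicate count and RNG seed.
#'
#' @param scheme A fitness scheme.
#' @param N Diploid individuals (default 1000).
#' @param rho Population-scaled recombination rate 4 * N_e * r (default 0).
#' @param G Maximum generations (default 1e5).
#' @param init_mode `"exact_quarters"` (default) or `"random_half"`.
#' @param replicates Number of replicate simulations (default 1000).
#' @param seed Optional RNG seed (integer) for this cell.
#' @return A `sim_params` list with derived fields `N_e` and `r`.
#' @export
sim_params <- function(scheme, N = 1000L, rho = 0, G = 100000L,
                       init_mode = c("exact_quarters", "random_half"),
                       replicates = 1000L, seed = NULL) {
  if (!inherits(scheme, "fitness_scheme"))
    stop("`scheme` must be a fitness scheme", call. = FALSE)
  init_mode <- match.arg(init_mode)
  if (N < 1 || N != round(N)) stop("`N` must be a positive integer", call. = FALSE)
  if (G < 1 || G != round(G)) stop("`G` must be a positive integer", call. = FALSE)
  if (replicates < 1 || replicates != round(replicates))
    stop("`replicates` must be a positive integer", call. = FALSE)
  N_e <- 2 * N
  structure(list(scheme = scheme, N = as.integer(N), rho = rho,
                 G = as.integer(G), init_mode = init_mode,
                 replicates = as.integer(replicates), seed = seed,
                 N_e = as.integer(N_e), r = rho_to_r(rho, N_e)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "sim_params: N = %d (N_e = %d), rho = %g (r = %g), G = %d, init = %s, %d replicates\n",
    x$N, x$N_e, x$rho, x$r, x$G, x$init_mode, x$replicates))
  print(x$scheme)
  invisible(x)
}

#' Classify the retained-haplotype outcome
#'
#' Five categories from the set of haplotypes still present at the end of a
#' replicate: `Fixed` (one haplotype, no polymorphism), `SimilarTwo` (two
#' haplotypes sharing the allele at one locus), `OppositeTwo` (two
#' haplotypes differing at both loci, i.e. AB/ab or Ab/aB), `Three`, `All`.
#'
#' @param final_presence Character vector of retained haplotype names
#'   (subset of `HAPLOTYPES`), or a logical/numeric vector of length 4
#'   marking presence in `HAPLOTYPES` order.
#' @return One of `"Fixed"`, `"SimilarTwo"`, `"OppositeTwo"`, `"Three"`,
#'   `"All"`.
#' @examples
#' classify_outcome(c("AB", "ab")) # "OppositeTwo"
#' @export
classify_outcome <- function(final_presence) {
  if (is.character(final_presence)) {
    if (!all(final_presence %in% HAPLOTYPES))
      stop("unknown haplotype name", call. = FALSE)
    present <- HAPLOTYPES %in% final_presence
  } else if (length(final_presence) == 4L) {
    present <- as.logical(final_presence > 0)
  } else {
    stop("`final_presence` must be haplotype names or a length-4 vector",
         call. = FALSE)
  }
  k <- sum(present)
  if (k == 0L) stop("`final_presence` must be non-empty", call. = FALSE)
  if (k == 1L) return("Fixed")
  if (k == 3L) return("Three")
  if (k == 4L) return("All")
  # two haplotypes: opposite iff they differ at both loci
  idx <- which(present)
  opposite <- (.hap_A[idx[1]] != .hap_A[idx[2]]) &&
              (.hap_B[idx[1]] != .hap_B[idx[2]])
  if (opposite) "OppositeTwo" else "SimilarTwo"
}

.outcome_levels <- c("Fixed", "SimilarTwo", "OppositeTwo", "Three", "All")

#' Run all replicates of one parameter cell
#'
#' Iterates the deterministic selection-recombination recursion followed by
#' one multinomial draw of 2N gametes per generation, for each replicate.
#' A locus is fixed once its allele count after sampling is 0 or 2N; without
#' mutation this is absorbing, and the first such generation is recorded
#' (the first sampled generation is generation 1). A replicate stops early
#' once both loci are fixed; a locus still polymorphic at G is censored
#' (`NA` fixation generation). Replicates where two complementary haplotypes
#' remain (AB/ab or Ab/aB) run until G like any other polymorphic state.
#'
#' @param params A [sim_params()] object.
#' @param trajectories If `TRUE`, also return per-generation allele
#'   frequencies (replicate, generation, freq_A, freq_B). Intended for small
#'   replicate counts; memory grows as replicates x generations.
#' @return A data.frame with one row per replicate: `replicate`, `outcome`,
#'   `fix_gen_locus1`, `fix_gen_locus2` (`NA` = censored at G), and the four
#'   final haplotype counts `n_AB`, `n_Ab`, `n_aB`, `n_ab`. When
#'   `trajectories = TRUE` the trajectory data.frame is attached as attribute
#'   `"trajectories"`. The `params` object is attached as attribute
#'   `"params"`.
#' @examples
#' p <- sim_params(additive_scheme(0.005), N = 100, rho = 0, G = 2000,
#'                 replicates = 20, seed = 1)
#' res <- run_cell(p)
#' table(res$outcome)
#' @export
run_cell <- function(params, trajectories = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  init <- initialize_state(params$init_mode, params$N, params$replicates)
  W <- fitness_matrix(params$scheme)
  out <- run_cell_cpp(W, params$r, params$N, params$G, init,
                      isTRUE(trajectories))
  finals <- out$final_counts
  colnames(finals) <- paste0("n_", HAPLOTYPES)
  outcome <- vapply(seq_len(nrow(finals)),
                    function(i) classify_outcome(finals[i, ] > 0), character(1))
  res <- data.frame(replicate = seq_len(params$replicates),
                    outcome = factor(outcome, levels = .outcome_levels),
                    fix_gen_locus1 = out$fix_gen_locus1,
                    fix_gen_locus2 = out$fix_gen_locus2,
                    finals)
  if (isTRUE(trajectories)) {
    tr <- as.data.frame(out$trajectories)
    names(tr) <- c("replicate", "generation", "freq_A", "freq_B")
    attr(res, "trajectories") <- tr
  }
  attr(res, "params") <- params
  res
}

#' Run a single replicate
#'
#' Convenience wrapper around [run_cell()] with one replicate; returns the
#' per-replicate record as a list.
#'
#' @inheritParams run_cell
#' @return A list with `outcome`, `fix_gen_locus1`, `fix_gen_locus2`,
#'   `final_presence` (character) and optionally `trajectory`.
#' @export
run_replicate <- function(params, trajectories = FALSE) {
  params$replicates <- 1L
  res <- run_cell(params, trajectories = trajectories)
  counts <- as.integer(res[1, paste0("n_", HAPLOTYPES)])
  out <- list(outcome = as.character(res$outcome[1]),
              fix_gen_locus1 = res$fix_gen_locus1[1],
              fix_gen_locus2 = res$fix_gen_locus2[1],
              final_presence = HAPLOTYPES[counts > 0])
  if (isTRUE(trajectories)) out$trajectory <- attr(res, "trajectories")
  out
}
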