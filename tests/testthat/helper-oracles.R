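# Independent brute-force oracle for the selection-recombination recursion:
# enumerate every ordered parental pair weighted by mating frequency and
# fitness, and distribute its gametes (parental with prob 1-r, recombinant
# with prob r). Shares no code with expected_gamete_frequencies().
enum_gamete_freqs <- function(x, scheme, r) {
  W <- fitness_matrix(scheme)
  hapA <- c(TRUE, TRUE, FALSE, FALSE)
  hapB <- c(TRUE, FALSE, TRUE, FALSE)
  hap_index <- function(a, b) which(hapA == a & hapB == b)
  g <- numeric(4)
  tot <- 0
  for (i in 1:4) for (j in 1:4) {
    wgt <- x[i] * x[j] * W[i, j]
    if (wgt == 0) next
    tot <- tot + wgt
    g[i] <- g[i] + wgt * (1 - r) / 2
    g[j] <- g[j] + wgt * (1 - r) / 2
    g[hap_index(hapA[i], hapB[j])] <- g[hap_index(hapA[i], hapB[j])] + wgt * r / 2
    g[hap_index(hapA[j], hapB[i])] <- g[hap_index(hapA[j], hapB[i])] + wgt * r / 2
  }
  g / tot
}

random_state <- function() {
  x <- stats::rgamma(4, 1)
  x / sum(x)
}

lin_disequilibrium <- function(x) x[1] * x[4] - x[2] * x[3]
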