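test_that("rho_to_r converts and clamps the recombination fraction", {
  expect_equal(rho_to_r(4000, 2000), 0.5) # half of all gametes recombinant
  expect_warning(r <- rho_to_r(9000, 2000), "clamping")
  expect_equal(r, 0.5)
  expect_equal(rho_to_r(0, 2000), 0)
  expect_equal(rho_to_r(1, 2000), 1.25e-4)
  expect_error(rho_to_r(-1, 2000), "non-negative")
})

test_that("deterministic recursion reproduces hand-derived cases", {
  # symmetric equilibrium is exactly invariant for both schemes, any r
  x0 <- rep(0.25, 4)
  for (sch in list(additive_scheme(0.008), multiplicative_scheme(1e6, 8e-9)))
    for (r in c(0, 0.1, 0.5))
      expect_equal(expected_gamete_frequencies(x0, sch, r), rep(0.25, 4))
  # neutral coupling-only state: recombination moves D = 0.25 down by r*D
  expect_equal(
    expected_gamete_frequencies(c(0.5, 0, 0, 0.5), additive_scheme(0), 0.5),
    c(0.375, 0.125, 0.125, 0.375))
  # locus 1 fixed on A; overdominance at locus 2 pushes freq(B) toward 0.5
  xp <- expected_gamete_frequencies(c(0.6, 0.4, 0, 0), additive_scheme(0.01), 0.3)
  expect_equal(xp[1], 0.6 * 1.004 / 1.0048, tolerance = 1e-12)
  expect_equal(xp[3], 0); expect_equal(xp[4], 0)
})

test_that("recursion matches brute-force parental-pair enumeration", {
  set.seed(42)
  for (sch in list(additive_scheme(0.012), multiplicative_scheme(1e6, 6e-9))) {
    for (k in 1:25) {
      x <- random_state()
      r <- stats::runif(1, 0, 0.5)
      expect_equal(expected_gamete_frequencies(x, sch, r),
                   enum_gamete_freqs(x, sch, r), tolerance = 1e-12)
    }
  }
})

test_that("recursion output is a frequency vector for random inputs", {
  set.seed(7)
  for (k in 1:50) {
    x <- random_state()
    sch <- additive_scheme(stats::runif(1, 0, 0.02))
    xp <- expected_gamete_frequencies(x, sch, stats::runif(1, 0, 0.5))
    expect_true(all(xp >= 0))
    expect_equal(sum(xp), 1)
  }
})

test_that("marginal allele-frequency dynamics do not depend on r", {
  set.seed(11)
  sch <- additive_scheme(0.01)
  for (k in 1:20) {
    x <- random_state()
    p0 <- expected_gamete_frequencies(x, sch, 0)
    p5 <- expected_gamete_frequencies(x, sch, 0.5)
    expect_equal(p0[1] + p0[2], p5[1] + p5[2], tolerance = 1e-14) # freq(A)
    expect_equal(p0[1] + p0[3], p5[1] + p5[3], tolerance = 1e-14) # freq(B)
  }
})

test_that("one step from linkage equilibrium leaves |D'| <= s^2/16", {
  sch <- additive_scheme(0.02)
  for (p in seq(0.1, 0.9, by = 0.2)) for (q in seq(0.1, 0.9, by = 0.2)) {
    x <- c(p * q, p * (1 - q), (1 - p) * q, (1 - p) * (1 - q)) # D = 0
    xp <- expected_gamete_frequencies(x, sch, 0)
    expect_lte(abs(lin_disequilibrium(xp)), 0.02^2 / 16 + 1e-15)
  }
})

test_that("multinomial sampling has the right support and moments", {
  expect_identical(sample_next_generation(c(1, 0, 0, 0), 500),
                   c(AB = 1000L, Ab = 0L, aB = 0L, ab = 0L))
  set.seed(5)
  draws <- replicate(1e4, sample_next_generation(rep(0.25, 4), 1000)[1])
  # mean 500, variance 2000 * 0.25 * 0.75 = 375
  expect_lt(abs(mean(draws) - 500), 4 * sqrt(375 / 1e4))
  expect_lt(abs(var(draws) - 375), 4 * 375 * sqrt(2 / 1e4))
  zeroed <- replicate(20, sample_next_generation(c(0.5, 0.5, 0, 0), 100))
  expect_true(all(zeroed[3:4, ] == 0))
})

test_that("initialization modes give exact 50% allele frequencies", {
  expect_identical(initialize_state("exact_quarters", 1000)[1, ],
                   c(AB = 500L, Ab = 500L, aB = 500L, ab = 500L))
  expect_error(initialize_state("exact_quarters", 3), "divisible")
  set.seed(9)
  cm <- initialize_state("random_half", 1000, n = 200)
  expect_true(all(cm[, "AB"] + cm[, "Ab"] == 1000)) # freq(A) = 0.5 always
  expect_true(all(cm[, "AB"] + cm[, "aB"] == 1000)) # freq(B) = 0.5 always
  expect_true(stats::sd(cm[, "AB"]) > 0)            # D random, not degenerate
  tiny <- initialize_state("random_half", 2, n = 50)
  expect_true(all(tiny[, "AB"] + tiny[, "Ab"] == 2))
  expect_true(all(rowSums(tiny) == 4))
})

test_that("outcome classification covers all five categories", {
  expect_identical(classify_outcome("AB"), "Fixed")
  expect_identical(classify_outcome(c("AB", "Ab")), "SimilarTwo")
  expect_identical(classify_outcome(c("aB", "ab")), "SimilarTwo")
  expect_identical(classify_outcome(c("AB", "ab")), "OppositeTwo")
  expect_identical(classify_outcome(c("Ab", "aB")), "OppositeTwo")
  expect_identical(classify_outcome(c("AB", "Ab", "aB")), "Three")
  expect_identical(classify_outcome(c("AB", "Ab", "aB", "ab")), "All")
  expect_identical(classify_outcome(c(3L, 0L, 0L, 5L)), "OppositeTwo")
  expect_error(classify_outcome(character(0)), "non-empty")
  expect_error(classify_outcome("XX"), "unknown")
})

test_that("replicates are reproducible given a seed", {
  p <- sim_params(additive_scheme(0.005), N = 100, rho = 1, G = 500,
                  replicates = 20, seed = 123)
  expect_identical(run_cell(p), run_cell(p))
})

test_that("fixation bookkeeping is consistent with final counts", {
  p <- sim_params(additive_scheme(0.002), N = 50, rho = 2, G = 2000,
                  replicates = 200, seed = 17)
  res <- run_cell(p)
  cA <- res$n_AB + res$n_Ab
  # locus 1 censored iff still polymorphic at the end
  expect_identical(is.na(res$fix_gen_locus1), cA > 0 & cA < 100)
  expect_true(all(res$fix_gen_locus1 >= 1 & res$fix_gen_locus1 <= 2000,
                  na.rm = TRUE))
  expect_true(all(rowSums(res[, paste0("n_", HAPLOTYPES)]) == 100))
  # Fixed outcome iff exactly one haplotype left
  nhap <- rowSums(res[, paste0("n_", HAPLOTYPES)] > 0)
  expect_identical(res$outcome == "Fixed", nhap == 1)
})

test_that("neutral fixation probability equals the initial frequency 0.5", {
  p <- sim_params(additive_scheme(0), N = 50, rho = 0, G = 5000,
                  replicates = 2000, seed = 31)
  res <- run_cell(p)
  expect_true(all(!is.na(res$fix_gen_locus1))) # G = 100 N_e: all fix
  fixed_on_A <- res$n_AB + res$n_Ab == 100
  bt <- stats::binom.test(sum(fixed_on_A), length(fixed_on_A), p = 0.5)
  expect_gt(bt$p.value, 1e-4)
})

test_that("neutral heterozygosity decays by 1 - 1/(2N) per generation", {
  N <- 100
  p <- sim_params(additive_scheme(0), N = N, rho = 0, G = 300,
                  replicates = 2000, seed = 57)
  tr <- attr(run_cell(p, trajectories = TRUE), "trajectories")
  het <- tapply(2 * tr$freq_A * (1 - tr$freq_A), tr$generation, mean)
  gens <- as.numeric(names(het))
  fit <- stats::lm(log(het) ~ gens)
  expect_equal(unname(stats::coef(fit)[2]), log(1 - 1 / (2 * N)),
               tolerance = 0.04)
})

test_that("free recombination makes the two loci independent", {
  # r = 0.5; joint retention should equal the product of the marginals
  N <- 100 # N_e = 200, N_e*s = 10, G = 10 N_e
  p <- sim_params(additive_scheme(0.05), N = N, rho = 4 * 2 * N * 0.5,
                  G = 2000, replicates = 2000, seed = 71)
  res <- run_cell(p)
  poly1 <- is.na(res$fix_gen_locus1)
  poly2 <- is.na(res$fix_gen_locus2)
  expect_gt(mean(poly1), 0.1) # informative margin, not degenerate
  expect_lt(mean(poly1), 0.9)
  ct <- stats::chisq.test(table(poly1, poly2))
  expect_gt(ct$p.value, 1e-4)
})

test_that("with perfect linkage the locus fixation times are correlated", {
  p <- sim_params(additive_scheme(0.005), N = 100, rho = 0, G = 4000,
                  replicates = 1000, seed = 83)
  res <- run_cell(p)
  both <- !is.na(res$fix_gen_locus1) & !is.na(res$fix_gen_locus2)
  expect_gt(sum(both), 100)
  expect_gt(stats::cor(res$fix_gen_locus1[both], res$fix_gen_locus2[both]), 0.3)
})

test_that("trajectories record per-generation allele frequencies", {
  p <- sim_params(additive_scheme(0.005), N = 100, rho = 0, G = 200,
                  replicates = 3, seed = 97)
  tr <- attr(run_cell(p, trajectories = TRUE), "trajectories")
  expect_named(tr, c("replicate", "generation", "freq_A", "freq_B"))
  expect_true(all(tr$freq_A >= 0 & tr$freq_A <= 1))
  # one row per surviving generation per replicate, starting at generation 1
  expect_identical(min(tr$generation), 1)
  expect_true(all(tapply(tr$generation, tr$replicate,
                         function(g) all(diff(sort(g)) == 1))))
})
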