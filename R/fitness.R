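#' Haplotype labels
#'
#' The four gamete haplotypes at two diallelic loci, in the fixed order used
#' throughout the package: locus-1 alleles A/a, locus-2 alleles B/b.
#' @export
HAPLOTYPES <- c("AB", "Ab", "aB", "ab")

# allele carried by haplotype h (1..4) at locus 1 (TRUE = A) and locus 2 (TRUE = B)
.hap_A <- c(TRUE, TRUE, FALSE, FALSE)
.hap_B <- c(TRUE, FALSE, TRUE, FALSE)

#' Additive overdominance fitness scheme
#'
#' Relative fitness is 1 for double homozygotes and increases by `s` for each
#' heterozygous locus, so single heterozygotes have fitness 1 + s and double
#' heterozygotes 1 + 2s. This scheme has no epistasis in the additive sense:
#' the residual a - b - c + d across the four genotype classes is exactly zero
#' (see [epistasis_residual()]).
#'
#' @param s Heterozygote advantage per locus (dimensionless relative fitness
#'   increment, `s >= 0`).
#' @return An object of class `c("additive_scheme", "fitness_scheme")`.
#' @examples
#' additive_scheme(0.005)
#' @seealso [multiplicative_scheme()], [genotype_fitness()]
#' @export
additive_scheme <- function(s) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0)
    stop("`s` must be a single non-negative number", call. = FALSE)
  structure(list(s = s), class = c("additive_scheme", "fitness_scheme"))
}

#' Multiplicative (large-dominance) fitness scheme
#'
#' Approximates symmetric overdominance the way a per-mutation simulator with
#' a dominance coefficient does: at each locus the derived allele (A at locus
#' 1, B at locus 2) contributes a multiplicative fitness factor of
#' 1 + d_dom * s_hom when heterozygous and 1 + s_hom when homozygous
#' (ancestral homozygote factor 1); total fitness is the product over loci.
#' With `d_dom` very large and `s_hom = s / d_dom` the heterozygote advantage
#' per locus equals `s` while the asymmetry between homozygotes (`s_hom`) is
#' negligible.
#'
#' @param d_dom Dominance coefficient (dimensionless, default 1e6).
#' @param s_hom Homozygote selection coefficient (`>= 0`); pick
#'   `s_hom = s / d_dom` to target a per-locus heterozygote advantage `s`.
#' @return An object of class `c("multiplicative_scheme", "fitness_scheme")`.
#' @examples
#' multiplicative_scheme(d_dom = 1e6, s_hom = 5e-9) # het advantage 0.005
#' @export
multiplicative_scheme <- function(d_dom = 1e6, s_hom) {
  if (!is.numeric(d_dom) || length(d_dom) != 1L || is.na(d_dom) || d_dom <= 0)
    stop("`d_dom` must be a single positive number", call. = FALSE)
  if (!is.numeric(s_hom) || length(s_hom) != 1L || is.na(s_hom) || s_hom < 0)
    stop("`s_hom` must be a single non-negative number", call. = FALSE)
  structure(list(d_dom = d_dom, s_hom = s_hom),
            class = c("multiplicative_scheme", "fitness_scheme"))
}

#' @export
print.fitness_scheme <- function(x, ...) {
  if (inherits(x, "additive_scheme")) {
    cat(sprintf("Additive overdominance scheme: s = %g (double het fitness %g)\n",
                x$s, 1 + 2 * x$s))
  } else {
    cat(sprintf(
      "Multiplicative scheme: d_dom = %g, s_hom = %g (het advantage %g per locus)\n",
      x$d_dom, x$s_hom, x$d_dom * x$s_hom))
  }
  invisible(x)
}

#' Heterozygote advantage targeted by a scheme
#'
#' The per-locus fitness increment of a heterozygote over the (ancestral)
#' homozygote: `s` for the additive scheme, `d_dom * s_hom` for the
#' multiplicative one.
#' @param scheme A fitness scheme.
#' @return A single number.
#' @export
het_advantage <- function(scheme) {
  if (inherits(scheme, "additive_scheme")) scheme$s else scheme$d_dom * scheme$s_hom
}

.check_hap_index <- function(i, arg) {
  if (!is.numeric(i) || length(i) != 1L || is.na(i) || i != round(i) ||
      i < 1 || i > 4)
    stop(sprintf("`%s` must be a haplotype index in 1..4 (1=AB, 2=Ab, 3=aB, 4=ab)",
                 arg), call. = FALSE)
  as.integer(i)
}

#' Diploid genotype fitness
#'
#' Relative fitness of the diploid formed by two gamete haplotypes.
#' Haplotypes are indexed 1=AB, 2=Ab, 3=aB, 4=ab (or given by name).
#' Additive scheme: 1 + s * (number of heterozygous loci). Multiplicative
#' scheme: product over loci of the per-locus factor (1 for ancestral
#' homozygote, 1 + s_hom for derived homozygote, 1 + d_dom * s_hom for
#' heterozygote). Symmetric in its two haplotype arguments.
#'
#' @param scheme A fitness scheme from [additive_scheme()] or
#'   [multiplicative_scheme()].
#' @param hap_i,hap_j Haplotype indices (1..4) or names (`"AB"`, `"Ab"`,
#'   `"aB"`, `"ab"`).
#' @return A positive relative fitness.
#' @examples
#' genotype_fitness(additive_scheme(0.005), "AB", "ab") # 1.01
#' @export
genotype_fitness <- function(scheme, hap_i, hap_j) {
  if (is.character(hap_i)) hap_i <- match(hap_i, HAPLOTYPES)
  if (is.character(hap_j)) hap_j <- match(hap_j, HAPLOTYPES)
  i <- .check_hap_index(hap_i, "hap_i")
  j <- .check_hap_index(hap_j, "hap_j")
  fitness_matrix(scheme)[i, j]
}

#' 4x4 genotype fitness matrix
#'
#' Fitness of every ordered pair of haplotypes; entry (i, j) is the fitness
#' of the diploid with gametes i and j. The matrix is symmetric.
#'
#' @param scheme A fitness scheme.
#' @return A symmetric 4x4 numeric matrix with dimnames `HAPLOTYPES`.
#' @export
fitness_matrix <- function(scheme) {
  if (!inherits(scheme, "fitness_scheme"))
    stop("`scheme` must be a fitness scheme", call. = FALSE)
  W <- matrix(0, 4, 4, dimnames = list(HAPLOTYPES, HAPLOTYPES))
  for (i in 1:4) for (j in 1:4) {
    het1 <- .hap_A[i] != .hap_A[j]
    het2 <- .hap_B[i] != .hap_B[j]
    if (inherits(scheme, "additive_scheme")) {
      W[i, j] <- 1 + scheme$s * (het1 + het2)
    } else {
      f1 <- if (het1) 1 + scheme$d_dom * scheme$s_hom
            else if (.hap_A[i]) 1 + scheme$s_hom else 1
      f2 <- if (het2) 1 + scheme$d_dom * scheme$s_hom
            else if (.hap_B[i]) 1 + scheme$s_hom else 1
      W[i, j] <- f1 * f2
    }
  }
  W
}

#' Additive epistasis residual
#'
#' The residual a - b - c + d across the four genotype classes along the
#' ancestral ladder, where a is the fitness of the double homozygote (ab/ab),
#' b and c are the two single-heterozygote fitnesses (ab/Ab and ab/aB) and d
#' is the double-heterozygote fitness (ab/AB). Zero residual means the two
#' loci contribute to fitness with no (additive-sense) epistasis; the
#' additive scheme satisfies this exactly, while the multiplicative scheme
#' leaves a residual equal to the square of the per-locus heterozygote
#' advantage.
#'
#' @param scheme A fitness scheme.
#' @return A single number (0 for the additive scheme).
#' @examples
#' epistasis_residual(additive_scheme(0.005))           # 0
#' epistasis_residual(multiplicative_scheme(1e6, 5e-9)) # 0.005^2
#' @export
epistasis_residual <- function(scheme) {
  W <- fitness_matrix(scheme)
  W["ab", "ab"] - W["ab", "Ab"] - W["ab", "aB"] + W["ab", "AB"]
}
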