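#' Median time to fixation with censoring
#'
#' Replicates still polymorphic at the horizon G are censored: their
#' (unknown) fixation time exceeds G, so they are ranked above every observed
#' fixation. The median of the augmented list is reported using the lower
#' of the two middle order statistics for even counts, so a defined MTF is
#' always an attained fixation generation. The MTF is undefined (NA) when
#' more than half of the replicates are censored, i.e. when fewer than half
#' fixed by G.
#'
#' @param fix_gens Integer vector of fixation generations, `NA` = censored.
#' @param G Simulation horizon in generations (used only for validation).
#' @return The median fixation generation, or `NA` if a majority of
#'   replicates are censored.
#' @examples
#' median_time_to_fixation(c(5, 10, NA), G = 100)       # 10
#' median_time_to_fixation(c(NA, NA, 7), G = 100)       # NA
#' @export
median_time_to_fixation <- function(fix_gens, G) {
  if (length(fix_gens) == 0L)
    stop("`fix_gens` must be non-empty", call. = FALSE)
  n <- length(fix_gens)
  n_cens <- sum(is.na(fix_gens))
  if (!all(is.na(fix_gens) | (fix_gens >= 1 & fix_gens <= G)))
    stop("fixation generations must lie in [1, G] or be NA (censored)",
         call. = FALSE)
  if (n_cens > n / 2) return(NA_real_)
  sorted <- sort(fix_gens, na.last = TRUE) # censored ranked last
  as.numeric(sorted[(n + 1L) %/% 2L])      # lower median
}

.slope_fit <- function(lx, ly) {
  fit <- stats::lm(ly ~ lx)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["lx", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       p_value = unname(cf["lx", "Pr(>|t|)"]))
}

#' Log-log regression of a response on rho
#'
#' Ordinary least squares of log(y) on log(rho) (natural logs; the
#' percent-per-halving transform is base-invariant). The two-sided p-value
#' is the usual t-test on the slope.
#'
#' @param rho Positive recombination-rate values.
#' @param y Positive responses (e.g. per-cell MTF); pairs with `NA` in `y`
#'   are dropped.
#' @return A list with `slope`, `intercept`, `p_value` and `n` (points used).
#' @examples
#' loglog_regression(c(0.1, 1, 10), c(100, 10, 1)) # slope -1
#' @export
loglog_regression <- function(rho, y) {
  keep <- !is.na(y)
  rho <- rho[keep]; y <- y[keep]
  if (length(rho) != length(y))
    stop("`rho` and `y` must have equal length", call. = FALSE)
  if (length(rho) < 3L)
    stop("need at least 3 points for the regression", call. = FALSE)
  if (any(rho <= 0) || any(y <= 0))
    stop("`rho` and `y` must be positive (log scale)", call. = FALSE)
  c(.slope_fit(log(rho), log(y)), n = length(rho))
}

#' Percent change per halving of rho
#'
#' Converts a log-log regression slope b into the percent increase in the
#' response caused by halving rho: (2^(-b) - 1) * 100. A slope of -1 (an
#' exact inverse power law) gives 100%: halving rho doubles the response.
#'
#' @param slope Log-log regression slope.
#' @return Percent increase per halving of rho.
#' @examples
#' percent_increase_per_halving(-1) # 100
#' @export
percent_increase_per_halving <- function(slope) {
  if (!is.finite(slope)) stop("`slope` must be finite", call. = FALSE)
  (2^(-slope) - 1) * 100
}

#' Log-log regression of the both-loci retention count on rho
#'
#' OLS of log(count + 1) on log(rho), where `count` is the number of
#' replicates (out of the per-cell total) retaining polymorphism at both
#' loci for the full horizon; the +1 keeps cells with zero retention on the
#' log scale.
#'
#' @param rho Positive recombination-rate values.
#' @param count Non-negative retention counts.
#' @return A list with `slope`, `intercept`, `p_value` and `n`.
#' @export
retention_count_regression <- function(rho, count) {
  if (length(rho) != length(count))
    stop("`rho` and `count` must have equal length", call. = FALSE)
  if (length(rho) < 3L)
    stop("need at least 3 points for the regression", call. = FALSE)
  if (any(rho <= 0)) stop("`rho` must be positive", call. = FALSE)
  if (anyNA(count) || any(count < 0))
    stop("`count` must be non-negative", call. = FALSE)
  c(.slope_fit(log(rho), log(count + 1)), n = length(rho))
}

#' Aggregate replicate results into a cell summary
#'
#' Tabulates the five outcome categories, counts replicates with both loci
#' polymorphic at the horizon (outcomes OppositeTwo, Three, All) and with at
#' least one polymorphic (those plus SimilarTwo), and computes the censored
#' median time to fixation at locus 1.
#'
#' @param results A per-replicate data.frame from [run_cell()].
#' @param params The matching [sim_params()] object; defaults to the params
#'   attached to `results`.
#' @return A one-row data.frame: `s` (per-locus heterozygote advantage),
#'   `Ne_s`, `rho`, `replicates`, `n_fixed`, `n_similar_two`,
#'   `n_opposite_two`, `n_three`, `n_all`, `retained_both`, `retained_any`,
#'   `mtf` (NA when undefined).
#' @export
summarize_cell <- function(results, params = attr(results, "params")) {
  if (is.null(params) || !inherits(params, "sim_params"))
    stop("`params` must be a sim_params object", call. = FALSE)
  if (nrow(results) == 0L) stop("`results` must be non-empty", call. = FALSE)
  if (nrow(results) != params$replicates)
    stop("`results` rows do not match params$replicates", call. = FALSE)
  tab <- table(factor(results$outcome, levels = .outcome_levels))
  s_eff <- het_advantage(params$scheme)
  data.frame(
    s = s_eff,
    Ne_s = params$N_e * s_eff,
    rho = params$rho,
    replicates = params$replicates,
    n_fixed = as.integer(tab["Fixed"]),
    n_similar_two = as.integer(tab["SimilarTwo"]),
    n_opposite_two = as.integer(tab["OppositeTwo"]),
    n_three = as.integer(tab["Three"]),
    n_all = as.integer(tab["All"]),
    retained_both = as.integer(tab["OppositeTwo"] + tab["Three"] + tab["All"]),
    retained_any = as.integer(tab["SimilarTwo"] + tab["OppositeTwo"] +
                                tab["Three"] + tab["All"]),
    mtf = median_time_to_fixation(results$fix_gen_locus1, params$G)
  )
}
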