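#' Derive a reproducible sub-seed
#'
#' Deterministic 31-bit stream split: each parameter cell gets its own seed
#' from the master seed and the cell index, so a grid is reproducible and
#' individual cells can be re-run in isolation.
#'
#' @param seed Master seed (integer).
#' @param index Positive stream index.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
seed_stream <- function(seed, index) {
  m <- 2147483647 # 2^31 - 1; products stay exact in doubles
  s <- (abs(as.numeric(seed)) %% m)
  as.integer(((s * 16807 + as.numeric(index) * 2246822519) %% m) %% (m - 1) + 1)
}

#' Parameter grid specification
#'
#' Defaults mirror the study design: N = 1,000 diploids (N_e = 2,000), s
#' spanning N_e s from 4 to 20, rho on a log-spaced grid from 0.005 to 20
#' plus the extremes 0 (perfect linkage) and 4,000 (free recombination),
#' 100,000 generations (50 N_e) and 1,000 replicates per cell.
#'
#' @param s_values Per-locus heterozygote advantages.
#' @param rho_values Population-scaled recombination rates.
#' @param N Diploid individuals per cell.
#' @param G Generations per replicate.
#' @param replicates Replicates per cell.
#' @param scheme_type `"additive"` or `"multiplicative"`.
#' @param d_dom Dominance coefficient (multiplicative scheme only).
#' @param init_mode Initialization mode for every cell.
#' @param seed Master seed.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(s_values = seq(0.002, 0.01, by = 0.001),
                      rho_values = c(0, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2,
                                     0.5, 1, 2, 5, 10, 20, 4000),
                      N = 1000L, G = 100000L, replicates = 1000L,
                      scheme_type = c("additive", "multiplicative"),
                      d_dom = 1e6,
                      init_mode = c("exact_quarters", "random_half"),
                      seed = 1L) {
  scheme_type <- match.arg(scheme_type)
  init_mode <- match.arg(init_mode)
  if (length(s_values) < 1 || any(s_values < 0))
    stop("`s_values` must be non-negative", call. = FALSE)
  if (length(rho_values) < 1 || any(rho_values < 0))
    stop("`rho_values` must be non-negative", call. = FALSE)
  structure(list(s_values = s_values, rho_values = rho_values,
                 N = as.integer(N), G = as.integer(G),
                 replicates = as.integer(replicates),
                 scheme_type = scheme_type, d_dom = d_dom,
                 init_mode = init_mode, seed = as.integer(seed)),
            class = "grid_spec")
}

.cell_scheme <- function(grid, s) {
  if (grid$scheme_type == "additive") additive_scheme(s)
  else multiplicative_scheme(d_dom = grid$d_dom, s_hom = s / grid$d_dom)
}

#' Run a full parameter grid
#'
#' Simulates every (s, rho) cell with its own derived seed and returns one
#' summary row per cell (see [summarize_cell()]). Cells are keyed and
#' ordered by (s, rho); given the same `grid_spec` the output is identical
#' across runs. When `out_dir` is given, writes `grid_summaries.tsv` and a
#' `manifest.json` recording the parameters, seed and package version.
#'
#' @param grid A [grid_spec()].
#' @param out_dir Optional output directory.
#' @param verbose Print per-cell progress to stderr.
#' @return A data.frame of cell summaries, one row per (s, rho).
#' @export
run_grid <- function(grid, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  cells <- expand.grid(rho = grid$rho_values, s = grid$s_values)[, c("s", "rho")]
  cells <- cells[order(cells$s, cells$rho), ]
  rows <- vector("list", nrow(cells))
  t0 <- Sys.time()
  for (i in seq_len(nrow(cells))) {
    s <- cells$s[i]; rho <- cells$rho[i]
    params <- sim_params(.cell_scheme(grid, s), N = grid$N, rho = rho,
                         G = grid$G, init_mode = grid$init_mode,
                         replicates = grid$replicates,
                         seed = seed_stream(grid$seed, i))
    if (verbose)
      message(sprintf("[%d/%d] s = %g, rho = %g", i, nrow(cells), s, rho))
    rows[[i]] <- summarize_cell(run_cell(params), params)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(out_dir, "grid_summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
      package = "linkbal",
      version = as.character(utils::packageVersion("linkbal")),
      seed = grid$seed,
      s_values = grid$s_values, rho_values = grid$rho_values,
      N = grid$N, G = grid$G, replicates = grid$replicates,
      scheme = grid$scheme_type, init_mode = grid$init_mode,
      wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Effect of rho on median time to fixation, per selection strength
#'
#' For each selection strength in a grid summary, regresses log(MTF) on
#' log(rho) over the interior rho grid (rho = 0 is excluded because its log
#' is undefined; rho = 4000 is off-grid saturation) and converts the slope
#' into the percent increase in MTF per halving of rho. Rows with fewer than
#' `min_cells` cells with defined MTF are marked not quantifiable (NA), as
#' happens at high N_e s where polymorphism usually outlives the horizon.
#'
#' @param grid_summary A data.frame from [run_grid()].
#' @param min_cells Minimum number of defined-MTF cells per regression.
#' @return A data.frame with one row per s: `Ne_s`, `pct_increase_per_halving`,
#'   `p_value`, `n_cells`.
#' @export
reproduce_table1 <- function(grid_summary, min_cells = 6L) {
  stopifnot(is.data.frame(grid_summary))
  out <- lapply(split(grid_summary, grid_summary$s), function(d) {
    keep <- d$rho > 0 & d$rho < 4000 & !is.na(d$mtf)
    base <- data.frame(Ne_s = d$Ne_s[1],
                       pct_increase_per_halving = NA_real_,
                       p_value = NA_real_, n_cells = sum(keep))
    if (sum(keep) >= max(3L, min_cells)) {
      fit <- loglog_regression(d$rho[keep], d$mtf[keep])
      base$pct_increase_per_halving <- percent_increase_per_halving(fit$slope)
      base$p_value <- fit$p_value
    }
    base
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$Ne_s), ]
}

#' Per-cell retention difference between two fitness schemes
#'
#' Compares the fraction of replicates retaining polymorphism at both loci
#' between two grid summaries run under different fitness schemes at matched
#' (heterozygote advantage, rho) cells, as a cross-validation that the two
#' parameterizations of overdominance capture the same dynamics.
#'
#' @param grid_a,grid_b Grid summaries from [run_grid()] sharing the same
#'   (s, rho) cells (s compared as the per-locus heterozygote advantage).
#' @return A list with `by_cell` (data.frame: s, rho, retained-both
#'   percentages under each scheme and their absolute difference in
#'   percentage points) and `max_diff` (max over cells).
#' @export
compare_schemes <- function(grid_a, grid_b) {
  key_a <- paste(signif(grid_a$s, 10), grid_a$rho)
  key_b <- paste(signif(grid_b$s, 10), grid_b$rho)
  if (nrow(grid_a) != nrow(grid_b) || !setequal(key_a, key_b))
    stop("grids do not share the same (s, rho) cells", call. = FALSE)
  b <- grid_b[match(key_a, key_b), ]
  pct_a <- 100 * grid_a$retained_both / grid_a$replicates
  pct_b <- 100 * b$retained_both / b$replicates
  by_cell <- data.frame(s = grid_a$s, rho = grid_a$rho,
                        retained_both_pct_a = pct_a,
                        retained_both_pct_b = pct_b,
                        abs_diff_pct = abs(pct_a - pct_b))
  list(by_cell = by_cell, max_diff = max(by_cell$abs_diff_pct))
}
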