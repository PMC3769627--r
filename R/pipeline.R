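#' Run the clade rate analysis
#'
#' Computes the per-clade net diversification rate table (see
#' [rate_table()]) from a clade table, rounding for presentation, and
#' optionally writes it as tab-delimited text. With the packaged
#' *Hypericum* table and defaults this reproduces all 21 published rate
#' values (7 clades x mean/max/min) at 3 decimal places.
#'
#' @param clades clade table; default [hypericum_clades()].
#' @param n0 initial diversity (1 per the taxonomic likelihood
#'   convention; 2 for the crown convention).
#' @param digits decimal places for the rounded rate columns, default 3.
#' @param file optional path to write the table (TSV).
#' @return Data frame: input columns plus `r_mean`, `r_max`, `r_min`
#'   rounded to `digits` (round-half-even, as [round()] does).
#' @export
run_rates <- function(clades = hypericum_clades(), n0 = 1, digits = 3,
                      file = NULL) {
  clades <- validate_clade_table(clades)
  if (nrow(clades) == 0L) {
    warning("empty clade table: nothing to compute")
    out <- clades
    out$r_mean <- numeric(0); out$r_max <- numeric(0); out$r_min <- numeric(0)
  } else {
    out <- rate_table(clades, n0 = n0)
    for (col in c("r_mean", "r_max", "r_min"))
      out[[col]] <- round(out[[col]], digits)
  }
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Run the exceptional species richness test
#'
#' Orchestrates [test_exceptional()] the way the published analysis was
#' set up: the background rate is the whole-phylogeny clade's `r_mean`,
#' that clade itself is excluded from testing (it defines the null), and
#' every remaining clade is tested at each relative-extinction
#' assumption. Also returns the plot coordinates of the
#' diversity-versus-age confidence bands via [richness_plot_data()].
#'
#' @param clades clade table; default [hypericum_clades()].
#' @param background name of the background clade (must be present in
#'   `clades`), or an explicit positive rate. When a rate is given, no
#'   clade is excluded.
#' @param epsilon relative extinction assumptions, default `c(0, 0.9)`.
#' @param coverage interval coverage, default 0.95.
#' @param file optional path to write the verdict table (TSV).
#' @param coords_file optional path to write plot coordinates (TSV).
#' @return List with `verdicts` (see [test_exceptional()]), `coords`
#'   (long-format plot data), and `background_r`.
#' @export
run_richness_test <- function(clades = hypericum_clades(),
                              background = "Triadenum+Myriandra+Brathys s.l.",
                              epsilon = c(0, 0.9), coverage = 0.95,
                              file = NULL, coords_file = NULL) {
  clades <- validate_clade_table(clades)
  r_bg <- resolve_background(clades, background)
  tested <- if (is.character(background))
    clades[clades$name != background, , drop = FALSE] else clades
  if (nrow(tested) == 0L) {
    warning("no clades to test once the background clade is excluded")
    verdicts <- data.frame(name = character(0), epsilon = numeric(0),
                           n_species = numeric(0), t = numeric(0),
                           k_lower = integer(0), k_upper = integer(0),
                           verdict = character(0), note = character(0))
    coords <- NULL
  } else {
    verdicts <- test_exceptional(tested, r_bg, epsilon = epsilon,
                                 coverage = coverage)
    coords <- richness_plot_data(clades, r_bg, epsilon = epsilon,
                                 coverage = coverage)
  }
  if (!is.null(file))
    utils::write.table(verdicts, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(coords_file) && !is.null(coords))
    utils::write.table(coords, coords_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(verdicts = verdicts, coords = coords, background_r = r_bg)
}

#' Simulation study: estimator recovery and interval calibration
#'
#' For each row of a parameter grid `(r, epsilon, t)`, simulates `reps`
#' crown-conditioned birth-death clades and summarizes (i) the empirical
#' 2.5/97.5 clade-size percentiles next to the closed-form
#' [richness_interval()] bounds, (ii) the empirical coverage of the
#' closed-form interval, and (iii) for pure-birth cells
#' (`epsilon == 0`), the bias of the taxonomic rate estimator
#' `ln(N) / t` applied to simulated clade sizes at the true age.
#'
#' @param grid data frame with columns `r`, `epsilon`, `t`.
#' @param reps simulated clades per grid cell.
#' @param coverage interval coverage, default 0.95.
#' @param seed integer seed; each cell derives its own substream
#'   deterministically from it.
#' @param file optional path to write the summary (TSV).
#' @return Data frame, one row per grid cell: the grid columns plus
#'   `k_lower`, `k_upper`, `q025_mc`, `q975_mc`, `coverage_mc`,
#'   `median_r_hat` (NA when `epsilon > 0`), `mean_size_mc`,
#'   `mean_size_theory`.
#' @export
run_simulation_study <- function(grid, reps = 2000, coverage = 0.95,
                                 seed = 1, file = NULL) {
  if (!is.data.frame(grid) || !all(c("r", "epsilon", "t") %in% names(grid)))
    stop("grid must be a data frame with columns r, epsilon, t", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  out <- grid
  out$k_lower <- NA_integer_; out$k_upper <- NA_integer_
  out$q025_mc <- NA_real_; out$q975_mc <- NA_real_
  out$coverage_mc <- NA_real_; out$median_r_hat <- NA_real_
  out$mean_size_mc <- NA_real_; out$mean_size_theory <- NA_real_
  for (i in seq_len(nrow(grid))) {
    r <- grid$r[i]; eps <- grid$epsilon[i]; tt <- grid$t[i]
    ci <- richness_interval(r, eps, tt, coverage)
    sizes <- mc_clade_sizes(r, eps, tt, reps = reps,
                            seed = (seed + i) %% .Machine$integer.max)
    q <- stats::quantile(sizes, c(0.025, 0.975), type = 1)
    out$k_lower[i] <- ci$k_lower
    out$k_upper[i] <- ci$k_upper
    out$q025_mc[i] <- q[[1L]]
    out$q975_mc[i] <- q[[2L]]
    out$coverage_mc[i] <- mean(sizes >= ci$k_lower & sizes <= ci$k_upper)
    out$mean_size_mc[i] <- mean(sizes)
    out$mean_size_theory[i] <- 2 / (1 - ci$beta)
    if (eps == 0)
      out$median_r_hat[i] <- stats::median(log(sizes) / tt)
  }
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
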