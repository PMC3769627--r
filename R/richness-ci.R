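#' Birth-death auxiliary quantities beta and alpha
#'
#' For a linear birth-death process with net diversification
#' \eqn{r = \lambda - \mu > 0} and relative extinction
#' \eqn{\epsilon = \mu/\lambda \in [0, 1)}, running for time \eqn{t}:
#' \deqn{\beta = \frac{e^{rt} - 1}{e^{rt} - \epsilon}, \qquad
#'       \alpha = \epsilon \beta.}
#' \eqn{\alpha} is the extinction probability of a single lineage by
#' time \eqn{t}; conditioned on survival, its number of descendants is
#' geometric with parameter \eqn{\beta}. At \eqn{\epsilon = 0} this
#' reduces to the Yule process: \eqn{\alpha = 0},
#' \eqn{\beta = 1 - e^{-rt}}.
#'
#' Computed via the \eqn{e^{-rt}} form
#' \eqn{\beta = (1 - e^{-rt}) / (1 - \epsilon e^{-rt})} so large
#' \eqn{rt} cannot overflow; if \eqn{rt} is so large that \eqn{\beta}
#' rounds to 1 in double precision the clade-size interval is unbounded
#' at working precision and an error is raised.
#'
#' @param r net diversification rate per lineage per Ma, `r > 0`.
#' @param epsilon relative extinction fraction, in `[0, 1)`.
#' @param t time in Ma, `t > 0`.
#' @return list with components `beta` and `alpha`, both in `[0, 1)`.
#' @export
bd_aux <- function(r, epsilon, t) {
  stopifnot(length(r) == 1L, length(epsilon) == 1L, length(t) == 1L)
  if (r <= 0) stop("background net rate r must be > 0", call. = FALSE)
  if (epsilon < 0 || epsilon >= 1)
    stop("relative extinction epsilon must be in [0, 1)", call. = FALSE)
  if (t <= 0) stop("time t must be > 0", call. = FALSE)
  emrt <- exp(-r * t)
  beta <- -expm1(-r * t) / (1 - epsilon * emrt)
  if (beta >= 1)
    stop("r*t so large that beta rounds to 1: the expected clade-size ",
         "interval is unbounded at working precision", call. = FALSE)
  list(beta = beta, alpha = epsilon * beta)
}

#' Crown clade size distribution under a background birth-death process
#'
#' A crown group of age `t` starts as two lineages, each of which is
#' observed to have survived to the present. Under the linear
#' birth-death process, each surviving lineage leaves a
#' geometric(\eqn{\beta}) number of extant descendants, so the crown
#' clade size is the sum of two independent geometrics:
#' \deqn{P(N = n) = (n - 1)(1 - \beta)^2 \beta^{n-2}, \quad n \ge 2,}
#' with distribution function
#' \deqn{P(N \le n) = 1 - \beta^{n-1}\,\{n (1 - \beta) + \beta\}.}
#' The CDF is evaluated in log space, so it is accurate for clade sizes
#' far into the tail.
#'
#' @param n integer clade size(s), `n >= 2`; vectorized.
#' @inheritParams bd_aux
#' @return `crown_size_pmf`: \eqn{P(N = n)}; `crown_size_cdf`:
#'   \eqn{P(N \le n)}.
#' @examples
#' crown_size_cdf(2, r = 0.195, epsilon = 0, t = 3.83)  # (1 - beta)^2
#' @export
crown_size_cdf <- function(n, r, epsilon, t) {
  if (any(n < 2) || any(n != round(n)))
    stop("crown clade size n must be an integer >= 2", call. = FALSE)
  beta <- bd_aux(r, epsilon, t)$beta
  .crown_cdf_beta(n, beta)
}

#' @rdname crown_size_cdf
#' @export
crown_size_pmf <- function(n, r, epsilon, t) {
  if (any(n < 2) || any(n != round(n)))
    stop("crown clade size n must be an integer >= 2", call. = FALSE)
  beta <- bd_aux(r, epsilon, t)$beta
  exp(log(n - 1) + 2 * log1p(-beta) + (n - 2) * log(beta))
}

## CDF at real-valued x >= 2 (continuous relaxation used for plot curves)
.crown_cdf_beta <- function(x, beta) {
  if (beta == 0) return(as.numeric(x >= 2))
  -expm1((x - 1) * log(beta) + log(x * (1 - beta) + beta))
}

#' 95% confidence bounds of expected clade size at age t
#'
#' Integer and continuous bounds of the central `coverage` interval of
#' the crown clade-size distribution (see [crown_size_cdf()]) under a
#' background birth-death process. With tail mass
#' \eqn{q = (1 - \mathrm{coverage})/2}:
#' `k_lower` is the largest integer \eqn{n \ge 2} with
#' \eqn{P(N < n) \le q}, and `k_upper` the smallest integer with
#' \eqn{P(N \le n) \ge 1 - q}. An observed richness strictly outside
#' `[k_lower, k_upper]` is exceptional at the chosen coverage.
#' `k_lower_cont`/`k_upper_cont` solve the same tail equations over the
#' reals (floored at 2) and give the smooth confidence-band curves of a
#' diversity-versus-age plot.
#'
#' @inheritParams bd_aux
#' @param coverage central coverage of the interval, default 0.95.
#' @return list of class `"richness_interval"` with `t`, `epsilon`, `r`,
#'   `beta`, `k_lower`, `k_upper` (integers), `k_lower_cont`,
#'   `k_upper_cont`, `coverage`.
#' @export
richness_interval <- function(r, epsilon, t, coverage = 0.95) {
  if (coverage <= 0 || coverage >= 1)
    stop("coverage must be in (0, 1)", call. = FALSE)
  beta <- bd_aux(r, epsilon, t)$beta
  q <- (1 - coverage) / 2
  k_upper <- .crown_quantile_ge(beta, 1 - q)
  ## largest n with P(N < n) = CDF(n - 1) <= q; n = 2 always qualifies
  ## (P(N < 2) = 0), so step the upper quantile convention down one.
  k_lower <- .crown_quantile_ge(beta, q)
  if (.crown_cdf_beta(k_lower, beta) > q) k_lower <- k_lower - 1L
  k_lower <- max(2L, k_lower + 1L)
  structure(
    list(t = t, epsilon = epsilon, r = r, beta = beta,
         k_lower = k_lower, k_upper = k_upper,
         k_lower_cont = .crown_cont_quantile(beta, q),
         k_upper_cont = .crown_cont_quantile(beta, 1 - q),
         coverage = coverage),
    class = "richness_interval"
  )
}

#' @export
print.richness_interval <- function(x, ...) {
  cat(sprintf(
    "expected crown clade size at t = %g Ma (r = %g, epsilon = %g):\n  %.0f%% interval [%d, %d] species (continuous [%.2f, %.2f])\n",
    x$t, x$r, x$epsilon, 100 * x$coverage, x$k_lower, x$k_upper,
    x$k_lower_cont, x$k_upper_cont))
  invisible(x)
}

## smallest integer n >= 2 with CDF(n) >= p, by bracket doubling + bisection
.crown_quantile_ge <- function(beta, p) {
  if (.crown_cdf_beta(2, beta) >= p) return(2L)
  lo <- 2; hi <- 4
  while (.crown_cdf_beta(hi, beta) < p) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e12) stop("clade-size quantile exceeds 1e12", call. = FALSE)
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (.crown_cdf_beta(mid, beta) >= p) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

## real x >= 2 with CDF(x) = p, floored at 2
.crown_cont_quantile <- function(beta, p) {
  if (.crown_cdf_beta(2, beta) >= p) return(2)
  hi <- 4
  while (.crown_cdf_beta(hi, beta) < p) hi <- hi * 2
  stats::uniroot(function(x) .crown_cdf_beta(x, beta) - p,
                 lower = 2, upper = hi, tol = 1e-10)$root
}

#' Test clades for exceptional species richness
#'
#' For each clade and each relative extinction assumption, compares the
#' observed standing richness with the `coverage` interval of expected
#' crown clade size at the clade's mean crown age under the background
#' rate. Verdicts use strict inequalities: `exceptionally_rich` iff
#' `n_species > k_upper`, `exceptionally_poor` iff `n_species < k_lower`,
#' otherwise `within_expectation`. Clades with fewer than 2 species
#' cannot form a crown group and are flagged `not_testable` rather than
#' dropped.
#'
#' @param clades clade table (see [rate_table()]); `age_mean` is the age
#'   used — HPD age bounds are not propagated into the test.
#' @param background background net diversification rate: either a
#'   single positive number, or the name of a clade in `clades` whose
#'   `r_mean` (from [rate_table()], `n0 = 1`) is used.
#' @param epsilon vector of relative extinction fractions, default
#'   `c(0, 0.9)`.
#' @param coverage interval coverage, default 0.95.
#' @return data frame of class `"exceptionality_result"`: one row per
#'   clade per epsilon with columns `name`, `epsilon`, `n_species`, `t`,
#'   `k_lower`, `k_upper`, `verdict`, `note`; attribute `background_r`.
#' @examples
#' test_exceptional(hypericum_clades(),
#'                  background = "Triadenum+Myriandra+Brathys s.l.")
#' @export
test_exceptional <- function(clades, background, epsilon = c(0, 0.9),
                             coverage = 0.95) {
  clades <- validate_clade_table(clades)
  if (any(epsilon < 0 | epsilon >= 1))
    stop("epsilon values must be in [0, 1)", call. = FALSE)
  r_bg <- resolve_background(clades, background)
  out <- expand.grid(i = seq_len(nrow(clades)), epsilon = epsilon,
                     KEEP.OUT.ATTRS = FALSE)
  res <- data.frame(
    name = clades$name[out$i],
    epsilon = out$epsilon,
    n_species = clades$n_species[out$i],
    t = clades$age_mean[out$i],
    k_lower = NA_integer_, k_upper = NA_integer_,
    verdict = NA_character_, note = "",
    stringsAsFactors = FALSE
  )
  for (j in seq_len(nrow(res))) {
    if (res$n_species[j] < 2) {
      res$verdict[j] <- "not_testable"
      res$note[j] <- "fewer than 2 species: no crown group to test"
      next
    }
    ci <- richness_interval(r_bg, res$epsilon[j], res$t[j], coverage)
    res$k_lower[j] <- ci$k_lower
    res$k_upper[j] <- ci$k_upper
    res$verdict[j] <-
      if (res$n_species[j] > ci$k_upper) "exceptionally_rich"
      else if (res$n_species[j] < ci$k_lower) "exceptionally_poor"
      else "within_expectation"
  }
  attr(res, "background_r") <- r_bg
  attr(res, "coverage") <- coverage
  class(res) <- c("exceptionality_result", "data.frame")
  res
}

resolve_background <- function(clades, background) {
  if (is.numeric(background)) {
    if (length(background) != 1L || background <= 0)
      stop("explicit background rate must be a single positive number",
           call. = FALSE)
    return(background)
  }
  if (!background %in% clades$name)
    stop("background clade '", background, "' not found; available: ",
         paste(clades$name, collapse = ", "), call. = FALSE)
  row <- clades[clades$name == background, , drop = FALSE]
  net_rate(row$n_species, row$age_mean)
}

#' Coordinates for a diversity-versus-age confidence-band plot
#'
#' Produces the coordinates of a semi-log plot of standing species
#' diversity against crown age: one point per clade at
#' `(age_mean, log10 n_species)` and, per relative-extinction
#' assumption, a lower and an upper confidence-band curve
#' `(t, log10 k(t))` from the continuous interval bounds. No rendering
#' is done; feed the long-format result to any plotting engine.
#'
#' @inheritParams test_exceptional
#' @param t_grid ages (Ma) at which to evaluate the band curves; default
#'   a 101-point grid spanning the clade ages.
#' @return data frame in long format: `series` (`"observed"` or
#'   `"k_lower_eps<e>"` / `"k_upper_eps<e>"`), `name` (clade, points
#'   only), `t`, `log10_value`.
#' @export
richness_plot_data <- function(clades, background, epsilon = c(0, 0.9),
                               coverage = 0.95, t_grid = NULL) {
  clades <- validate_clade_table(clades)
  r_bg <- resolve_background(clades, background)
  if (is.null(t_grid)) {
    t_grid <- seq(max(1e-3, 0.5 * min(clades$age_mean)),
                  max(clades$age_mean) * 1.05, length.out = 101L)
  }
  pts <- data.frame(series = "observed", name = clades$name,
                    t = clades$age_mean,
                    log10_value = log10(clades$n_species),
                    stringsAsFactors = FALSE)
  bands <- lapply(epsilon, function(e) {
    ks <- vapply(t_grid, function(tt) {
      ci <- richness_interval(r_bg, e, tt, coverage)
      c(ci$k_lower_cont, ci$k_upper_cont)
    }, c(0, 0))
    rbind(
      data.frame(series = sprintf("k_lower_eps%g", e), name = NA_character_,
                 t = t_grid, log10_value = log10(ks[1, ]),
                 stringsAsFactors = FALSE),
      data.frame(series = sprintf("k_upper_eps%g", e), name = NA_character_,
                 t = t_grid, log10_value = log10(ks[2, ]),
                 stringsAsFactors = FALSE)
    )
  })
  out <- rbind(pts, do.call(rbind, bands))
  attr(out, "background_r") <- r_bg
  out
}
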