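test_that("bd_aux matches the direct exponential form and its limits", {
  # pure birth: alpha = 0, beta = 1 - exp(-rt)
  aux <- bd_aux(0.195, 0, 9.79)
  expect_equal(aux$beta, 1 - exp(-0.195 * 9.79), tolerance = 1e-12)
  expect_equal(aux$alpha, 0)

  # with extinction: agree with the textbook e^{rt} form
  aux9 <- bd_aux(0.195, 0.9, 3.83)
  expect_equal(aux9$beta, beta_direct(0.195, 0.9, 3.83), tolerance = 1e-12)
  expect_equal(aux9$alpha, 0.9 * aux9$beta)
  expect_true(aux9$alpha <= aux9$beta && aux9$beta < 1)

  # t -> 0+: beta -> 0
  expect_lt(bd_aux(0.5, 0.9, 1e-10)$beta, 1e-9)

  # rt overflow is caught, not silently saturated
  expect_error(bd_aux(10, 0, 1e4), "unbounded")
  expect_error(bd_aux(-1, 0, 1), "r must be")
  expect_error(bd_aux(1, 1, 1), "epsilon")
  expect_error(bd_aux(1, 0.5, 0), "t must be")
})

test_that("closed-form crown size CDF equals brute-force summation", {
  grid <- expand.grid(r = c(0.195, 0.5, 1.1),
                      epsilon = c(0, 0.5, 0.9),
                      t = c(0.5, 3.83, 9.79))
  for (i in seq_len(nrow(grid))) {
    beta <- beta_direct(grid$r[i], grid$epsilon[i], grid$t[i])
    for (n in c(2:10, 50, 137, 500)) {
      expect_lt(abs(crown_size_cdf(n, grid$r[i], grid$epsilon[i], grid$t[i]) -
                      brute_crown_cdf(n, beta)), 1e-12)
    }
  }
})

test_that("crown size distribution behaves as a distribution", {
  expect_equal(crown_size_cdf(2, 0.195, 0.9, 3.83),
               (1 - bd_aux(0.195, 0.9, 3.83)$beta)^2)
  cdf <- crown_size_cdf(2:2000, 0.195, 0.9, 3.83)
  expect_true(all(diff(cdf) >= 0))
  expect_true(all(diff(cdf)[cdf[-1] < 1 - 1e-9] > 0))  # strict until saturation
  expect_equal(cdf[length(cdf)], 1, tolerance = 1e-6)
  pmf <- crown_size_pmf(2:2000, 0.195, 0.9, 3.83)
  expect_equal(cumsum(pmf), cdf, tolerance = 1e-10)
  expect_error(crown_size_cdf(1, 0.2, 0, 1), "integer >= 2")
})

test_that("interval bounds match an exhaustive enumeration oracle", {
  cases <- expand.grid(r = c(0.195, 0.529), epsilon = c(0, 0.9),
                       t = c(3.83, 9.79))
  for (i in seq_len(nrow(cases))) {
    ci <- richness_interval(cases$r[i], cases$epsilon[i], cases$t[i])
    ref <- enum_interval(cases$r[i], cases$epsilon[i], cases$t[i])
    expect_identical(ci$k_lower, as.integer(ref["k_lower"]))
    expect_identical(ci$k_upper, as.integer(ref["k_upper"]))
    # continuous relaxations solve the same tail equations (or floor at 2)
    cont_cdf <- function(x)
      1 - ci$beta^(x - 1) * (x * (1 - ci$beta) + ci$beta)
    if (ci$k_lower_cont > 2)
      expect_equal(cont_cdf(ci$k_lower_cont), 0.025, tolerance = 1e-7)
    expect_equal(cont_cdf(ci$k_upper_cont), 0.975, tolerance = 1e-7)
    expect_lte(ci$k_lower_cont, ci$k_upper_cont)
    expect_lte(ci$k_lower, ci$k_upper)
    expect_gte(ci$k_lower, 2L)
  }
})

test_that("vanishing clade age pins the interval at the crown pair", {
  ci <- richness_interval(0.195, 0.9, 1e-8)
  expect_identical(ci$k_lower, 2L)
  expect_identical(ci$k_upper, 2L)
  expect_equal(ci$k_lower_cont, 2)
  expect_equal(ci$k_upper_cont, 2)
})

test_that("upper bound grows with age, rate, and extinction fraction", {
  ks_t <- vapply(seq(1, 20, by = 1),
                 function(tt) richness_interval(0.3, 0.5, tt)$k_upper, 0L)
  expect_true(all(diff(ks_t) >= 0))
  ks_r <- vapply(seq(0.1, 1.5, by = 0.1),
                 function(r) richness_interval(r, 0.5, 5)$k_upper, 0L)
  expect_true(all(diff(ks_r) >= 0))
  ks_e <- vapply(seq(0, 0.95, by = 0.05),
                 function(e) richness_interval(0.3, e, 5)$k_upper, 0L)
  expect_true(all(diff(ks_e) >= 0))
})

test_that("exceptionality verdicts use strict interval inequalities", {
  ci <- richness_interval(0.195, 0.9, 3.83)
  mk <- function(n) data.frame(name = "X", n_species = n, age_mean = 3.83)
  at_upper <- test_exceptional(mk(ci$k_upper), 0.195, epsilon = 0.9)
  expect_equal(at_upper$verdict, "within_expectation")
  above <- test_exceptional(mk(ci$k_upper + 1), 0.195, epsilon = 0.9)
  expect_equal(above$verdict, "exceptionally_rich")
  at_lower <- test_exceptional(mk(ci$k_lower), 0.195, epsilon = 0.9)
  expect_equal(at_lower$verdict, "within_expectation")
  below <- test_exceptional(mk(ci$k_lower - 1), 0.195, epsilon = 0.9)
  expect_equal(below$verdict, "exceptionally_poor")
})

test_that("untestable clades are flagged, not dropped", {
  clades <- data.frame(name = c("single", "pair"), n_species = c(1, 5),
                       age_mean = c(2, 2))
  res <- test_exceptional(clades, 0.3, epsilon = 0)
  expect_equal(nrow(res), 2L)
  expect_equal(res$verdict[res$name == "single"], "not_testable")
  expect_match(res$note[res$name == "single"], "fewer than 2")
})

test_that("raising observed richness never moves a verdict away from rich", {
  rank <- c(exceptionally_poor = 1, within_expectation = 2,
            exceptionally_rich = 3)
  for (n in c(2, 5, 20, 66, 67, 200)) {
    v <- vapply(c(n, n + 1), function(k) {
      test_exceptional(data.frame(name = "X", n_species = k, age_mean = 3.83),
                       0.195, epsilon = 0.9)$verdict
    }, "")
    expect_gte(rank[v[2]], rank[v[1]])
  }
})

test_that("plot coordinates are definitionally consistent with the interval", {
  clades <- hypericum_clades()
  pd <- richness_plot_data(clades, "Triadenum+Myriandra+Brathys s.l.",
                           epsilon = c(0, 0.9))
  pt <- pd[pd$series == "observed" & pd$name == "Páramo", ]
  expect_equal(pt$t, 3.83)
  expect_equal(pt$log10_value, log10(67))
  r_bg <- attr(pd, "background_r")
  for (series in c("k_upper_eps0", "k_upper_eps0.9", "k_lower_eps0.9")) {
    curve <- pd[pd$series == series, ]
    expect_true(all(diff(curve$log10_value) >= 0))  # nondecreasing in t
    tt <- curve$t[50]
    ci <- richness_interval(r_bg, ifelse(grepl("0.9", series), 0.9, 0), tt)
    want <- if (grepl("upper", series)) ci$k_upper_cont else ci$k_lower_cont
    expect_equal(curve$log10_value[50], log10(want), tolerance = 1e-10)
  }
})
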