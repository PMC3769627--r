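test_that("identical seed and configuration give identical results", {
  a <- simulate_bd(1, 0.4, t_stop = 3, condition = "crown_both_survive",
                   seed = 21)
  b <- simulate_bd(1, 0.4, t_stop = 3, condition = "crown_both_survive",
                   seed = 21)
  expect_identical(write_chronogram(a$tree), write_chronogram(b$tree))
  expect_identical(a$node_ages, b$node_ages)

  qa <- mc_clade_size_quantiles(0.3, 0.5, 4, reps = 1000, seed = 22)
  qb <- mc_clade_size_quantiles(0.3, 0.5, 4, reps = 1000, seed = 22)
  expect_identical(as.numeric(qa), as.numeric(qb))
})

test_that("vanishing duration leaves exactly the crown pair", {
  for (s in 1:10) {
    sim <- simulate_bd(1, 0, t_stop = 1e-4, condition = "crown_both_survive",
                       seed = 100 + s)
    expect_equal(sim$n_extant, 2L)
    expect_equal(unname(sim$node_ages), 1e-4)
  }
})

test_that("simulated chronograms are exactly ultrametric with true node ages", {
  set.seed(23)
  for (i in 1:10) {
    sim <- simulate_bd(0.9, 0.45, t_stop = 4, condition = "crown_both_survive")
    tr <- sim$tree
    expect_true(check_ultrametric(tr, rel_tol = 1e-9)$pass)
    expect_equal(sim$n_extant, ape::Ntip(tr))
    # crown node is at exactly t_stop under crown conditioning
    expect_equal(unname(sim$node_ages[as.character(ape::Ntip(tr) + 1)]), 4)
    # crown_age on random tip pairs reproduces ages recorded at event time
    for (j in 1:3) {
      pair <- sample(tr$tip.label, 2)
      expect_equal(crown_age(tr, pair, rel_tol = 1e-9),
                   true_divergence_age(sim, pair[1], pair[2]),
                   tolerance = 1e-12)
    }
  }
})

test_that("simulator argument contracts are enforced", {
  expect_error(simulate_bd(1, 1.2, t_stop = 1), "mu")
  expect_error(simulate_bd(1, 0, t_stop = 1, n_stop = 10), "exactly one")
  expect_error(simulate_bd(1, 0), "exactly one")
  expect_error(simulate_bd(1, 0.5, n_stop = 10), "pure birth")
  expect_error(simulate_bd(1, 0, t_stop = 1, start_mode = "single_lineage",
                           condition = "crown_both_survive"), "crown_pair")
  # near-critical process: both-survive acceptance ~3e-4, guard must trip
  expect_error(simulate_bd(1, 0.999, t_stop = 50,
                           condition = "crown_both_survive",
                           max_attempts = 5, seed = 1),
               "rejection guard")
})

test_that("pure-birth n_stop yields the requested number of tips", {
  sim <- simulate_bd(1, 0, n_stop = 50, seed = 24)
  expect_equal(sim$n_extant, 50L)
  expect_equal(ape::Ntip(sim$tree), 50L)
  expect_true(check_ultrametric(sim$tree, rel_tol = 1e-9)$pass)
})

test_that("crown-conditioned clade sizes match the geometric-sum law", {
  # mean of the sum of two geometric(beta) lineages is 2 / (1 - beta)
  r <- 0.5; eps <- 0.6; t <- 3
  beta <- beta_direct(r, eps, t)
  sizes <- mc_clade_sizes(r, eps, t, reps = 2e4, seed = 25)
  m_theory <- 2 / (1 - beta)
  sd_theory <- sqrt(2 * beta) / (1 - beta)
  expect_lt(abs(mean(sizes) - m_theory), 4 * sd_theory / sqrt(length(sizes)))
  expect_true(all(sizes >= 2))

  # full goodness of fit against (n-1)(1-beta)^2 beta^(n-2), alpha = 0.01
  n_max <- max(sizes)
  p <- crown_size_pmf(2:n_max, r, eps, t)
  obs <- tabulate(sizes, nbins = n_max)[2:n_max]
  keep <- which(p * length(sizes) >= 5)
  bins <- c(p[keep], 1 - sum(p[keep]))
  counts <- c(obs[keep], length(sizes) - sum(obs[keep]))
  gof <- suppressWarnings(stats::chisq.test(counts, p = bins))
  expect_gt(gof$p.value, 0.01)
})

test_that("unconditioned single-lineage counts follow the zero-class law", {
  # P(0) = alpha, P(n) = (1 - alpha)(1 - beta) beta^(n-1)
  lambda <- 0.4; mu <- 0; t <- 5
  set.seed(26)
  n <- divrich:::bd_single_sizes_cpp(5e4, lambda, mu, t)
  beta <- beta_direct(lambda - mu, mu / lambda, t)
  n_max <- max(n)
  p <- (1 - beta) * beta^(seq_len(n_max) - 1)   # pure birth: no zero class
  expect_equal(sum(n == 0), 0L)
  obs <- tabulate(n, nbins = n_max)
  keep <- which(p * length(n) >= 5)
  bins <- c(p[keep], 1 - sum(p[keep]))
  counts <- c(obs[keep], length(n) - sum(obs[keep]))
  gof <- suppressWarnings(stats::chisq.test(counts, p = bins))
  expect_gt(gof$p.value, 0.01)
})

test_that("rate parameterization round-trips between (lambda, mu) and (r, eps)", {
  r <- 0.195; eps <- 0.9
  lambda <- r / (1 - eps); mu <- eps * lambda
  expect_equal(lambda - mu, r, tolerance = 1e-14)
  expect_equal(mu / lambda, eps, tolerance = 1e-14)
})

test_that("tip subsampling is binomial and never deepens the crown", {
  big <- simulate_bd(1, 0, n_stop = 1000, seed = 27)
  set.seed(28)
  counts <- vapply(1:20, function(i) {
    sub <- subsample_tips(big, 0.5)
    expect_true(check_ultrametric(sub$tree, rel_tol = 1e-9)$pass)
    expect_lte(max(sub$node_ages), max(big$node_ages) + 1e-12)
    sub$n_extant
  }, 0L)
  # Binomial(1000, 0.5): all draws within 4 sigma of 500
  expect_true(all(abs(counts - 500) < 4 * sqrt(1000 * 0.25)))

  ident <- subsample_tips(big, 1)
  expect_identical(ape::Ntip(ident$tree), ape::Ntip(big$tree))

  tiny <- simulate_bd(1, 0, t_stop = 1e-4, condition = "crown_both_survive",
                      seed = 29)
  sub <- suppressWarnings(subsample_tips(tiny, 1e-6, seed = 30))
  expect_true(sub$degenerate)
  expect_null(sub$tree)
})

test_that("Monte-Carlo quantiles expose acceptance diagnostics", {
  q <- mc_clade_size_quantiles(0.195, 0.9, 3.83, reps = 2000, seed = 31)
  acc <- attr(q, "acceptance_probability")
  # single-lineage survival prob is 1 - alpha; both-survive is its square
  aux <- bd_aux(0.195, 0.9, 3.83)
  expect_equal(acc, 1 - aux$alpha, tolerance = 0.05)
  expect_gte(q[[1]], 2)
  expect_lte(q[[1]], q[[2]])
})
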