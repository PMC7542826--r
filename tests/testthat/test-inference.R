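test_that("constant tip data drives the change-rate MLEs to zero", {
  tr <- random_tree(12, seed = 21)
  counts <- setNames(as.list(rep(7L, 12)), tr$tip.label)
  fit <- fit_ml(tr, counts, chromosome_model(n_max = 15),
                include_polyploidy = FALSE)
  expect_lt(fit$rates_unit[["rate_fission"]], 0.01)
  expect_lt(fit$rates_unit[["rate_fusion"]], 0.01)
  expect_true(fit$converged)
})

test_that("likelihood-ratio p-values follow the chi-square machinery", {
  f <- structure(list(log_likelihood = -10), class = "karyo_ml_fit")
  lrt0 <- likelihood_ratio_test(f, f)
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p_value, 1)

  f2 <- structure(list(log_likelihood = -10 + 3.841 / 2), class = "karyo_ml_fit")
  plain <- likelihood_ratio_test(f, f2, boundary = FALSE)
  expect_equal(plain$statistic, 3.841)
  expect_equal(plain$df, 1)
  expect_equal(plain$p_value, 0.05, tolerance = 1e-3)
  mix <- likelihood_ratio_test(f, f2, boundary = TRUE)
  expect_equal(mix$p_value, plain$p_value / 2, tolerance = 1e-12)

  f3 <- structure(list(log_likelihood = -9), class = "karyo_ml_fit")
  expect_warning(likelihood_ratio_test(f3, f), "optimizer")
})

test_that("MCMC chains are reproducible from the seed", {
  tr <- random_tree(8, seed = 5)
  counts <- setNames(as.list(c(4L, 4L, 5L, 5L, 6L, 6L, 7L, 7L)), tr$tip.label)
  st <- mcmc_settings(generations = 60, samples_per_tree = 10, seed = 42)
  c1 <- run_mcmc(tr, counts, settings = st, tree_index = 2)
  c2 <- run_mcmc(tr, counts, settings = st, tree_index = 2)
  expect_identical(c1$draws, c2$draws)
  c3 <- run_mcmc(tr, counts, settings = mcmc_settings(
    generations = 60, samples_per_tree = 10, seed = 43), tree_index = 2)
  expect_false(identical(c1$draws$rate_fission, c3$draws$rate_fission))
})

test_that("with the likelihood disabled the sampler recovers its prior", {
  tr <- random_tree(4, seed = 9)
  counts <- setNames(as.list(rep(5L, 4)), tr$tip.label)
  st <- mcmc_settings(generations = 12000, samples_per_tree = 100, seed = 7,
                      prior = 100)
  ch <- run_mcmc(tr, counts, settings = st, use_likelihood = FALSE)
  draws <- ch$draws$rate_fission[ch$draws$generation >= 2000]
  ks <- suppressWarnings(stats::ks.test(draws, stats::pexp, rate = 1 / 100))
  expect_lt(unname(ks$statistic), 0.05)
  # mean of an exponential(mean = 100) prior
  expect_equal(mean(draws), 100, tolerance = 0.1)
})

test_that("pooling keeps exact bookkeeping and per-tree back-transform", {
  trs <- lapply(c(31, 32, 33), function(s) {
    tr <- random_tree(6, seed = s)
    tr$edge.length <- tr$edge.length * (50 * (s - 30)) # distinct root depths
    tr
  })
  counts <- setNames(as.list(c(4L, 5L, 5L, 6L, 7L, 8L)), trs[[1]]$tip.label)
  st <- mcmc_settings(generations = 80, samples_per_tree = 20, seed = 3)
  chains <- lapply(1:3, function(i) {
    run_mcmc(trs[[i]], counts, settings = st, tree_index = i)
  })
  pooled <- pool_posterior(chains, st)
  expect_equal(nrow(pooled), 3 * 20)
  expect_true(all(pooled$generation >= floor(0.25 * 80)))
  expect_true(all(pooled$generation <= 79))
  expect_true(all(pooled$rate_fission >= 0))
  # provenance: every draw maps to a stored post-burnin state of its chain
  for (i in 1:3) {
    sub <- pooled[pooled$tree == i, ]
    expect_false(any(duplicated(sub$generation)))
    src <- chains[[i]]$draws[match(sub$generation, chains[[i]]$draws$generation), ]
    expect_equal(sub$rate_fusion,
                 src$rate_fusion / chains[[i]]$scale_factor)
  }
  # permutation invariance in tree order (same multiset of draws)
  pooled_rev <- pool_posterior(chains[c(3, 1, 2)], st)
  expect_equal(sort(pooled_rev$rate_fission), sort(pooled$rate_fission))
})

test_that("burnin arithmetic matches the sampling design", {
  st <- mcmc_settings(generations = 1000, burnin_fraction = 0.25,
                      samples_per_tree = 100, seed = 1)
  expect_equal(floor(st$burnin_fraction * st$generations), 250)
  expect_error(mcmc_settings(generations = 100, samples_per_tree = 90),
               "post-burnin")
})

test_that("HPD intervals are the shortest windows (brute-force checked)", {
  expect_equal(hpd_interval(rep(3.5, 10)), c(low = 3.5, high = 3.5))
  expect_error(hpd_interval(numeric(0)), "draws")

  brute_hpd <- function(x, mass) {
    x <- sort(x)
    m <- ceiling(mass * length(x))
    best <- c(-Inf, Inf)
    for (i in seq_len(length(x) - m + 1)) {
      if (x[i + m - 1] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + m - 1])
    }
    setNames(best, c("low", "high"))
  }
  x <- as.numeric(1:100)
  expect_equal(hpd_interval(x, 0.95), brute_hpd(x, 0.95))
  expect_equal(diff(unname(hpd_interval(x, 0.95))), 94) # 95 draws in window
  set.seed(14)
  for (i in 1:5) {
    y <- rexp(200, 0.3)
    expect_equal(hpd_interval(y, 0.9), brute_hpd(y, 0.9))
  }
  set.seed(15)
  z <- stats::rnorm(50000)
  h <- hpd_interval(z, 0.95)
  expect_equal(unname(h["low"]), -1.96, tolerance = 0.05)
  expect_equal(unname(h["high"]), 1.96, tolerance = 0.05)
})

test_that("rate comparison flags disjoint and overlapping intervals", {
  a <- tibble::tibble(tree = 1, generation = 1:100,
                      rate_fission = seq(0, 1, length.out = 100))
  class(a) <- c("posterior_rates", class(a))
  cmp_same <- compare_rates(a, a, "rate_fission")
  expect_false(cmp_same$disjoint)
  b <- a
  b$rate_fission <- b$rate_fission + 10
  expect_true(compare_rates(a, b, "rate_fission")$disjoint)
  expect_error(compare_rates(a, b, "rate_polyploidy"), "not found")
})

test_that("pooled posterior recovers moderate unit-tree rates", {
  set.seed(77)
  tr <- ape::rcoal(200)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  truth <- chromosome_model(n_max = 40, rate_fission = 8, rate_fusion = 8,
                            rate_polyploidy = 0.5)
  sim <- simulate_chromosomes(tr, truth, root_state = 10, seed = 78)
  st <- mcmc_settings(generations = 600, samples_per_tree = 100, seed = 79)
  ch <- run_mcmc(tr, as.list(sim$tip_counts), settings = st)
  post <- pool_posterior(list(ch), st)
  med <- tidy(post)
  fis <- med$median[med$parameter == "rate_fission"]
  fus <- med$median[med$parameter == "rate_fusion"]
  expect_gt(fis, 8 / 1.5); expect_lt(fis, 8 * 1.5)
  expect_gt(fus, 8 / 1.5); expect_lt(fus, 8 * 1.5)
})
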