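test_that("rate matrices follow the fission/fusion/polyploidy rules", {
  # all rates zero -> zero generator
  Q0 <- build_rate_matrix(chromosome_model(n_max = 5))
  expect_true(all(Q0 == 0))

  # fission only on states 2..4: boundary truncation at n_max
  Qf <- build_rate_matrix(chromosome_model(n_min = 2, n_max = 4,
                                           rate_fission = 1))
  expect_equal(Qf["2", "3"], 1)
  expect_equal(Qf["3", "4"], 1)
  expect_equal(unname(diag(Qf)), c(-1, -1, 0))

  # polyploidy targets 2n only while in range
  Qp <- build_rate_matrix(chromosome_model(n_min = 2, n_max = 8,
                                           rate_polyploidy = 0.1))
  for (n in 2:8) {
    for (m in 2:8) {
      expected <- if (m == 2 * n) 0.1 else if (m == n - 1 || m == n + 1) 0 else 0
      if (m != n) expect_equal(Qp[as.character(n), as.character(m)], expected)
    }
  }
  expect_equal(Qp["3", "6"], 0.1)
  expect_false("10" %in% colnames(Qp))

  # rows always sum to zero
  Qall <- build_rate_matrix(chromosome_model(
    n_max = 12, rate_fission = 2, rate_fusion = 3, rate_polyploidy = 0.4,
    rate_demiploidy = 0.2))
  expect_lt(max(abs(rowSums(Qall))), 1e-12)
  expect_equal(Qall["4", "6"], 0.2) # demiploidy 4 -> ceil(6)
  expect_equal(Qall["4", "8"], 0.4)

  expect_warning(
    build_rate_matrix(chromosome_model(n_min = 5, n_max = 9,
                                       rate_polyploidy = 1)),
    "unreachable")
})

test_that("trait-linked models double the state space with block structure", {
  m <- chromosome_model(n_max = 4, rate_fission = 1, rate_fusion = 2,
                        trait = list(q01 = 0.3, q10 = 0.7,
                                     rate_fission2 = 5, rate_fusion2 = 6))
  Q <- build_rate_matrix(m)
  expect_equal(dim(Q), c(8, 8))
  expect_equal(Q["2.0", "3.0"], 1)
  expect_equal(Q["2.1", "3.1"], 5)
  expect_equal(Q["3.0", "3.1"], 0.3)
  expect_equal(Q["3.1", "3.0"], 0.7)
  expect_equal(Q["2.0", "3.1"], 0)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
})

test_that("unit-tree rescaling and rate back-transform invert each other", {
  tr <- ape::read.tree(text = "((A:100,B:100):150,C:250);")
  r <- rescale_to_unit(tr)
  expect_equal(r$scale_factor, 250)
  expect_equal(max(ape::node.depth.edgelength(r$tree)), 1)
  back <- r$tree
  back$edge.length <- back$edge.length * r$scale_factor
  expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-12)

  r2 <- rescale_to_unit(r$tree)
  expect_equal(r2$scale_factor, 1)
  expect_equal(r2$tree$edge.length, r$tree$edge.length)

  expect_equal(back_transform_rates(0.5, 250), 0.002)
  expect_equal(back_transform_rates(3.7, 1), 3.7)
  expect_equal(back_transform_rates(0.5 * 250, 250), 0.5) # inverse
})

test_that("branch propagators are stochastic matrices", {
  set.seed(11)
  for (i in 1:5) {
    m <- chromosome_model(n_max = sample(4:12, 1),
                          rate_fission = runif(1, 0, 5),
                          rate_fusion = runif(1, 0, 5),
                          rate_polyploidy = runif(1, 0, 2))
    prop <- make_propagator(build_rate_matrix(m))
    for (t in c(0, 0.01, 0.3, 2)) {
      P <- prop$matrix(t)
      expect_true(all(P >= 0))
      expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    }
  }
})

test_that("two-tip likelihood matches the closed-form matrix-exponential sum", {
  m <- chromosome_model(n_max = 5, rate_fission = 0.8, rate_fusion = 1.1,
                        rate_polyploidy = 0.2)
  Q <- build_rate_matrix(m)
  tr <- ape::read.tree(text = "(A:0.4,B:0.9);")
  tm <- tip_state_matrix(list(A = 2L, B = 4L), m)
  k <- nrow(Q)
  Pa <- as.matrix(Matrix::expm(Q * 0.4))
  Pb <- as.matrix(Matrix::expm(Q * 0.9))
  expected <- log(sum(vapply(1:k, function(r) {
    (1 / k) * Pa[r, 2] * Pb[r, 4]
  }, numeric(1))))
  expect_equal(log_likelihood(tr, tm, Q), expected, tolerance = 1e-10)
})

test_that("zero-length branches give the no-change likelihood", {
  m <- chromosome_model(n_max = 6, rate_fission = 2, rate_fusion = 1)
  Q <- build_rate_matrix(m)
  tr <- ape::read.tree(text = "(A:0,B:0);")
  tm <- tip_state_matrix(list(A = 3L, B = 3L), m)
  expect_equal(log_likelihood(tr, tm, Q), log(1 / 6))
})

test_that("likelihood is invariant to child order and to rate/time rescaling", {
  m <- chromosome_model(n_max = 6, rate_fission = 1.3, rate_fusion = 0.6,
                        rate_polyploidy = 0.15)
  Q <- build_rate_matrix(m)
  t1 <- ape::read.tree(text = "((A:0.2,B:0.7):0.3,C:0.9);")
  t2 <- ape::read.tree(text = "((B:0.7,A:0.2):0.3,C:0.9);")
  counts <- list(A = 2L, B = c(3L, 4L), C = 5L)
  tm <- tip_state_matrix(counts, m)
  expect_equal(log_likelihood(t1, tm, Q), log_likelihood(t2, tm, Q),
               tolerance = 1e-12)

  c_ <- 7.3
  t3 <- t1
  t3$edge.length <- t3$edge.length / c_
  expect_equal(log_likelihood(t1, tm, Q), log_likelihood(t3, tm, c_ * Q),
               tolerance = 1e-9)
})

test_that("the complex model nests the simple model exactly at zero polyploidy", {
  simple <- chromosome_model(n_max = 7, rate_fission = 1.2, rate_fusion = 0.9)
  complex <- chromosome_model(n_max = 7, rate_fission = 1.2, rate_fusion = 0.9,
                              rate_polyploidy = 0)
  expect_identical(build_rate_matrix(simple), build_rate_matrix(complex))
})

test_that("degenerate tip inputs raise informative errors", {
  m <- chromosome_model(n_max = 5, rate_fission = 1)
  Q <- build_rate_matrix(m)
  tr <- ape::read.tree(text = "(A:1,B:1);")
  tm <- tip_state_matrix(list(A = 2L, B = 3L), m)
  tm["B", ] <- 0
  expect_error(log_likelihood(tr, tm, Q), "B")
  expect_error(tip_state_matrix(list(A = 2L, B = 9L), m), "bounds")
  expect_error(rescale_to_unit(ape::read.tree(text = "(A:0,B:0);")), "root depth")
})

test_that("trait-linked likelihood reduces to the plain model when the trait is inert", {
  # q01 = q10 = 0 and all tips in trait state 0: the state-1 block is
  # unreachable, so the joint likelihood is the plain one times the root
  # prior mass of the state-0 block (1/2 under the uniform prior).
  base <- chromosome_model(n_max = 5, rate_fission = 1.1, rate_fusion = 0.7)
  joint <- chromosome_model(n_max = 5, rate_fission = 1.1, rate_fusion = 0.7,
                            trait = list(q01 = 0, q10 = 0))
  tr <- ape::read.tree(text = "((A:0.3,B:0.6):0.2,C:0.8);")
  counts <- list(A = 2L, B = 3L, C = 4L)
  tm0 <- tip_state_matrix(counts, base)
  tmj <- tip_state_matrix(counts, joint, trait = c(A = 0, B = 0, C = 0))
  ll0 <- log_likelihood(tr, tm0, build_rate_matrix(base))
  llj <- log_likelihood(tr, tmj, build_rate_matrix(joint))
  expect_equal(llj, ll0 + log(0.5), tolerance = 1e-9)
})
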