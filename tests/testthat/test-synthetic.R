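test_that("generators are pure functions of (config, seed)", {
  cfg <- simulation_config(n_tips = 12, n_trees = 2, root_age = 50, seed = 3,
                           model = chromosome_model(n_max = 20,
                                                    rate_fission = 0.05,
                                                    rate_fusion = 0.05),
                           root_state = 8)
  a <- simulate_tree_set(cfg)
  b <- simulate_tree_set(cfg)
  expect_identical(lapply(unclass(a), `[[`, "edge.length"),
                   lapply(unclass(b), `[[`, "edge.length"))
  s1 <- simulate_chromosomes(a[[1]], cfg$model, 8, seed = 4)
  s2 <- simulate_chromosomes(a[[1]], cfg$model, 8, seed = 4)
  expect_identical(s1$tip_counts, s2$tip_counts)
  expect_identical(s1$history, s2$history)
  s3 <- simulate_chromosomes(a[[1]], cfg$model, 8, seed = 5)
  expect_false(identical(s1$tip_counts, s3$tip_counts))
})

test_that("tree sets honour tip count, root age and shared labels", {
  cfg <- simulation_config(n_tips = 9, n_trees = 3, root_age = 120, seed = 8)
  ts <- simulate_tree_set(cfg)
  expect_length(ts, 3)
  for (t in ts) {
    expect_length(t$tip.label, 9)
    expect_equal(max(ape::node.depth.edgelength(t)), 120, tolerance = 1e-9)
    expect_true(ape::is.ultrametric(t, tol = 1e-6))
  }
  expect_identical(sort(ts[[1]]$tip.label), sort(ts[[3]]$tip.label))

  cherry <- simulate_tree_set(simulation_config(n_tips = 2, n_trees = 1,
                                                root_age = 10, seed = 2))
  expect_length(cherry[[1]]$tip.label, 2)
  expect_equal(max(ape::node.depth.edgelength(cherry[[1]])), 10)
})

test_that("pure-birth branching-time proportions follow the Yule model", {
  # with death = 0, inter-speciation intervals are Exp(k * b); compare the
  # mean proportion of tree depth in the last interval against the Yule
  # expectation, across replicates of the unrescaled generator
  n <- 12; b <- 0.4
  deepest <- replicate(150, {
    cfg <- simulation_config(n_tips = n, birth = b, death = 0,
                             n_trees = 1, seed = sample.int(1e6, 1))
    tr <- simulate_tree_set(cfg, rescale_to_root_age = FALSE)[[1]]
    bt <- sort(ape::branching.times(tr), decreasing = TRUE)
    unname(bt[1] - bt[2]) # duration of the 2-lineage epoch
  })
  expect_equal(mean(deepest), 1 / (2 * b), tolerance = 0.1)
})

test_that("chromosome histories replay exactly to the recorded tip states", {
  cfg <- simulation_config(n_tips = 15, n_trees = 1, root_age = 80, seed = 6,
                           model = chromosome_model(n_max = 30,
                                                    rate_fission = 0.02,
                                                    rate_fusion = 0.02,
                                                    rate_polyploidy = 0.002),
                           root_state = 10)
  tr <- simulate_tree_set(cfg)[[1]]
  sim <- simulate_chromosomes(tr, cfg$model, 10, seed = 7)
  post <- sim$tree # postorder copy used in simulation
  ntip <- length(post$tip.label)
  states <- sim$states
  node_state <- integer(ntip + post$Nnode)
  node_state[ntip + 1] <- match(10, states)
  for (e in rev(seq_len(nrow(post$edge)))) {
    cur <- node_state[post$edge[e, 1]]
    ev <- sim$history[sim$history$edge == e, , drop = FALSE]
    if (nrow(ev) > 0) {
      ev <- ev[order(ev$time), ]
      for (j in seq_len(nrow(ev))) {
        expect_equal(ev$from[j], cur)
        cur <- ev$to[j]
      }
    }
    node_state[post$edge[e, 2]] <- cur
  }
  expect_equal(unname(states[node_state[seq_len(ntip)]]),
               unname(sim$tip_counts[post$tip.label]))
})

test_that("binary traits reach their stationary frequency on deep trees", {
  cfg <- simulation_config(n_tips = 300, n_trees = 8, root_age = 300, seed = 12)
  ts <- simulate_tree_set(cfg)
  q01 <- 0.03; q10 <- 0.01 # stationary P(state 2) = 0.75
  frac <- vapply(seq_along(ts), function(i) {
    sim <- simulate_binary_trait(ts[[i]], q01, q10, 1, seed = 100 + i)
    mean(sim$tip_states == "1")
  }, numeric(1))
  expect_equal(mean(frac), q01 / (q01 + q10), tolerance = 0.05)

  still <- simulate_binary_trait(ts[[1]], 0, 0, 2, seed = 1,
                                 labels = c("XO", "XY"))
  expect_true(all(still$tip_states == "XY"))
  expect_equal(nrow(still$history), 0)
})

test_that("synthetic karyotype tables round-trip and honour fractions", {
  cfg <- simulation_config(n_tips = 30, n_trees = 1, root_age = 60, seed = 21,
                           model = chromosome_model(n_max = 25,
                                                    rate_fission = 0.03,
                                                    rate_fusion = 0.03),
                           root_state = 9, ambiguity_fraction = 0,
                           genome_size_missing = 1)
  ds <- simulate_dataset(cfg, per_tree_data = FALSE)
  rec <- ds$records
  expect_true(all(lengths(rec$haploid_counts) == 1)) # no ambiguity injected
  expect_true(all(is.na(rec$genome_size)))           # fully missing
  path <- withr::local_tempfile(fileext = ".csv")
  write_karyotype_table(rec, path)
  back <- read_karyotype_table(path)
  expect_equal(back$species, rec$species)
  expect_equal(back$haploid_counts, rec$haploid_counts)
  expect_equal(back$scs, rec$scs)

  cfg2 <- simulation_config(n_tips = 40, n_trees = 1, seed = 22,
                            ambiguity_fraction = 1)
  ds2 <- simulate_dataset(cfg2, per_tree_data = FALSE)
  expect_true(all(lengths(ds2$records$haploid_counts) >= 2 |
                    vapply(ds2$records$haploid_counts, function(x)
                      1L %in% x, logical(1))))
  cfg_bad <- cfg2
  cfg_bad$ambiguity_fraction <- 2
  expect_error(
    build_karyotype_table(cfg_bad, ds2$trees, ds2$chrom[[1]]$tip_counts),
    "fractions")
})
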