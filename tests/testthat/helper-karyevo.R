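# Shared fixtures and independent oracles for the test suite.

# Independent brute-force likelihood: sum over all internal-node state
# assignments, with per-edge transition probabilities from Matrix::expm
# (scaling-and-squaring, independent of the package's propagator).
brute_force_loglik <- function(tree, tipmat, Q, prior = NULL) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- tr$Nnode
  k <- nrow(Q)
  if (is.null(prior)) prior <- rep(1 / k, k)
  Pm <- lapply(seq_len(nrow(tr$edge)), function(e) {
    as.matrix(Matrix::expm(Q * tr$edge.length[e]))
  })
  tm <- tipmat[tr$tip.label, , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  tot <- 0
  for (gi in seq_len(nrow(grid))) {
    assign <- grid[gi, ]
    w <- prior[assign[1]] # internal node 1 (= ntip + 1) is the root
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      row <- Pm[[e]][assign[par - ntip], ]
      w <- w * if (ch <= ntip) sum(row * tm[ch, ]) else row[assign[ch - ntip]]
    }
    tot <- tot + w
  }
  unname(log(tot))
}

# Brute-force marginal distribution at one internal node (same enumeration).
brute_force_marginal <- function(tree, tipmat, Q, node, prior = NULL) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- tr$Nnode
  k <- nrow(Q)
  if (is.null(prior)) prior <- rep(1 / k, k)
  Pm <- lapply(seq_len(nrow(tr$edge)), function(e) {
    as.matrix(Matrix::expm(Q * tr$edge.length[e]))
  })
  tm <- tipmat[tr$tip.label, , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  mass <- numeric(k)
  for (gi in seq_len(nrow(grid))) {
    assign <- grid[gi, ]
    w <- prior[assign[1]]
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      row <- Pm[[e]][assign[par - ntip], ]
      w <- w * if (ch <= ntip) sum(row * tm[ch, ]) else row[assign[ch - ntip]]
    }
    mass[assign[node - ntip]] <- mass[assign[node - ntip]] + w
  }
  mass / sum(mass)
}

# A small random ultrametric tree with given tip count.
random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

# Random small chromosome model + tip data for oracle comparisons.
random_instance <- function(seed) {
  set.seed(seed)
  ntips <- sample(2:4, 1)
  tree <- ape::rtree(ntips)
  tree$edge.length <- runif(nrow(tree$edge), 0.05, 1.5)
  n_max <- sample(3:6, 1)
  model <- chromosome_model(n_max = n_max, rate_fission = runif(1, 0, 3),
                            rate_fusion = runif(1, 0, 3),
                            rate_polyploidy = runif(1, 0, 1))
  counts <- lapply(seq_len(ntips), function(i) {
    r <- runif(1)
    if (r < 0.15) NULL # missing
    else if (r < 0.4) sort(sample(1:n_max, 2)) # ambiguous
    else sample(1:n_max, 1)
  })
  names(counts) <- tree$tip.label
  list(tree = tree, model = model, counts = counts,
       tipmat = tip_state_matrix(counts, model))
}
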