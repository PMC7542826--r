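#' Configuration for synthetic karyotype datasets
#'
#' Bundles the generative settings used to emulate an empirical comparative
#' dataset: a posterior-like set of time-calibrated birth-death trees, a
#' chromosome-number history under the fission/fusion/polyploidy CTMC, binary
#' traits (sex chromosome system, reproductive mode) and genome sizes.
#' Defaults mirror the scale of the Polyneoptera analysis this package
#' reproduces: order-sized clades of 100-250 tips on ~300 MY trees, haploid
#' numbers roughly 2-40, per-MY rates in the 0.003-0.42 band, a minority of
#' asexual lineages and genome sizes spanning ~2,000-18,000 Mbp.
#'
#' @param n_tips Number of tips per tree.
#' @param birth,death Birth-death rates for tree shape simulation.
#' @param root_age Root depth in MY; trees are scaled to this depth.
#' @param n_trees Number of trees in the set (shared tip labels).
#' @param model A [chromosome_model()] with the true per-MY rates.
#' @param root_state Haploid number at the root.
#' @param scs_q01,scs_q10 Per-MY SCS gain/loss rates (XO -> XY, XY -> XO).
#' @param scs_root Root SCS state (1 = XO, 2 = XY).
#' @param repro_q01,repro_q10 Per-MY sexual -> asexual and back rates.
#' @param gs_meanlog,gs_sdlog Log-normal genome-size parameters (Mbp).
#' @param gs_per_chromosome Additive genome-size component per chromosome
#'   (Mbp per haploid chromosome, default 0).
#' @param ambiguity_fraction Fraction of species given a two-value candidate
#'   count set (the true count plus a neighbour within 1).
#' @param genome_size_missing Fraction of species with missing genome size.
#' @param genus_size Tips per synthetic genus.
#' @param n_orders Number of synthetic orders (tips are split into contiguous
#'   clades of the first tree).
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_tips = 100, birth = 0.05, death = 0.02,
                              root_age = 300, n_trees = 100,
                              model = chromosome_model(
                                n_max = 50, rate_fission = 0.385,
                                rate_fusion = 0.420, rate_polyploidy = 0.004),
                              root_state = 7,
                              scs_q01 = 0.002, scs_q10 = 0.002, scs_root = 1,
                              repro_q01 = 0.001, repro_q10 = 0.01,
                              gs_meanlog = log(6000), gs_sdlog = 0.5,
                              gs_per_chromosome = 0,
                              ambiguity_fraction = 0.1,
                              genome_size_missing = 0.7,
                              genus_size = 5, n_orders = 2, seed = 1) {
  stopifnot(n_tips >= 2, birth > 0, death >= 0, root_age > 0, n_trees >= 1,
            root_state >= model$n_min, root_state <= model$n_max,
            ambiguity_fraction >= 0, ambiguity_fraction <= 1,
            genome_size_missing >= 0, genome_size_missing <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a posterior-like set of time-calibrated trees
#'
#' Simulates `n_trees` birth-death trees conditioned on the number of tips
#' (via `phytools::pbtree`) and standardises each to the configured root age
#' — the shape of an empirical posterior sample of time-calibrated trees,
#' whose depth is set by the calibrations. Tip labels (`t1..tn`) are shared
#' across trees.
#'
#' @param config A [simulation_config()].
#' @param rescale_to_root_age If `FALSE`, trees keep their simulated depths
#'   (used to check the generator's branching-time distribution).
#' @return A `posterior_trees` object.
#' @export
simulate_tree_set <- function(config, rescale_to_root_age = TRUE) {
  set.seed(sub_seed(config$seed, 0L, 11L))
  trees <- vector("list", config$n_trees)
  for (i in seq_len(config$n_trees)) {
    t <- NULL
    for (attempt in 1:50) { # rejection budget: full-extinction replicates
      t <- tryCatch(
        phytools::pbtree(b = config$birth, d = config$death,
                         n = config$n_tips, quiet = TRUE, extant.only = TRUE),
        error = function(e) NULL)
      if (!is.null(t) && length(t$tip.label) == config$n_tips) break
      t <- NULL
    }
    if (is.null(t)) {
      abort("Tree simulation failed after 50 attempts; adjust birth/death rates.")
    }
    if (rescale_to_root_age) {
      t$edge.length <- t$edge.length * config$root_age / tree_root_depth(t)
    }
    t$tip.label <- paste0("t", seq_len(config$n_tips))
    trees[[i]] <- t
  }
  as_tree_set(trees)
}

# Preorder Gillespie simulation of a CTMC (given an event table) down a tree.
# Returns integer tip states (indices into the state space) and the realized
# event history.
sim_ctmc_on_tree <- function(tree, etab, root_index) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nedge <- nrow(tr$edge)
  st <- integer(ntip + tr$Nnode)
  st[ntip + 1L] <- root_index
  hist <- vector("list", nedge)
  for (e in rev(seq_len(nedge))) {
    path <- sim_path_forward(etab, st[tr$edge[e, 1]], tr$edge.length[e])
    st[tr$edge[e, 2]] <- path$end
    if (nrow(path$events) > 0) {
      path$events$edge <- e
      path$events$child_node <- tr$edge[e, 2]
    }
    hist[[e]] <- path$events
  }
  history <- dplyr::bind_rows(hist)
  tips <- setNames(st[seq_len(ntip)], tr$tip.label)
  list(tip_states = tips, history = tibble::as_tibble(history), node_states = st,
       tree = tr)
}

#' Simulate chromosome-number evolution along a tree
#'
#' Exact event sampling (exponential waiting times with the current state's
#' total exit rate, categorical event choice) from the root down every
#' branch; both the tip states and the realized per-branch event history are
#' returned, so simulations can be replayed and event counts compared with
#' analytic expectations.
#'
#' @param tree Rooted `phylo`; branch lengths in the model's time units.
#' @param model A [chromosome_model()] holding the true rates.
#' @param root_state Haploid number at the root.
#' @param seed Integer seed.
#' @return List with `tip_counts` (named integer vector of haploid numbers),
#'   `history` (tibble of events: time within branch, from/to state indices,
#'   `type`, `edge`, `child_node`) and `node_states`.
#' @export
simulate_chromosomes <- function(tree, model, root_state, seed = 1) {
  assert_tree(tree)
  stopifnot(root_state >= model$n_min, root_state <= model$n_max)
  set.seed(as.integer(seed) %% 2147483647)
  etab <- event_table(model)
  ns <- model$n_min:model$n_max
  sim <- sim_ctmc_on_tree(tree, etab, match(root_state, ns))
  list(tip_counts = setNames(ns[sim$tip_states], names(sim$tip_states)),
       history = sim$history, node_states = sim$node_states, tree = sim$tree,
       states = ns)
}

#' Simulate a binary trait along a tree
#'
#' Two-state CTMC simulation used for sex chromosome systems (XO/XY) and
#' reproductive mode (sexual/asexual).
#'
#' @param tree Rooted `phylo`.
#' @param q01 Rate state 1 -> state 2; `q10` the reverse.
#' @param q10 See `q01`.
#' @param root_state 1 or 2.
#' @param seed Integer seed.
#' @param labels Length-2 character vector of state labels.
#' @return List with `tip_states` (named character vector) and `history`.
#' @export
simulate_binary_trait <- function(tree, q01, q10, root_state = 1, seed = 1,
                                  labels = c("0", "1")) {
  assert_tree(tree)
  stopifnot(q01 >= 0, q10 >= 0, root_state %in% c(1, 2))
  set.seed(as.integer(seed) %% 2147483647)
  Q <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE,
              dimnames = list(labels, labels))
  etab <- event_table(Q)
  sim <- sim_ctmc_on_tree(tree, etab, root_state)
  list(tip_states = setNames(labels[sim$tip_states], names(sim$tip_states)),
       history = sim$history, node_states = sim$node_states)
}

#' Assemble a synthetic karyotype table
#'
#' Combines simulated tip data into the standard karyotype record tibble,
#' assigning tips to synthetic genera and orders, optionally injecting count
#' ambiguity (a two-value candidate set within one of the truth) and
#' genome-size missingness at configured fractions. Orders are contiguous
#' clades of the first tree so order-level analyses see real phylogenetic
#' structure.
#'
#' @param config A [simulation_config()].
#' @param trees A tree set from [simulate_tree_set()].
#' @param tip_counts Named haploid counts (from [simulate_chromosomes()]).
#' @param scs Named SCS states (from [simulate_binary_trait()] with labels
#'   `c("XO","XY")`), or `NULL`.
#' @param repro Named reproductive modes (labels `c("sexual","asexual")`), or
#'   `NULL`.
#' @return A karyotype record tibble (CSV-writable with
#'   [write_karyotype_table()]).
#' @export
build_karyotype_table <- function(config, trees, tip_counts, scs = NULL,
                                  repro = NULL) {
  if (config$ambiguity_fraction < 0 || config$ambiguity_fraction > 1 ||
      config$genome_size_missing < 0 || config$genome_size_missing > 1) {
    abort("Ambiguity and missingness fractions must lie in [0, 1].")
  }
  set.seed(sub_seed(config$seed, 0L, 13L))
  tree1 <- trees[[1]]
  sp <- tree1$tip.label
  n <- length(sp)
  # contiguous clades of the first tree define synthetic orders
  ord_assign <- rep("Order1", n)
  if (config$n_orders > 1) {
    tr <- stats::reorder(tree1, "postorder")
    target <- ceiling(n / config$n_orders)
    # grow orders by walking tips in the tree's ladderized order
    tip_order <- tr$edge[tr$edge[, 2] <= n, 2]
    ord_assign[tip_order] <- paste0("Order", pmin(
      config$n_orders, ((seq_len(n) - 1) %/% target) + 1))
  }
  genus_assign <- paste0("Genus", ((match(sp, sp) - 1) %/% config$genus_size) + 1)
  counts <- lapply(sp, function(s) {
    ct <- unname(tip_counts[[s]])
    if (runif(1) < config$ambiguity_fraction) {
      nb <- ct + sample(c(-1L, 1L), 1)
      sort(unique(c(ct, max(1L, nb))))
    } else ct
  })
  gsize <- exp(stats::rnorm(n, config$gs_meanlog, config$gs_sdlog)) +
    config$gs_per_chromosome * vapply(counts, function(x) mean(x), numeric(1))
  gsize[runif(n) < config$genome_size_missing] <- NA_real_
  tibble::tibble(
    species = sp,
    genus = genus_assign,
    order = ord_assign,
    haploid_counts = counts,
    scs = if (is.null(scs)) rep("unknown", n) else unname(scs[sp]),
    reproductive_mode = if (is.null(repro)) rep("unknown", n) else unname(repro[sp]),
    genome_size = gsize
  )
}

#' Simulate a complete synthetic dataset
#'
#' Runs the full generator: tree set, chromosome numbers, SCS and
#' reproductive mode, and the assembled karyotype table. Chromosome data are
#' simulated on each tree separately (returned per tree) so that parameter
#' recovery can be assessed without tree misspecification; the karyotype
#' table is built from the first tree's data.
#'
#' @param config A [simulation_config()].
#' @param per_tree_data Simulate chromosome data on every tree (default) or
#'   only the first.
#' @return List with `trees`, `chrom` (list per tree), `scs`, `repro`,
#'   `records`, `config`.
#' @export
simulate_dataset <- function(config, per_tree_data = TRUE) {
  trees <- simulate_tree_set(config)
  idx <- if (per_tree_data) seq_along(trees) else 1L
  chrom <- lapply(idx, function(i) {
    simulate_chromosomes(trees[[i]], config$model, config$root_state,
                         seed = sub_seed(config$seed, i, 17L))
  })
  scs <- simulate_binary_trait(trees[[1]], config$scs_q01, config$scs_q10,
                               config$scs_root,
                               seed = sub_seed(config$seed, 1L, 19L),
                               labels = c("XO", "XY"))
  repro <- simulate_binary_trait(trees[[1]], config$repro_q01, config$repro_q10,
                                 1, seed = sub_seed(config$seed, 1L, 23L),
                                 labels = c("sexual", "asexual"))
  records <- build_karyotype_table(config, trees,
                                   chrom[[1]]$tip_counts,
                                   scs = scs$tip_states,
                                   repro = repro$tip_states)
  list(trees = trees, chrom = chrom, scs = scs, repro = repro,
       records = records, config = config)
}
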