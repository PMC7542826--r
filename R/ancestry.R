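#' Marginal ancestral state reconstruction under a fixed-rate CTMC
#'
#' Computes, for every node of the tree (tips included), the marginal
#' posterior distribution over states given the tip data and a fixed rate
#' matrix, by combining the rootward (pruning) conditionals with the
#' tipward ("outside") conditionals. In the chromosome analysis the rates
#' are taken as each tree's posterior-mean estimates; the same routine also
#' serves the two-state SCS model. Ties in the most-probable state are broken
#' towards the smaller (first-ordered) state.
#'
#' @inheritParams log_likelihood
#' @return An object of class `ancestral_reconstruction`: list with `probs`
#'   (matrix, rows = nodes in ape numbering `1..(2n-1)`, columns = states),
#'   `map_state` (most-probable state label per node), `tree`, `Q`.
#' @export
marginal_ancestral_states <- function(tree, tipmat, Q, root_prior = "uniform",
                                      propagator = NULL) {
  assert_tree(tree)
  prop <- propagator %||% make_propagator(Q)
  pi0 <- resolve_root_prior(root_prior, Q, tipmat)
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  k <- nrow(Q)
  nedge <- nrow(tr$edge)

  L <- matrix(1, ntip + nnode, k) # rootward conditionals, renormalised
  L[seq_len(ntip), ] <- tipmat[tr$tip.label, , drop = FALSE]
  bad <- which(rowSums(L[seq_len(ntip), , drop = FALSE]) <= 0)
  if (length(bad) > 0) {
    abort(paste0("All-zero tip state vector for: ",
                 paste(tr$tip.label[bad], collapse = ", ")))
  }
  Pmats <- vector("list", nedge)
  vmat <- matrix(NA_real_, nedge, k) # normalised P_e %*% L_child per edge
  for (e in seq_len(nedge)) {
    ch <- tr$edge[e, 2]
    Pmats[[e]] <- prop$matrix(tr$edge.length[e])
    v <- drop(Pmats[[e]] %*% L[ch, ])
    s <- sum(v)
    if (s <= 0) abort("Zero likelihood encountered in reconstruction.")
    vmat[e, ] <- v / s
    L[tr$edge[e, 1], ] <- L[tr$edge[e, 1], ] * vmat[e, ]
    L[tr$edge[e, 1], ] <- L[tr$edge[e, 1], ] / sum(L[tr$edge[e, 1], ])
  }

  # outside pass (preorder = reverse postorder edge order)
  G <- matrix(NA_real_, ntip + nnode, k)
  root <- ntip + 1L
  G[root, ] <- pi0
  for (e in rev(seq_len(nedge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sib <- which(tr$edge[, 1] == par & seq_len(nedge) != e)
    H <- G[par, ]
    for (e2 in sib) H <- H * vmat[e2, ]
    g <- drop(crossprod(Pmats[[e]], H)) # t(P) %*% H
    s <- sum(g)
    if (s <= 0) abort("Zero outside conditional encountered.")
    G[ch, ] <- g / s
  }
  probs <- G * L
  probs <- probs / rowSums(probs)
  colnames(probs) <- colnames(Q)
  map_state <- colnames(Q)[apply(probs, 1, which.max)] # ties -> first/smaller
  structure(list(probs = probs, map_state = map_state, tree = tree, Q = Q,
                 root_prior = pi0),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  cat(sprintf("<ancestral_reconstruction> %d tips, %d states; root MAP state %s\n",
              ntip, ncol(x$probs), x$map_state[ntip + 1]))
  invisible(x)
}

#' State probabilities at the most recent common ancestor of a tip set
#'
#' @param recon An [marginal_ancestral_states()] result.
#' @param tipset Character vector of tip labels (a single tip returns that
#'   tip's own, typically degenerate, vector).
#' @return Named probability vector over states.
#' @export
mrca_state <- function(recon, tipset) {
  tree <- recon$tree
  if (length(tipset) == 0) abort("tipset must be non-empty.")
  miss <- setdiff(tipset, tree$tip.label)
  if (length(miss) > 0) {
    abort(paste0("Tips not in tree: ", paste(miss, collapse = ", ")))
  }
  node <- if (length(tipset) == 1) {
    match(tipset, tree$tip.label)
  } else {
    ape::getMRCA(tree, tipset)
  }
  recon$probs[node, ]
}

#' Average MRCA state probabilities across a posterior set of reconstructions
#'
#' The combination rule behind per-order ancestral-state pie charts: the MRCA
#' probability vector is computed on each tree and averaged across the
#' posterior sample.
#'
#' @param recons List of `ancestral_reconstruction` objects (one per tree).
#' @param tipset Tip labels defining the clade.
#' @return Named probability vector over states.
#' @export
average_mrca_state <- function(recons, tipset) {
  vs <- lapply(recons, mrca_state, tipset = tipset)
  Reduce(`+`, vs) / length(vs)
}

#' Two-state all-rates-different (ARD) model fit for sex chromosome systems
#'
#' Fits the Mk2 ARD model (`q01`: state 1 -> state 2 gain rate, `q10`: the
#' reverse) by maximising the pruning likelihood on each tree of a posterior
#' set, and summarises across trees. multi-XY systems should be collapsed to
#' XY beforehand so the character is binary (see [collapse_scs()]); tips with
#' unknown state (or flagged for exclusion, e.g. parthenogens) are dropped.
#'
#' @param trees A `posterior_trees` object, list of trees, or single `phylo`.
#' @param states Named character vector of tip states (two levels, e.g.
#'   `"XO"`/`"XY"`; `NA` or `"unknown"` tips are dropped).
#' @param drop_tips Additional tip labels to exclude before fitting.
#' @param state_order Optional character vector fixing which level is state 1.
#' @return An object of class `mk2_fit`: tibble `fits` with per-tree per-MY
#'   `q01`, `q10`, `log_lik`, `boundary` flag, plus `summary` (pooled means)
#'   and the state labels.
#' @export
fit_mk2_ard <- function(trees, states, drop_tips = character(),
                        state_order = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  states <- states[!is.na(states) & states != "unknown"]
  states <- states[!names(states) %in% drop_tips]
  levs <- state_order %||% sort(unique(states))
  if (length(levs) != 2) {
    abort(sprintf("Mk2 needs exactly two observed states, got: %s",
                  paste(levs, collapse = ", ")))
  }
  one_state <- length(unique(states)) < 2

  fits <- purrr::map_dfr(seq_along(trees), function(i) {
    tree <- trees[[i]]
    keep <- intersect(tree$tip.label, names(states))
    tree <- ape::keep.tip(tree, keep)
    resc <- rescale_to_unit(tree)
    tipmat <- matrix(0, length(keep), 2, dimnames = list(keep, levs))
    tipmat[cbind(keep, unname(states[keep]))] <- 1
    nll <- function(x) {
      Q <- matrix(c(-x[1], x[1], x[2], -x[2]), 2, 2, byrow = TRUE,
                  dimnames = list(levs, levs))
      ll <- log_likelihood(resc$tree, tipmat, Q, "uniform")
      if (!is.finite(ll)) 1e12 else -ll
    }
    best <- NULL
    for (st in list(c(0.5, 0.5), c(2, 2), c(0.05, 0.05))) {
      f <- tryCatch(optim(st, nll, method = "L-BFGS-B", lower = 0,
                          upper = 1000), error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
    }
    if (is.null(best)) abort("Mk2 optimisation failed.")
    tibble::tibble(tree = i,
                   q01 = best$par[1] / resc$scale_factor,
                   q10 = best$par[2] / resc$scale_factor,
                   log_lik = -best$value,
                   scale_factor = resc$scale_factor,
                   boundary = one_state || any(best$par < 1e-8))
  })
  if (any(fits$boundary)) {
    warn("Mk2 fit at the zero boundary for at least one tree; one rate may be unidentifiable.")
  }
  structure(list(
    fits = fits,
    summary = tibble::tibble(parameter = c("q01", "q10"),
                             mean = c(mean(fits$q01), mean(fits$q10)),
                             from = c(levs[1], levs[2]),
                             to = c(levs[2], levs[1])),
    states = levs),
    class = "mk2_fit")
}

#' @export
print.mk2_fit <- function(x, ...) {
  cat(sprintf("<mk2_fit> %d tree(s); states %s -> %s\n", nrow(x$fits),
              x$states[1], x$states[2]))
  print(x$summary)
  invisible(x)
}

#' Collapse sex chromosome systems to a binary XO/XY character
#'
#' multi-XY systems are classified as XY so the character has two states.
#'
#' @param scs Character vector of SCS values.
#' @return Character vector with values `"XO"`, `"XY"` or `NA`.
#' @export
collapse_scs <- function(scs) {
  out <- ifelse(scs %in% c("XY", "multiXY"), "XY",
                ifelse(scs == "XO", "XO", NA_character_))
  out
}

# Decompose a model (or bare Q) into per-state event tables for simulation
# and mapping: for each source state, target states, rates, and event types.
event_table <- function(model_or_Q) {
  if (inherits(model_or_Q, "chromosome_model")) {
    model <- model_or_Q
    Q <- build_rate_matrix(model)
    states <- model_states(model)
    joint <- !is.null(model$trait)
    ns <- model$n_min:model$n_max
    k <- length(ns)
    events <- list()
    add <- function(i, j, rate, type) {
      if (rate > 0) events[[length(events) + 1]] <<-
          list(from = i, to = j, rate = rate, type = type)
    }
    blocks <- if (joint) list(
      list(off = 0L, fis = model$rate_fission, fus = model$rate_fusion,
           pol = model$rate_polyploidy, dem = model$rate_demiploidy),
      list(off = k, fis = model$trait$rate_fission2, fus = model$trait$rate_fusion2,
           pol = model$trait$rate_polyploidy2, dem = model$trait$rate_demiploidy2))
    else list(list(off = 0L, fis = model$rate_fission, fus = model$rate_fusion,
                   pol = model$rate_polyploidy, dem = model$rate_demiploidy))
    for (b in blocks) {
      for (i in seq_len(k)) {
        n <- ns[i]
        if (n + 1 <= model$n_max) add(b$off + i, b$off + i + 1, b$fis, "fission")
        if (n - 1 >= model$n_min) add(b$off + i, b$off + i - 1, b$fus, "fusion")
        if (2 * n <= model$n_max && 2 * n != n) {
          add(b$off + i, b$off + match(2 * n, ns), b$pol, "polyploidy")
        }
        tgt <- ceiling(1.5 * n)
        if (tgt != n && tgt <= model$n_max) {
          add(b$off + i, b$off + match(tgt, ns), b$dem, "demiploidy")
        }
      }
    }
    if (joint) {
      for (i in seq_len(k)) {
        add(i, k + i, model$trait$q01, "trait_gain")
        add(k + i, i, model$trait$q10, "trait_loss")
      }
    }
  } else {
    Q <- model_or_Q
    states <- colnames(Q) %||% as.character(seq_len(nrow(Q)))
    events <- list()
    for (i in seq_len(nrow(Q))) {
      for (j in seq_len(ncol(Q))) {
        if (i != j && Q[i, j] > 0) {
          events[[length(events) + 1]] <-
            list(from = i, to = j, rate = Q[i, j],
                 type = paste0(states[i], "->", states[j]))
        }
      }
    }
  }
  ev <- if (length(events) == 0) {
    tibble::tibble(from = integer(), to = integer(), rate = numeric(),
                   type = character())
  } else {
    dplyr::bind_rows(lapply(events, tibble::as_tibble))
  }
  by_state <- split(ev, factor(ev$from, levels = seq_len(nrow(Q))))
  list(Q = Q, states = states, events = ev, by_state = by_state,
       exit_rate = -diag(Q))
}

# Forward-simulate a CTMC path from state i over duration t.
# Returns list(end, events = data.frame(time, from, to, type)).
sim_path_forward <- function(etab, i, t, force_first = FALSE) {
  times <- numeric(0); froms <- integer(0); tos <- integer(0); types <- character(0)
  cur <- i; now <- 0
  if (force_first) {
    rate <- etab$exit_rate[cur]
    if (rate <= 0) return(NULL)
    # first event time from an exponential truncated to [0, t]
    u <- runif(1)
    now <- -log(1 - u * (1 - exp(-rate * t))) / rate
    ev <- etab$by_state[[cur]]
    j <- sample.int(nrow(ev), 1, prob = ev$rate)
    times <- now; froms <- cur; tos <- ev$to[j]; types <- ev$type[j]
    cur <- ev$to[j]
  }
  repeat {
    rate <- etab$exit_rate[cur]
    if (rate <= 0) break
    now <- now + rexp(1, rate)
    if (now >= t) break
    ev <- etab$by_state[[cur]]
    j <- sample.int(nrow(ev), 1, prob = ev$rate)
    times <- c(times, now); froms <- c(froms, cur); tos <- c(tos, ev$to[j])
    types <- c(types, ev$type[j])
    cur <- ev$to[j]
  }
  list(end = cur,
       events = data.frame(time = times, from = froms, to = tos, type = types,
                           stringsAsFactors = FALSE))
}

# Conditional path sampling from state i to j over t: modified rejection
# sampling with a uniformization fallback (never silent truncation).
sim_path_conditional <- function(etab, i, j, t, max_attempts = 500) {
  if (t <= 0) {
    if (i != j) abort("Impossible endpoint pair on zero-length branch.")
    return(data.frame(time = numeric(0), from = integer(0), to = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  for (a in seq_len(max_attempts)) {
    path <- sim_path_forward(etab, i, t, force_first = (i != j))
    if (is.null(path)) break
    if (path$end == j) return(path$events)
  }
  sim_path_uniformization(etab, i, j, t)
}

# Uniformization: sample the number of jumps of the uniformized chain
# conditional on endpoints, place them uniformly, then sample the state
# sequence by backward recursion over powers of R = I + Q / Lambda.
sim_path_uniformization <- function(etab, i, j, t) {
  Q <- etab$Q
  k <- nrow(Q)
  Lam <- max(-diag(Q))
  if (Lam <= 0) {
    if (i != j) abort("No transitions possible but endpoints differ.")
    return(data.frame(time = numeric(0), from = integer(0), to = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  R <- diag(k) + Q / Lam
  nmax <- max(10, ceiling(Lam * t + 12 * sqrt(Lam * t) + 20))
  Rpow <- vector("list", nmax + 1)
  Rpow[[1]] <- diag(k)
  for (m in seq_len(nmax)) Rpow[[m + 1]] <- Rpow[[m]] %*% R
  wts <- vapply(0:nmax, function(n) {
    stats::dpois(n, Lam * t) * Rpow[[n + 1]][i, j]
  }, numeric(1))
  if (sum(wts) <= 0) abort("Uniformization failed: endpoint pair has zero probability.")
  n <- sample.int(nmax + 1, 1, prob = wts) - 1L
  if (n == 0) {
    return(data.frame(time = numeric(0), from = integer(0), to = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  jump_times <- sort(runif(n, 0, t))
  seqs <- integer(n + 1)
  seqs[1] <- i; seqs[n + 1] <- j
  if (n > 1) {
    for (m in 2:n) {
      w <- R[seqs[m - 1], ] * Rpow[[n - m + 2]][, j] # remaining n - m + 1 steps
      seqs[m] <- sample.int(k, 1, prob = w)
    }
  }
  keep <- which(seqs[-1] != seqs[-(n + 1)]) # drop virtual self-jumps
  if (length(keep) == 0) {
    return(data.frame(time = numeric(0), from = integer(0), to = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  froms <- seqs[keep]; tos <- seqs[keep + 1]
  types <- vapply(seq_along(keep), function(m) {
    ev <- etab$by_state[[froms[m]]]
    cand <- ev[ev$to == tos[m], , drop = FALSE]
    if (nrow(cand) == 1) return(cand$type[1])
    cand$type[sample.int(nrow(cand), 1, prob = cand$rate)]
  }, character(1))
  data.frame(time = jump_times[keep], from = froms, to = tos, type = types,
             stringsAsFactors = FALSE)
}

#' Stochastic character mapping with per-event-type counts
#'
#' Samples full character histories conditional on the tip data: node states
#' are drawn from the marginal/joint reconstruction (root from its marginal,
#' then each child conditional on its parent), and each branch path is
#' sampled conditional on its endpoints by modified rejection sampling with a
#' uniformization fallback. Events are counted per type per map — fission /
#' fusion / polyploidy (/ demiploidy) for chromosome models, `"A->B"` labels
#' for bare rate matrices such as the two-state SCS model.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param tipmat Tip state matrix ([tip_state_matrix()] or hand-built; use a
#'   matrix of ones for unconditioned maps).
#' @param model A [chromosome_model()] or a bare rate matrix.
#' @param n_maps Number of maps (default 100).
#' @param seed Integer seed.
#' @param root_prior Root prior (see [log_likelihood()]).
#' @return Object of class `stochastic_maps`: `counts` (tibble map x type),
#'   `mean_counts` (tibble type, mean), `node_freq` (matrix of sampled
#'   node-state frequencies), `n_maps`.
#' @export
stochastic_map <- function(tree, tipmat, model, n_maps = 100, seed = 1,
                           root_prior = "uniform") {
  assert_tree(tree)
  etab <- event_table(model)
  Q <- etab$Q
  recon <- marginal_ancestral_states(tree, tipmat, Q, root_prior)
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  k <- nrow(Q)
  nedge <- nrow(tr$edge)
  prop <- make_propagator(Q)
  Pmats <- lapply(seq_len(nedge), function(e) prop$matrix(tr$edge.length[e]))
  L <- matrix(1, ntip + tr$Nnode, k)
  L[seq_len(ntip), ] <- tipmat[tr$tip.label, , drop = FALSE]
  for (e in seq_len(nedge)) {
    v <- drop(Pmats[[e]] %*% L[tr$edge[e, 2], ])
    L[tr$edge[e, 1], ] <- L[tr$edge[e, 1], ] * (v / sum(v))
    L[tr$edge[e, 1], ] <- L[tr$edge[e, 1], ] / sum(L[tr$edge[e, 1], ])
  }
  root <- ntip + 1L
  root_marg <- recon$probs[root, ]

  set.seed(as.integer(seed) %% 2147483647)
  all_types <- unique(etab$events$type)
  counts <- matrix(0L, n_maps, length(all_types),
                   dimnames = list(NULL, all_types))
  node_cnt <- matrix(0L, ntip + tr$Nnode, k)
  preorder_edges <- rev(seq_len(nedge))
  for (m in seq_len(n_maps)) {
    st <- integer(ntip + tr$Nnode)
    st[root] <- sample.int(k, 1, prob = root_marg)
    for (e in preorder_edges) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      w <- Pmats[[e]][st[par], ] * L[ch, ]
      st[ch] <- sample.int(k, 1, prob = w)
    }
    node_cnt[cbind(seq_along(st), st)] <- node_cnt[cbind(seq_along(st), st)] + 1L
    for (e in seq_len(nedge)) {
      ev <- sim_path_conditional(etab, st[tr$edge[e, 1]], st[tr$edge[e, 2]],
                                 tr$edge.length[e])
      if (nrow(ev) > 0) {
        tb <- table(ev$type)
        counts[m, names(tb)] <- counts[m, names(tb)] + as.integer(tb)
      }
    }
  }
  if (length(all_types) == 0) {
    counts_tbl <- tibble::tibble(map = integer(), type = character(),
                                 n = integer())
  } else {
    counts_tbl <- tibble::as_tibble(as.data.frame(counts))
    counts_tbl$map <- seq_len(n_maps)
    counts_tbl <- tidyr::pivot_longer(counts_tbl, -"map", names_to = "type",
                                      values_to = "n")
  }
  mean_counts <- dplyr::summarise(dplyr::group_by(counts_tbl, .data$type),
                                  mean = mean(.data$n), .groups = "drop")
  node_freq <- node_cnt / n_maps
  colnames(node_freq) <- etab$states
  # node_freq rows follow the postorder tree's node numbering, which matches
  # the input tree's numbering (reorder only permutes edges)
  structure(list(counts = counts_tbl, mean_counts = mean_counts,
                 node_freq = node_freq, n_maps = n_maps, seed = seed,
                 states = etab$states),
            class = "stochastic_maps")
}

#' @export
print.stochastic_maps <- function(x, ...) {
  cat(sprintf("<stochastic_maps> %d maps\n", x$n_maps))
  print(x$mean_counts)
  invisible(x)
}

#' Compare fusion and fission event counts across a posterior tree set
#'
#' Takes per-tree stochastic-map summaries produced under the chromosome
#' model, extracts the mean per-map count of each event type per tree, and
#' tests fusion against fission counts with a paired t-test across trees.
#'
#' @param maps_per_tree List of `stochastic_maps` objects, one per tree.
#' @return List with `per_tree` (tibble tree x type means), `means` (overall
#'   per-type means) and `t_test` (tibble with statistic, p value and a
#'   `degenerate` flag set when the paired differences have zero variance).
#' @export
count_fusion_fission_events <- function(maps_per_tree) {
  per_tree <- purrr::map_dfr(seq_along(maps_per_tree), function(i) {
    mc <- maps_per_tree[[i]]$mean_counts
    mc$tree <- i
    mc
  })
  wide <- tidyr::pivot_wider(per_tree, names_from = "type",
                             values_from = "mean", values_fill = 0)
  for (col in c("fusion", "fission")) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  means <- dplyr::summarise(dplyr::group_by(per_tree, .data$type),
                            mean = mean(.data$mean), .groups = "drop")
  d <- wide$fusion - wide$fission
  if (length(d) < 2 || var(d) == 0) {
    tt <- tibble::tibble(
      statistic = if (length(d) >= 1 && all(d == 0)) 0 else NA_real_,
      p_value = if (length(d) >= 1 && all(d == 0)) 1 else NA_real_,
      mean_difference = mean(d), degenerate = TRUE)
  } else {
    ht <- t.test(wide$fusion, wide$fission, paired = TRUE)
    tt <- tibble::tibble(statistic = unname(ht$statistic),
                         p_value = ht$p.value, mean_difference = mean(d),
                         degenerate = FALSE)
  }
  list(per_tree = wide, means = means, t_test = tt)
}
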