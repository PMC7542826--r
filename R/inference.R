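#' MCMC settings for chromosome-rate estimation
#'
#' Defaults follow the analysis design the package reproduces: a short chain
#' of 1000 generations per tree in the posterior sample, the first 25%
#' discarded as burnin, and 100 states drawn at random from the post-burnin
#' portion of each chain, so a 100-tree posterior yields 10 000 pooled draws.
#'
#' @param generations Stored chain length per tree (including the initial
#'   state, generation 0).
#' @param burnin_fraction Fraction of each chain discarded before sampling.
#' @param samples_per_tree States sampled (without replacement) per chain.
#' @param seed Integer seed controlling ambiguity resolution, proposals and
#'   post-burnin subsampling.
#' @param proposal_scale Initial sliding-window half-width, as a multiple of
#'   the prior mean (tuned adaptively during burnin towards 25-45%
#'   acceptance).
#' @param prior Either a single number (exponential prior mean shared by all
#'   unit-tree rates) or a named vector of per-parameter prior means.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(generations = 1000, burnin_fraction = 0.25,
                          samples_per_tree = 100, seed = 1,
                          proposal_scale = 1, prior = 100) {
  stopifnot(generations >= 2, burnin_fraction >= 0, burnin_fraction < 1,
            samples_per_tree >= 1, proposal_scale > 0, all(prior > 0))
  if (samples_per_tree > generations * (1 - burnin_fraction)) {
    abort("samples_per_tree exceeds the post-burnin chain length.")
  }
  structure(list(generations = as.integer(generations),
                 burnin_fraction = burnin_fraction,
                 samples_per_tree = as.integer(samples_per_tree),
                 seed = as.integer(seed), proposal_scale = proposal_scale,
                 prior = prior),
            class = "mcmc_settings")
}

# Free (sampled / optimised) parameter names for a model
free_parameters <- function(model, include_polyploidy = TRUE,
                            include_demiploidy = NULL) {
  pars <- c("rate_fission", "rate_fusion")
  if (include_polyploidy) pars <- c(pars, "rate_polyploidy")
  if (include_demiploidy %||% (model$rate_demiploidy > 0)) {
    pars <- c(pars, "rate_demiploidy")
  }
  if (!is.null(model$trait)) {
    pars <- c(pars, "rate_fission2", "rate_fusion2")
    if (include_polyploidy) pars <- c(pars, "rate_polyploidy2")
    pars <- c(pars, "q01", "q10")
  }
  pars
}

#' Update a chromosome model with named rate values
#'
#' Convenience for plugging estimated rates (e.g. per-tree posterior means)
#' back into a model template. Recognised names: `rate_fission`,
#' `rate_fusion`, `rate_polyploidy`, `rate_demiploidy`, and for trait-linked
#' models additionally `q01`, `q10` and the `*2` state-1 rates.
#'
#' @param model A [chromosome_model()].
#' @param values Named numeric vector of rates.
#' @return The updated model.
#' @export
set_model_rates <- function(model, values) {
  for (nm in names(values)) {
    if (nm %in% c("rate_fission", "rate_fusion", "rate_polyploidy",
                  "rate_demiploidy")) {
      model[[nm]] <- unname(values[[nm]])
    } else if (nm %in% c("q01", "q10", "rate_fission2", "rate_fusion2",
                         "rate_polyploidy2", "rate_demiploidy2")) {
      if (is.null(model$trait)) abort(sprintf("'%s' needs a trait-linked model.", nm))
      model$trait[[nm]] <- unname(values[[nm]])
    } else {
      abort(sprintf("Unknown rate parameter '%s'.", nm))
    }
  }
  model
}

# Prior mean per parameter from settings$prior
prior_means <- function(prior, pars) {
  if (length(prior) == 1 && is.null(names(prior))) {
    return(setNames(rep(prior, length(pars)), pars))
  }
  mu <- setNames(rep(100, length(pars)), pars)
  mu[names(prior)] <- prior
  mu
}

#' Default upper state bound from observed counts
#'
#' The bounded chromosome model needs a largest haploid number; the default
#' rule is `2 * max(observed) + 1`, so one whole-genome duplication from the
#' largest observed state stays inside the state space while keeping the
#' rate matrix small.
#'
#' @param counts Named list (or vector) of observed haploid counts.
#' @return An integer upper bound.
#' @export
default_n_max <- function(counts) {
  mx <- max(unlist(counts), na.rm = TRUE)
  as.integer(2 * mx + 1)
}

#' Maximum-likelihood fit of the chromosome model on one tree
#'
#' Optimises the unit-tree fission/fusion (and optionally polyploidy) rates
#' by bounded quasi-Newton search from several starting points. Ambiguous
#' tip counts enter as uniform probability vectors over the candidate set.
#'
#' @param tree Rooted `phylo` (branch lengths in MY; rescaled internally).
#' @param counts Named list of candidate haploid count vectors per tip.
#' @param model A [chromosome_model()] template giving the state bounds; if
#'   `NULL`, bounds default to `1 .. 2 * max(count) + 1`.
#' @param include_polyploidy If `FALSE` the polyploidy rate is fixed at 0
#'   (the "simple" fission/fusion model).
#' @param root_prior Root state prior (see [log_likelihood()]).
#' @param starts Optional matrix of extra starting points (columns = free
#'   parameters, unit-tree scale).
#' @return A list of class `karyo_ml_fit` with unit-tree and per-MY rate
#'   estimates, the maximised log-likelihood and a convergence flag.
#' @export
fit_ml <- function(tree, counts, model = NULL, include_polyploidy = TRUE,
                   root_prior = "uniform", starts = NULL) {
  assert_tree(tree)
  if (is.null(model)) model <- chromosome_model(n_max = default_n_max(counts))
  pars <- free_parameters(model, include_polyploidy,
                          include_demiploidy = model$rate_demiploidy > 0)
  resc <- rescale_to_unit(tree)
  tipmat <- tip_state_matrix(counts, model)
  if (!include_polyploidy) model <- set_model_rates(model, c(rate_polyploidy = 0))

  nll <- function(x) {
    m <- set_model_rates(model, setNames(x, pars))
    Q <- build_rate_matrix(m)
    ll <- log_likelihood(resc$tree, tipmat, Q, root_prior)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  base_starts <- rbind(rep(0.5, length(pars)), rep(5, length(pars)),
                       rep(50, length(pars)))
  if (!is.null(starts)) base_starts <- rbind(base_starts, starts)
  best <- NULL
  conv <- FALSE
  for (i in seq_len(nrow(base_starts))) {
    fit <- tryCatch(
      optim(base_starts[i, ], nll, method = "L-BFGS-B", lower = 0,
            upper = 5000, control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      conv <- fit$convergence == 0
    }
  }
  if (is.null(best)) abort("All optimisation starts failed.")
  est <- setNames(best$par, pars)
  structure(list(
    rates_unit = est,
    rates_per_my = est / resc$scale_factor,
    log_likelihood = -best$value,
    scale_factor = resc$scale_factor,
    include_polyploidy = include_polyploidy,
    converged = conv,
    model = set_model_rates(model, est),
    n_tips = length(tree$tip.label)
  ), class = "karyo_ml_fit")
}

#' @export
print.karyo_ml_fit <- function(x, ...) {
  cat(sprintf("<karyo_ml_fit> logLik %.4f%s\n", x$log_likelihood,
              if (x$converged) "" else " (optimizer not converged)"))
  print(round(rbind(unit_tree = x$rates_unit, per_MY = x$rates_per_my), 6))
  invisible(x)
}

#' Likelihood-ratio test between the simple and complex chromosome models
#'
#' Compares the fission/fusion model against the fission/fusion/polyploidy
#' model fitted to the same data. The statistic is `2 * (llC - llS)`, clipped
#' at zero. Because the polyploidy rate is constrained to be non-negative,
#' the null hypothesis places it on the boundary of the parameter space and
#' the reference distribution is the equal mixture of a point mass at zero
#' and chi-square with 1 df (`boundary = TRUE`, the calibrated default);
#' `boundary = FALSE` gives the naive chi-square(1) p-value.
#'
#' @param simple,complex `karyo_ml_fit` objects for the nested pair.
#' @param boundary Use the boundary-corrected mixture null (default).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `boundary`.
#' @export
likelihood_ratio_test <- function(simple, complex, boundary = TRUE) {
  llS <- simple$log_likelihood
  llC <- complex$log_likelihood
  if (llC < llS - 1e-6) {
    warn(sprintf(
      "Complex-model log-likelihood (%.6f) below simple's (%.6f): optimizer failure likely.",
      llC, llS))
  }
  stat <- max(0, 2 * (llC - llS))
  p <- if (stat == 0) 1 else pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary && stat > 0) p <- 0.5 * p
  tibble::tibble(statistic = stat, df = 1, p_value = min(p, 1),
                 boundary = boundary)
}

#' Fit the simple and complex models and test them on one tree
#'
#' Convenience wrapper: fits the fission/fusion model, then the
#' fission/fusion/polyploidy model (seeding the search from the simple
#' optimum so the nested likelihood ordering holds), and runs the LRT.
#'
#' @inheritParams fit_ml
#' @param boundary Passed to [likelihood_ratio_test()].
#' @return List with `simple`, `complex` (fits) and `lrt` (tibble).
#' @export
chrom_lrt <- function(tree, counts, model = NULL, root_prior = "uniform",
                      boundary = TRUE) {
  if (is.null(model)) model <- chromosome_model(n_max = default_n_max(counts))
  simple <- fit_ml(tree, counts, model, include_polyploidy = FALSE,
                   root_prior = root_prior)
  seedrow <- matrix(c(simple$rates_unit[c("rate_fission", "rate_fusion")], 1e-4),
                    nrow = 1)
  complex <- fit_ml(tree, counts, model, include_polyploidy = TRUE,
                    root_prior = root_prior, starts = seedrow)
  list(simple = simple, complex = complex,
       lrt = likelihood_ratio_test(simple, complex, boundary = boundary))
}

# deterministic per-(seed, tree) sub-seed kept inside 32-bit integer range
sub_seed <- function(seed, tree_index, salt = 0L) {
  as.integer((as.numeric(seed) + 1009 * as.numeric(tree_index) +
                99991 * as.numeric(salt)) %% 2147483647)
}

# one uniform seeded draw per tip from its candidate count set
resolve_counts <- function(counts, seed) {
  set.seed(seed)
  lapply(counts, function(cs) {
    if (is.null(cs) || length(cs) <= 1) cs else cs[sample.int(length(cs), 1)]
  })
}

#' Metropolis-Hastings MCMC for chromosome-model rates on one tree
#'
#' Samples the free unit-tree rates under independent exponential priors with
#' per-parameter sliding-window proposals reflected at zero. Tip-count
#' ambiguity is resolved by one seeded uniform draw per (tree, chain) before
#' the chain starts. The chain stores every generation (generation 0 is the
#' initial state); windows adapt towards 25-45% acceptance during burnin
#' only.
#'
#' @inheritParams fit_ml
#' @param settings An [mcmc_settings()] object.
#' @param tree_index Index of this tree within its posterior set (enters the
#'   seed so chains differ across trees but are reproducible).
#' @param use_likelihood If `FALSE` the likelihood term is dropped and the
#'   chain targets the prior (used to validate the sampler).
#' @param include_polyploidy Sample the polyploidy rate (default `TRUE`).
#' @return A `karyo_chain`: list with `draws` (tibble of generation, rates on
#'   the unit-tree scale, `log_lik`, `log_post`), `scale_factor`,
#'   `acceptance`, `resolved_counts`, `tree_index`, `settings`.
#' @export
run_mcmc <- function(tree, counts, model = NULL, settings = mcmc_settings(),
                     tree_index = 1, root_prior = "uniform",
                     include_polyploidy = TRUE, use_likelihood = TRUE) {
  assert_tree(tree)
  if (is.null(model)) model <- chromosome_model(n_max = default_n_max(counts))
  pars <- free_parameters(model, include_polyploidy,
                          include_demiploidy = model$rate_demiploidy > 0)
  mu <- prior_means(settings$prior, pars)
  resc <- rescale_to_unit(tree)

  set.seed(sub_seed(settings$seed, tree_index, salt = 1L))
  counts_res <- resolve_counts(counts, sub_seed(settings$seed, tree_index, 2L))
  tipmat <- tip_state_matrix(counts_res, model)

  loglik_at <- function(x) {
    if (!use_likelihood) return(0)
    m <- set_model_rates(model, setNames(x, pars))
    Q <- build_rate_matrix(m)
    log_likelihood(resc$tree, tipmat, Q, root_prior)
  }
  logprior_at <- function(x) sum(stats::dexp(x, rate = 1 / mu, log = TRUE))

  G <- settings$generations
  burn_n <- floor(settings$burnin_fraction * G)
  np <- length(pars)
  # Start at a cheap ML estimate so short chains sample the posterior from
  # generation one (the prior mean can sit orders of magnitude away from the
  # posterior mode); without a likelihood the prior mean is the natural start.
  x <- mu
  if (use_likelihood) {
    nll <- function(z) {
      v <- loglik_at(z)
      if (!is.finite(v)) 1e12 else -v
    }
    init <- tryCatch(
      optim(pmin(mu, 5), nll, method = "L-BFGS-B", lower = 1e-6, upper = 5000,
            control = list(maxit = 120)),
      error = function(e) NULL)
    if (!is.null(init)) x <- pmax(init$par, 1e-3)
  }
  win <- settings$proposal_scale * pmax(x, 0.05 * mu)
  ll <- loglik_at(x)
  lp <- ll + logprior_at(x)
  if (!is.finite(lp)) {
    x <- mu / 100
    ll <- loglik_at(x)
    lp <- ll + logprior_at(x)
  }
  draws <- matrix(NA_real_, G, np, dimnames = list(NULL, pars))
  llv <- lpv <- numeric(G)
  draws[1, ] <- x; llv[1] <- ll; lpv[1] <- lp
  acc <- att <- setNames(rep(0, np), pars)
  acc_block <- att_block <- acc

  for (g in 2:G) {
    for (j in seq_len(np)) {
      prop <- x
      prop[j] <- abs(x[j] + runif(1, -win[j], win[j])) # reflect at 0
      ll_p <- loglik_at(prop)
      lp_p <- ll_p + logprior_at(prop)
      att[j] <- att[j] + 1; att_block[j] <- att_block[j] + 1
      if (is.finite(lp_p) && log(runif(1)) < lp_p - lp) {
        x <- prop; ll <- ll_p; lp <- lp_p
        acc[j] <- acc[j] + 1; acc_block[j] <- acc_block[j] + 1
      }
    }
    draws[g, ] <- x; llv[g] <- ll; lpv[g] <- lp
    # window tuning during burnin only
    if (g <= burn_n && g %% 25 == 0) {
      r <- acc_block / pmax(att_block, 1)
      win[r < 0.05] <- win[r < 0.05] * 0.2
      win[r >= 0.05 & r < 0.25] <- win[r >= 0.05 & r < 0.25] * 0.6
      win[r > 0.45] <- win[r > 0.45] * 1.8
      acc_block[] <- 0; att_block[] <- 0
    }
  }
  out <- tibble::as_tibble(as.data.frame(draws))
  out$generation <- 0:(G - 1)
  out$log_lik <- llv
  out$log_post <- lpv
  out <- dplyr::relocate(out, "generation")
  structure(list(draws = out, scale_factor = resc$scale_factor,
                 acceptance = acc / pmax(att, 1), parameters = pars,
                 resolved_counts = counts_res, tree_index = tree_index,
                 settings = settings),
            class = "karyo_chain")
}

#' @export
print.karyo_chain <- function(x, ...) {
  cat(sprintf("<karyo_chain> tree %d, %d generations, scale factor %.4g MY\n",
              x$tree_index, nrow(x$draws), x$scale_factor))
  cat("acceptance: ", paste(sprintf("%s %.2f", names(x$acceptance),
                                    x$acceptance), collapse = ", "), "\n")
  invisible(x)
}

#' Pool post-burnin MCMC draws across a posterior tree set
#'
#' Drops the burnin fraction of each per-tree chain, subsamples
#' `samples_per_tree` states without replacement (seeded), back-transforms
#' every rate to per-MY units using that tree's own root depth, and
#' concatenates. With 100 trees and 100 samples each this yields the 10 000
#' pooled point estimates that define the posterior distribution.
#'
#' @param chains List of `karyo_chain` objects.
#' @param settings [mcmc_settings()]; defaults to the first chain's settings.
#' @return A tibble of class `posterior_rates`: columns `tree`, `generation`
#'   and one per-MY rate column per free parameter.
#' @export
pool_posterior <- function(chains, settings = NULL) {
  if (inherits(chains, "karyo_chain")) chains <- list(chains)
  settings <- settings %||% chains[[1]]$settings
  pooled <- purrr::map_dfr(chains, function(ch) {
    G <- nrow(ch$draws)
    burn_n <- floor(settings$burnin_fraction * G)
    eligible <- ch$draws[ch$draws$generation >= burn_n, , drop = FALSE]
    if (nrow(eligible) < settings$samples_per_tree) {
      abort(sprintf(
        "Chain for tree %d has %d post-burnin states < samples_per_tree = %d.",
        ch$tree_index, nrow(eligible), settings$samples_per_tree))
    }
    set.seed(sub_seed(settings$seed, ch$tree_index, 3L))
    idx <- sample.int(nrow(eligible), settings$samples_per_tree)
    sub <- eligible[idx, , drop = FALSE]
    out <- sub[, ch$parameters, drop = FALSE] / ch$scale_factor
    out$tree <- ch$tree_index
    out$generation <- sub$generation
    dplyr::relocate(out, "tree", "generation")
  })
  class(pooled) <- c("posterior_rates", class(pooled))
  attr(pooled, "settings") <- settings
  pooled
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval of sorted draws containing
#' `ceiling(mass * N)` of them.
#'
#' @param draws Numeric vector of posterior draws.
#' @param mass Probability mass (default 0.95).
#' @return Named numeric vector `c(low, high)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 2) abort("hpd_interval needs at least 2 draws.")
  stopifnot(mass > 0, mass <= 1)
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(low = x[1], high = x[n]))
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(low = x[i], high = x[i + m - 1])
}

#' Compare a rate between two pooled posteriors by 95% HPD overlap
#'
#' Two clades are reported as significantly different in a rate when their
#' highest-posterior-density intervals are disjoint — the operational rule
#' used throughout the analysis (no multiple-testing correction is applied).
#'
#' @param a,b `posterior_rates` tibbles.
#' @param parameter Rate column name (e.g. `"rate_fission"`).
#' @param mass HPD mass (default 0.95).
#' @return One-row tibble with both intervals, `disjoint` and `significant`.
#' @export
compare_rates <- function(a, b, parameter, mass = 0.95) {
  for (obj in list(a, b)) {
    if (!parameter %in% names(obj)) {
      abort(sprintf("Parameter '%s' not found in posterior.", parameter))
    }
  }
  ha <- hpd_interval(a[[parameter]], mass)
  hb <- hpd_interval(b[[parameter]], mass)
  disjoint <- ha["high"] < hb["low"] || hb["high"] < ha["low"]
  tibble::tibble(parameter = parameter, mass = mass,
                 a_low = unname(ha["low"]), a_high = unname(ha["high"]),
                 b_low = unname(hb["low"]), b_high = unname(hb["high"]),
                 disjoint = unname(disjoint), significant = unname(disjoint))
}
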