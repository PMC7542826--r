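#' Specify a chromosome-number evolution model
#'
#' Defines the bounded continuous-time Markov model of haploid chromosome
#' number with per-lineage rates of fission (`n -> n + 1`), fusion
#' (`n -> n - 1`), polyploidy (`n -> 2n`) and, optionally, demiploidy
#' (`n -> ceiling(1.5 n)`, off by default). The state space is the integer
#' interval `n_min..n_max`; transitions whose target falls outside the bounds
#' are dropped so no probability mass leaves the state space.
#'
#' A binary trait (e.g. sexual/asexual reproduction) can be linked to the
#' chromosome process via `trait`: the state space is then doubled to pairs
#' (haploid number, trait state), chromosome rates become trait-specific and
#' the trait itself switches with rates `q01`/`q10`.
#'
#' @param n_max Largest haploid number in the state space.
#' @param n_min Smallest haploid number (default 1).
#' @param rate_fission,rate_fusion,rate_polyploidy,rate_demiploidy
#'   Non-negative rates, per unit branch length.
#' @param trait Optional list with elements `q01`, `q10` (trait switch rates)
#'   and optionally `rate_fission2`, `rate_fusion2`, `rate_polyploidy2`,
#'   `rate_demiploidy2` (chromosome rates in trait state 1; default equal to
#'   the state-0 rates).
#' @return An object of class `chromosome_model`.
#' @export
#' @examples
#' m <- chromosome_model(n_max = 12, rate_fission = 1, rate_fusion = 2,
#'                       rate_polyploidy = 0.1)
#' Q <- build_rate_matrix(m)
#' Q["3", "6"] # polyploidy 3 -> 6
chromosome_model <- function(n_max, n_min = 1, rate_fission = 0, rate_fusion = 0,
                             rate_polyploidy = 0, rate_demiploidy = 0,
                             trait = NULL) {
  stopifnot(n_min >= 1, n_max > n_min)
  rates <- c(rate_fission = rate_fission, rate_fusion = rate_fusion,
             rate_polyploidy = rate_polyploidy, rate_demiploidy = rate_demiploidy)
  if (any(rates < 0)) abort("All rates must be non-negative.")
  if (!is.null(trait)) {
    trait$q01 <- trait$q01 %||% 0
    trait$q10 <- trait$q10 %||% 0
    if (trait$q01 < 0 || trait$q10 < 0) abort("Trait rates must be non-negative.")
    trait$rate_fission2 <- trait$rate_fission2 %||% rate_fission
    trait$rate_fusion2 <- trait$rate_fusion2 %||% rate_fusion
    trait$rate_polyploidy2 <- trait$rate_polyploidy2 %||% rate_polyploidy
    trait$rate_demiploidy2 <- trait$rate_demiploidy2 %||% rate_demiploidy
  }
  structure(list(n_min = as.integer(n_min), n_max = as.integer(n_max),
                 rate_fission = rate_fission, rate_fusion = rate_fusion,
                 rate_polyploidy = rate_polyploidy,
                 rate_demiploidy = rate_demiploidy, trait = trait),
            class = "chromosome_model")
}

#' @export
print.chromosome_model <- function(x, ...) {
  cat(sprintf(
    "<chromosome_model> states %d..%d%s\n  fission %.4g  fusion %.4g  polyploidy %.4g  demiploidy %.4g\n",
    x$n_min, x$n_max, if (is.null(x$trait)) "" else " x {0,1} trait",
    x$rate_fission, x$rate_fusion, x$rate_polyploidy, x$rate_demiploidy))
  if (!is.null(x$trait)) {
    cat(sprintf("  trait q01 %.4g q10 %.4g; state-1 rates %.4g/%.4g/%.4g/%.4g\n",
                x$trait$q01, x$trait$q10, x$trait$rate_fission2,
                x$trait$rate_fusion2, x$trait$rate_polyploidy2,
                x$trait$rate_demiploidy2))
  }
  invisible(x)
}

#' State labels of a chromosome model
#' @param model A `chromosome_model`.
#' @return Character vector: `"n"` for plain models, `"n.0"`/`"n.1"` for
#'   trait-linked models.
#' @export
model_states <- function(model) {
  ns <- as.character(model$n_min:model$n_max)
  if (is.null(model$trait)) return(ns)
  c(paste0(ns, ".0"), paste0(ns, ".1"))
}

#' Build the transition rate matrix of a chromosome model
#'
#' @param model A [chromosome_model()].
#' @return A square matrix over the ordered state space with row/column names
#'   from [model_states()]; off-diagonals hold transition intensities, rows
#'   sum to zero.
#' @export
build_rate_matrix <- function(model) {
  ns <- model$n_min:model$n_max
  k <- length(ns)
  fill_block <- function(fis, fus, pol, dem) {
    Q <- matrix(0, k, k, dimnames = list(as.character(ns), as.character(ns)))
    for (i in seq_len(k)) {
      n <- ns[i]
      if (n + 1 <= model$n_max) Q[i, i + 1] <- Q[i, i + 1] + fis
      if (n - 1 >= model$n_min) Q[i, i - 1] <- Q[i, i - 1] + fus
      if (pol > 0 && 2 * n <= model$n_max && 2 * n >= model$n_min && 2 * n != n) {
        j <- match(2 * n, ns)
        Q[i, j] <- Q[i, j] + pol
      }
      if (dem > 0) {
        tgt <- ceiling(1.5 * n)
        if (tgt != n && tgt <= model$n_max && tgt >= model$n_min) {
          j <- match(tgt, ns)
          Q[i, j] <- Q[i, j] + dem
        }
      }
    }
    Q
  }
  if (model$rate_polyploidy > 0 && model$n_max < 2 * model$n_min) {
    warn("Polyploidy is unreachable from every state given these bounds.")
  }
  Q0 <- fill_block(model$rate_fission, model$rate_fusion,
                   model$rate_polyploidy, model$rate_demiploidy)
  if (is.null(model$trait)) {
    Q <- Q0
  } else {
    tr <- model$trait
    Q1 <- fill_block(tr$rate_fission2, tr$rate_fusion2,
                     tr$rate_polyploidy2, tr$rate_demiploidy2)
    Q <- rbind(cbind(Q0, diag(tr$q01, k)), cbind(diag(tr$q10, k), Q1))
    dimnames(Q) <- list(model_states(model), model_states(model))
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Rescale a tree to unit root depth
#'
#' Divides every branch length by the root-to-tip depth so rates are
#' estimated per unit tree; the returned scale factor (the original root
#' depth, in MY for time-calibrated trees) back-transforms them.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return A list with `tree` (root depth 1) and `scale_factor`.
#' @export
rescale_to_unit <- function(tree) {
  assert_tree(tree)
  depth <- tree_root_depth(tree)
  if (depth <= 0) abort("Tree has zero root depth; cannot rescale.")
  tree$edge.length <- tree$edge.length / depth
  list(tree = tree, scale_factor = depth)
}

#' Convert a unit-tree rate to a per-MY rate
#'
#' @param unit_rate Rate per unit tree length.
#' @param scale_factor Root depth in MY returned by [rescale_to_unit()].
#' @return `unit_rate / scale_factor`.
#' @export
back_transform_rates <- function(unit_rate, scale_factor) {
  stopifnot(all(scale_factor > 0))
  unit_rate / scale_factor
}

#' Branch transition-probability operator for a rate matrix
#'
#' Returns a function `(t, v)` computing `expm(Q t) %*% v`. Uses an
#' eigendecomposition of `Q` when it is numerically diagonalizable (one
#' factorisation, then two dense mat-vec products per branch) and falls back
#' to scaling-and-squaring matrix exponentials otherwise (e.g. for defective
#' single-direction chains). Zero-length branches return `v` exactly.
#'
#' @param Q A valid rate matrix.
#' @return A list with elements `apply(t, v)` and `matrix(t)` (full
#'   `expm(Q t)`), plus `method` used.
#' @export
make_propagator <- function(Q) {
  k <- nrow(Q)
  method <- "eigen"
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  U <- NULL; Uinv <- NULL; lam <- NULL
  if (!is.null(eg)) {
    U <- eg$vectors
    lam <- eg$values
    Uinv <- tryCatch(solve(U), error = function(e) NULL)
    if (!is.null(Uinv)) {
      recon <- U %*% (lam * Uinv)
      err <- max(abs(Re(recon) - Q)) + max(abs(Im(recon)))
      if (!is.finite(err) || err > 1e-8 * max(1, max(abs(Q)))) Uinv <- NULL
    }
    if (is.null(Uinv)) method <- "expm"
  } else {
    method <- "expm"
  }
  apply_fun <- if (method == "eigen") {
    is_cplx <- is.complex(U) || is.complex(lam)
    function(t, v) {
      if (t == 0) return(v)
      w <- U %*% (exp(lam * t) * (Uinv %*% v))
      w <- if (is_cplx) Re(w) else w
      pmax(drop(w), 0) # clamp eigen round-off; magnitudes are ~1e-14
    }
  } else {
    function(t, v) {
      if (t == 0) return(v)
      P <- as.matrix(Matrix::expm(Q * t))
      pmax(drop(P %*% v), 0)
    }
  }
  mat_fun <- function(t) {
    if (t == 0) return(diag(k))
    if (method == "eigen") {
      P <- U %*% (exp(lam * t) * Uinv)
      P <- Re(P)
    } else {
      P <- as.matrix(Matrix::expm(Q * t))
    }
    P <- pmax(P, 0)
    dimnames(P) <- dimnames(Q)
    P
  }
  list(apply = apply_fun, matrix = mat_fun, method = method)
}

#' Tip state probability matrix for chromosome counts
#'
#' Builds the per-tip likelihood vectors over the model's state space:
#' probability 1 on an observed count, uniform over a candidate set for
#' ambiguous records, and all ones for missing data.
#'
#' @param counts Named list (names = tip labels) of integer vectors of
#'   candidate haploid counts; `NULL`/empty elements mean missing.
#' @param model A [chromosome_model()] (must not be trait-linked).
#' @param trait Optional named vector of trait states (0, 1 or `NA`) when
#'   `model` is trait-linked.
#' @return A matrix with one row per tip (rownames = tip labels) and one
#'   column per model state.
#' @export
tip_state_matrix <- function(counts, model, trait = NULL) {
  states <- model_states(model)
  ns <- model$n_min:model$n_max
  k <- length(ns)
  tips <- names(counts)
  joint <- !is.null(model$trait)
  M <- matrix(0, length(tips), length(states),
              dimnames = list(tips, states))
  for (i in seq_along(tips)) {
    cs <- counts[[i]]
    base <- rep(0, k)
    if (is.null(cs) || length(cs) == 0 || all(is.na(cs))) {
      base <- rep(1, k)
    } else {
      cs <- cs[!is.na(cs)]
      inr <- cs[cs >= model$n_min & cs <= model$n_max]
      if (length(inr) == 0) {
        abort(sprintf("Tip '%s': no candidate count within model bounds %d..%d.",
                      tips[i], model$n_min, model$n_max))
      }
      base[match(inr, ns)] <- 1 / length(inr)
    }
    if (!joint) {
      M[i, ] <- base
    } else {
      ti <- if (is.null(trait)) NA else trait[[tips[i]]]
      if (is.na(ti)) {
        M[i, ] <- c(base, base)
      } else if (ti == 0) {
        M[i, ] <- c(base, rep(0, k))
      } else {
        M[i, ] <- c(rep(0, k), base)
      }
    }
  }
  M
}

# Resolve a root prior spec ("uniform", "observed", or numeric) to a vector
resolve_root_prior <- function(root_prior, Q, tipmat = NULL) {
  k <- nrow(Q)
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == k)
    return(root_prior / sum(root_prior))
  }
  if (identical(root_prior, "uniform")) return(rep(1 / k, k))
  if (identical(root_prior, "observed")) {
    if (is.null(tipmat)) abort("Observed root prior needs tip data.")
    w <- colSums(tipmat / pmax(rowSums(tipmat), 1e-300))
    if (sum(w) <= 0) return(rep(1 / k, k))
    return(w / sum(w))
  }
  abort("root_prior must be 'uniform', 'observed' or a numeric vector.")
}

#' Pruning log-likelihood of tip states under a CTMC on a tree
#'
#' Felsenstein's pruning algorithm: conditional likelihood vectors are
#' propagated rootward through `expm(Q t)` along each branch and multiplied
#' at internal nodes, with per-node rescaling to avoid underflow.
#'
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param tipmat Tip-state matrix from [tip_state_matrix()] (rows must cover
#'   all tree tips).
#' @param Q Rate matrix.
#' @param root_prior `"uniform"` (default), `"observed"`, or a numeric vector
#'   over states.
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(tree, tipmat, Q, root_prior = "uniform") {
  assert_tree(tree)
  miss <- setdiff(tree$tip.label, rownames(tipmat))
  if (length(miss) > 0) {
    abort(paste0("Tip states missing for: ", paste(miss, collapse = ", ")))
  }
  zero <- rownames(tipmat)[rowSums(tipmat) <= 0]
  zero <- intersect(zero, tree$tip.label)
  if (length(zero) > 0) {
    abort(paste0("All-zero tip state vector for: ", paste(zero, collapse = ", ")))
  }
  pi0 <- resolve_root_prior(root_prior, Q, tipmat)
  tr <- stats::reorder(tree, "postorder")
  cpp_chrom_loglik(tr$edge, tr$edge.length,
                   tipmat[tr$tip.label, , drop = FALSE],
                   unname(Q), pi0)
}
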