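#' Per-tip rates of chromosome-number change
#'
#' For each tip and each tree of a posterior set, the tip rate is the
#' difference between the tip's chromosome number and the most probable
#' chromosome number of its immediate ancestor (the argmax of the marginal
#' reconstruction, ties to the smaller state), divided by the terminal branch
#' length in MY. The directional rate is the mean of the signed per-tree
#' values and the absolute rate the mean of their magnitudes, across trees.
#' Zero-length terminal branches are skipped with a message.
#'
#' @param trees List of trees (or `posterior_trees`).
#' @param recons List of [marginal_ancestral_states()] results, one per tree
#'   (over the chromosome state space; column names are haploid numbers).
#' @param tip_counts Named numeric vector of observed tip chromosome numbers
#'   (ambiguous species should contribute their within-species mean).
#' @return Tibble: `species`, `directional_rate`, `absolute_rate`, `n_trees`.
#' @export
tip_rates <- function(trees, recons, tip_counts) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) == length(recons))
  vals <- purrr::map_dfr(seq_along(trees), function(i) {
    tree <- trees[[i]]
    recon <- recons[[i]]
    sp <- intersect(tree$tip.label, names(tip_counts))
    ntip <- length(tree$tip.label)
    tipidx <- match(sp, tree$tip.label)
    edge_of_tip <- match(tipidx, tree$edge[, 2])
    bl <- tree$edge.length[edge_of_tip]
    parent <- tree$edge[edge_of_tip, 1]
    anc_state <- as.numeric(recon$map_state[parent])
    keep <- bl > 0
    if (any(!keep)) {
      inform(sprintf("tip_rates: skipped %d zero-length terminal branch(es) on tree %d.",
                     sum(!keep), i))
    }
    tibble::tibble(species = sp[keep], tree = i,
                   rate = (unname(tip_counts[sp[keep]]) - anc_state[keep]) /
                     bl[keep])
  })
  vals |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(directional_rate = mean(.data$rate),
                     absolute_rate = mean(abs(.data$rate)),
                     n_trees = dplyr::n(), .groups = "drop")
}

#' Ordinary least-squares regression with a slope test
#'
#' Thin wrapper around [stats::lm()] returning a tidy one-row report, used
#' for the genome-size regressions (genome size predicting chromosome number
#' or tip rate).
#'
#' @param data A data frame.
#' @param x,y Column names of predictor and response.
#' @return One-row tibble: `slope`, `intercept`, `p_value`, `r_squared`, `n`,
#'   `method = "ols"`.
#' @export
ols_fit <- function(data, x, y) {
  df <- data[, c(x, y)]
  names(df) <- c("x", "y")
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 3) abort("ols_fit needs at least 3 complete observations.")
  if (var(df$x) == 0) abort("Predictor is constant; slope undefined.")
  fit <- lm(y ~ x, data = df)
  sm <- summary(fit)
  tibble::tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 p_value = sm$coefficients[2, 4], r_squared = sm$r.squared,
                 n = nrow(df), method = "ols")
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' GLS regression with residual covariance proportional to shared branch
#' lengths (`ape::vcv`), the standard phylogenetic correction for a
#' continuous regression; the slope test is the usual t-test with `n - 2`
#' degrees of freedom. On a star phylogeny the covariance is diagonal and the
#' fit equals OLS; estimates are invariant to rescaling all branch lengths.
#'
#' @param tree Rooted `phylo` covering the observations.
#' @param data Data frame with a `species` column matching tip labels.
#' @param x,y Column names of predictor and response.
#' @return One-row tibble: `slope`, `intercept`, `p_value`, `n`,
#'   `method = "pgls"`.
#' @export
pgls_fit <- function(tree, data, x, y) {
  df <- data[, c("species", x, y)]
  names(df) <- c("species", "x", "y")
  df <- df[complete.cases(df), , drop = FALSE]
  df <- df[df$species %in% tree$tip.label, , drop = FALSE]
  if (nrow(df) < 3) abort("pgls_fit needs at least 3 complete observations on the tree.")
  tree <- ape::keep.tip(tree, df$species)
  V <- ape::vcv(tree)[df$species, df$species]
  Vi <- tryCatch(solve(V), error = function(e) {
    d <- ape::cophenetic.phylo(tree)
    dup <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
    pairs <- if (nrow(dup) > 0) {
      paste(rownames(d)[dup[, 1]], rownames(d)[dup[, 2]], sep = "/",
            collapse = ", ")
    } else "unknown"
    abort(paste0("Singular phylogenetic covariance (zero-distance tips: ",
                 pairs, ")."))
  })
  X <- cbind(1, df$x)
  XtVi <- crossprod(X, Vi)
  beta <- solve(XtVi %*% X, XtVi %*% df$y)
  r <- df$y - X %*% beta
  n <- nrow(df)
  s2 <- drop(crossprod(r, Vi %*% r)) / (n - 2)
  covb <- s2 * solve(XtVi %*% X)
  tstat <- beta[2] / sqrt(covb[2, 2])
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  tibble::tibble(slope = beta[2], intercept = beta[1], p_value = p, n = n,
                 method = "pgls")
}
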