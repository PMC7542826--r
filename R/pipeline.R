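#' Configuration for an end-to-end analysis run
#'
#' @param clades Optional named list of tip-label vectors defining clades;
#'   default: one clade per value of the karyotype table's `order` column.
#'   Elements may also be lists `list(tips =, exclude =)` for set-difference
#'   clades such as an order minus a nested subclade.
#' @param min_clade_size Minimum number of usable tips for a clade to be
#'   analysed (default 20, the cut-off used for order-level rate estimation).
#' @param settings [mcmc_settings()] for the per-tree chains.
#' @param include_polyploidy Fit/sample the polyploidy rate (default `TRUE`).
#' @param run_mcmc,run_lrt,run_asr,run_scs_maps Stage switches.
#' @param n_maps Stochastic maps per tree for the SCS analysis.
#' @param seed Master seed (overrides `settings$seed`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(clades = NULL, min_clade_size = 20,
                       settings = mcmc_settings(), include_polyploidy = TRUE,
                       run_mcmc = TRUE, run_lrt = TRUE, run_asr = TRUE,
                       run_scs_maps = TRUE, n_maps = 10, seed = NULL) {
  stopifnot(min_clade_size >= 2)
  if (!is.null(seed)) settings$seed <- as.integer(seed)
  structure(list(clades = clades, min_clade_size = min_clade_size,
                 settings = settings, include_polyploidy = include_polyploidy,
                 run_mcmc = run_mcmc, run_lrt = run_lrt, run_asr = run_asr,
                 run_scs_maps = run_scs_maps, n_maps = n_maps),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys: `min_clade_size`, `include_polyploidy`, `n_maps`, `seed`,
#' `clades` (name -> tip list), and an `mcmc` block with [mcmc_settings()]
#' fields.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  st <- do.call(mcmc_settings, y$mcmc %||% list())
  run_config(clades = y$clades,
             min_clade_size = y$min_clade_size %||% 20,
             settings = st,
             include_polyploidy = y$include_polyploidy %||% TRUE,
             n_maps = y$n_maps %||% 10,
             seed = y$seed)
}

#' Extract the subtree for a clade specification
#'
#' Returns the MRCA-rooted subtree spanned by `tips`; `exclude` supports
#' set-difference clades (e.g. an order minus a nested subclade) by pruning
#' the excluded tips afterwards.
#'
#' @param tree Rooted `phylo`.
#' @param tips Tip labels defining the clade (MRCA spanning set).
#' @param exclude Tip labels to prune from the extracted subtree.
#' @return A `phylo`.
#' @export
clade_subtree <- function(tree, tips, exclude = NULL) {
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss) > 0) {
    abort(paste0("Clade tips not in tree: ", paste(miss, collapse = ", ")))
  }
  sub <- if (length(setdiff(tree$tip.label, tips)) == 0) {
    tree
  } else if (length(tips) == 1) {
    abort("A clade needs at least 2 tips.")
  } else {
    node <- ape::getMRCA(tree, tips)
    ape::extract.clade(tree, node)
  }
  if (!is.null(exclude) && length(exclude) > 0) {
    keep <- setdiff(sub$tip.label, exclude)
    if (length(keep) < 2) abort("Clade is empty after exclusions.")
    sub <- ape::keep.tip(sub, keep)
  }
  sub
}

#' Run the full comparative analysis
#'
#' Orchestrates the pipeline on a karyotype table and posterior tree set:
#' per-clade likelihood-ratio tests (simple vs. complex chromosome model) on
#' every tree, per-tree MCMC pooled into per-MY rate posteriors, ancestral
#' chromosome-number reconstruction with each tree's posterior-mean rates,
#' the SCS Mk2 fit with stochastic transition maps, the genus-level
#' fusion/fission table, and (when genome sizes are present) ordinary and
#' phylogenetically corrected regressions of chromosome number on genome
#' size. Clades below `min_clade_size` usable tips are skipped with a
#' message.
#'
#' @param records Karyotype record tibble.
#' @param trees A `posterior_trees` object.
#' @param config A [run_config()].
#' @return A list of class `karyo_pipeline` with elements `clades` (per-clade
#'   results: `lrt`, `posterior`, `asr_root`), `scs` (`mk2`, `maps`,
#'   `transition_means`), `genus_table`, `mechanism_counts`, `regressions`,
#'   `skipped`, and `manifest`.
#' @export
run_pipeline <- function(records, trees, config = run_config()) {
  matched <- match_tips(records, trees)
  records <- matched$records
  trees <- matched$trees
  settings <- config$settings

  counts_all <- setNames(records$haploid_counts, records$species)
  clades <- config$clades
  if (is.null(clades)) {
    clades <- split(records$species, records$order)
  }
  clade_results <- list()
  skipped <- character()
  for (cl in names(clades)) {
    spec <- clades[[cl]]
    tips <- if (is.list(spec)) setdiff(spec$tips, spec$exclude) else spec
    tips <- intersect(tips, trees[[1]]$tip.label)
    if (length(tips) < config$min_clade_size) {
      inform(sprintf("Clade '%s' has %d usable tips (< %d); skipped.",
                     cl, length(tips), config$min_clade_size))
      skipped <- c(skipped, cl)
      next
    }
    counts <- counts_all[tips]
    model <- chromosome_model(n_max = default_n_max(counts))
    lrt_tbl <- NULL
    chains <- list()
    asr_root <- NULL
    for (i in seq_along(trees)) {
      sub <- clade_subtree(trees[[i]], tips,
                           exclude = if (is.list(spec)) spec$exclude else NULL)
      sub <- ape::keep.tip(sub, tips)
      if (config$run_lrt) {
        lr <- chrom_lrt(sub, counts, model)
        lr$lrt$tree <- i
        lrt_tbl <- dplyr::bind_rows(lrt_tbl, lr$lrt)
      }
      if (config$run_mcmc) {
        chains[[i]] <- run_mcmc(sub, counts, model, settings, tree_index = i,
                                include_polyploidy = config$include_polyploidy)
      }
    }
    posterior <- NULL
    if (config$run_mcmc) {
      posterior <- pool_posterior(chains, settings)
      if (config$run_asr) {
        root_vecs <- lapply(seq_along(trees), function(i) {
          sub <- clade_subtree(trees[[i]], tips,
                               exclude = if (is.list(spec)) spec$exclude else NULL)
          sub <- ape::keep.tip(sub, tips)
          post_i <- posterior[posterior$tree == i, , drop = FALSE]
          rates <- colMeans(post_i[, chains[[i]]$parameters, drop = FALSE]) *
            chains[[i]]$scale_factor # back to unit-tree scale for this tree
          m <- set_model_rates(model, rates)
          resc <- rescale_to_unit(sub)
          tipmat <- tip_state_matrix(chains[[i]]$resolved_counts[sub$tip.label], m)
          rec <- marginal_ancestral_states(resc$tree, tipmat,
                                           build_rate_matrix(m))
          mrca_state(rec, sub$tip.label)
        })
        asr_root <- Reduce(`+`, root_vecs) / length(root_vecs)
      }
    }
    clade_results[[cl]] <- list(
      n_tips = length(tips),
      lrt = lrt_tbl,
      lrt_support_complex = if (!is.null(lrt_tbl)) mean(lrt_tbl$p_value < 0.05),
      posterior = posterior,
      asr_root = asr_root)
  }

  # SCS: binary ARD fit + stochastic transition maps on the full tree set
  scs_res <- NULL
  scs_states <- collapse_scs(records$scs)
  names(scs_states) <- records$species
  asex <- records$species[records$reproductive_mode == "asexual"]
  scs_states <- scs_states[!is.na(scs_states)]
  if (length(unique(scs_states[setdiff(names(scs_states), asex)])) == 2) {
    mk2 <- fit_mk2_ard(trees, scs_states, drop_tips = asex)
    maps <- lapply(seq_along(trees), function(i) {
      if (!config$run_scs_maps) return(NULL)
      keep <- setdiff(intersect(trees[[i]]$tip.label, names(scs_states)), asex)
      sub <- ape::keep.tip(trees[[i]], keep)
      q <- as.numeric(mk2$fits[i, c("q01", "q10")])
      Q <- matrix(c(-q[1], q[1], q[2], -q[2]), 2, 2, byrow = TRUE,
                  dimnames = list(mk2$states, mk2$states))
      tipmat <- matrix(0, length(keep), 2, dimnames = list(keep, mk2$states))
      tipmat[cbind(keep, unname(scs_states[keep]))] <- 1
      stochastic_map(sub, tipmat, Q, n_maps = config$n_maps,
                     seed = sub_seed(settings$seed, i, 29L))
    })
    transition_means <- NULL
    if (config$run_scs_maps) {
      all_counts <- purrr::map_dfr(seq_along(maps), function(i) {
        dplyr::mutate(maps[[i]]$counts, tree = i)
      })
      transition_means <- dplyr::summarise(
        dplyr::group_by(all_counts, .data$type), mean = mean(.data$n),
        .groups = "drop")
    }
    scs_res <- list(mk2 = mk2, maps = if (config$run_scs_maps) maps,
                    transition_means = transition_means)
  }

  genus_table <- classify_mechanism(summarize_genus(records))
  mech_counts <- tabulate_mechanisms(genus_table)

  regressions <- NULL
  if (any(!is.na(records$genome_size))) {
    df <- tibble::tibble(
      species = records$species,
      genome_size = records$genome_size,
      chromosome_number = vapply(records$haploid_counts,
                                 function(x) mean(as.numeric(x)), numeric(1)))
    ols <- tryCatch(ols_fit(df, "genome_size", "chromosome_number"),
                    error = function(e) NULL)
    pgls <- tryCatch(pgls_fit(trees[[1]], df, "genome_size",
                              "chromosome_number"),
                     error = function(e) NULL)
    regressions <- dplyr::bind_rows(ols, pgls)
  }

  manifest <- list(
    seed = settings$seed,
    settings = unclass(settings),
    n_trees = length(trees),
    n_records = nrow(records),
    clades = lapply(clades, function(s) if (is.list(s)) s else sort(s)),
    input_digest = rlang::hash(list(records$species, records$haploid_counts,
                                    lapply(unclass(trees), function(t) t$edge.length))),
    result_digest = NA_character_)
  out <- list(clades = clade_results, scs = scs_res,
              genus_table = genus_table, mechanism_counts = mech_counts,
              regressions = regressions, skipped = skipped,
              manifest = manifest)
  out$manifest$result_digest <- rlang::hash(out[c("clades", "scs", "genus_table")])
  structure(out, class = "karyo_pipeline")
}

#' @export
print.karyo_pipeline <- function(x, ...) {
  cat(sprintf("<karyo_pipeline> %d clade(s) analysed, %d skipped\n",
              length(x$clades), length(x$skipped)))
  for (cl in names(x$clades)) {
    r <- x$clades[[cl]]
    cat(sprintf("  %s: %d tips%s\n", cl, r$n_tips,
                if (!is.null(r$lrt_support_complex))
                  sprintf(", complex model supported in %.0f%% of LRTs",
                          100 * r$lrt_support_complex) else ""))
  }
  invisible(x)
}
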