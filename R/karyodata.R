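#' Read a karyotype table
#'
#' Reads a CSV table of per-species karyotype observations into a tibble of
#' karyotype records: species, genus, order, candidate haploid chromosome
#' counts, sex chromosome system (SCS), reproductive mode and (optionally)
#' genome size in Mbp. Counts may be a single integer or a delimited list of
#' candidate values (`;`, `|` or `/` separated) when the literature reports
#' several; candidates are kept as a set and resolved later, at inference time.
#'
#' Rows whose count field cannot be parsed are *reported*, not silently
#' dropped: they are returned in the `problems` attribute (see
#' [karyotype_problems()]) and a warning summarises them.
#'
#' @param path Path to a CSV file (may be gzip-compressed).
#' @param dialect Named character vector mapping the canonical column names
#'   (`species`, `genus`, `order`, `haploid_counts`, `scs`,
#'   `reproductive_mode`, `genome_size`) to the column names used in the file.
#'   Unmapped names default to themselves.
#' @return A tibble with one row per parsed record and columns `species`,
#'   `genus`, `order`, `haploid_counts` (list-column of integer vectors),
#'   `scs`, `reproductive_mode`, `genome_size`. Attribute `problems` holds a
#'   tibble of rejected rows.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "species,genus,order,haploid_counts,scs,reproductive_mode,genome_size",
#'   "Gryllus_a,Gryllus,Orthoptera,11,XY,sexual,",
#'   "Gryllus_b,Gryllus,Orthoptera,12;13,XO,sexual,2100"
#' ), path)
#' read_karyotype_table(path)
read_karyotype_table <- function(path, dialect = NULL) {
  canon <- c("species", "genus", "order", "haploid_counts", "scs",
             "reproductive_mode", "genome_size")
  map <- setNames(canon, canon)
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), canon)
    if (length(bad) > 0) {
      abort(paste0("Unknown dialect keys: ", paste(bad, collapse = ", ")))
    }
    map[names(dialect)] <- dialect
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  mandatory <- c("species", "genus", "order", "haploid_counts", "scs")
  missing_cols <- mandatory[!map[mandatory] %in% names(raw)]
  if (length(missing_cols) > 0) {
    abort(paste0("Karyotype table is missing mandatory column(s): ",
                 paste(map[missing_cols], collapse = ", ")))
  }

  get_col <- function(nm) {
    if (map[[nm]] %in% names(raw)) raw[[map[[nm]]]] else rep(NA_character_, nrow(raw))
  }
  counts_raw <- get_col("haploid_counts")
  parsed <- lapply(counts_raw, parse_count_set)
  ok <- !vapply(parsed, is.null, logical(1))

  records <- tibble::tibble(
    species = trimws(get_col("species")),
    genus = trimws(get_col("genus")),
    order = trimws(get_col("order")),
    haploid_counts = parsed,
    scs = normalize_scs(get_col("scs")),
    reproductive_mode = normalize_repro(get_col("reproductive_mode")),
    genome_size = suppressWarnings(as.numeric(get_col("genome_size")))
  )
  problems <- tibble::tibble(
    row = which(!ok),
    species = records$species[!ok],
    haploid_counts = counts_raw[!ok],
    reason = "unparseable haploid count field"
  )
  records <- records[ok, , drop = FALSE]
  if (nrow(problems) > 0) {
    warn(sprintf(
      "%d row(s) with unparseable haploid counts were excluded; see karyotype_problems().",
      nrow(problems)))
  }
  attr(records, "problems") <- problems
  records
}

#' Rows rejected while reading a karyotype table
#'
#' @param records A tibble returned by [read_karyotype_table()].
#' @return A tibble of rejected rows (empty if all rows parsed).
#' @export
karyotype_problems <- function(records) {
  attr(records, "problems") %||%
    tibble::tibble(row = integer(), species = character(),
                   haploid_counts = character(), reason = character())
}

#' Write a karyotype table to CSV
#'
#' Inverse of [read_karyotype_table()]: candidate count sets are joined with
#' `";"`. Reading the written file back yields identical records.
#'
#' @param records Karyotype record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_karyotype_table <- function(records, path) {
  out <- records
  out$haploid_counts <- vapply(records$haploid_counts,
                               function(x) paste(x, collapse = ";"), character(1))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

# "12" -> 12L; "12;13" -> c(12L,13L); "abc" / "" / "0" -> NULL (rejected)
parse_count_set <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(NULL)
  parts <- trimws(strsplit(x, "[;|/]")[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0 || !all(grepl("^[0-9]+$", parts))) return(NULL)
  vals <- sort(unique(as.integer(parts)))
  if (any(vals < 1)) return(NULL)
  vals
}

normalize_scs <- function(x) {
  x <- trimws(x)
  x[is.na(x) | !nzchar(x)] <- "unknown"
  key <- tolower(gsub("[^A-Za-z0-9]", "", x))
  out <- dplyr::case_when(
    key %in% c("xo", "x0") ~ "XO",
    key %in% c("xy") ~ "XY",
    key %in% c("multixy", "complex", "xxy", "xyy", "x1x2y", "neoxy") ~ "multiXY",
    TRUE ~ "unknown"
  )
  out
}

normalize_repro <- function(x) {
  x <- trimws(x)
  x[is.na(x) | !nzchar(x)] <- "unknown"
  key <- tolower(x)
  dplyr::case_when(
    key %in% c("sexual", "s") ~ "sexual",
    key %in% c("asexual", "parthenogenetic", "parthenogenesis", "a") ~ "asexual",
    TRUE ~ "unknown"
  )
}

#' Read a posterior sample of trees
#'
#' Reads one or more Newick or Nexus files into a validated posterior tree
#' set. All trees must be rooted with branch lengths (assumed to be in
#' millions of years) and share an identical tip label set; polytomies are
#' resolved to binary nodes with zero-length branches and reported.
#'
#' @param paths Character vector of file paths (each may contain one or many
#'   trees; gzip-compressed files are accepted).
#' @param format `"newick"` or `"nexus"`.
#' @return A `multiPhylo` object of class `c("posterior_trees", "multiPhylo")`
#'   with attributes `labels` (the shared tip set) and `n_resolved` (number of
#'   trees in which polytomies were resolved).
#' @export
read_tree_set <- function(paths, format = c("newick", "nexus")) {
  format <- match.arg(format)
  trees <- list()
  for (p in paths) {
    if (format == "newick") {
      txt <- readLines(gzfile(p))
      tr <- ape::read.tree(text = paste(txt, collapse = "\n"))
    } else {
      # ape::read.nexus needs a file path; decompress gz to a temp file first
      fp <- p
      if (grepl("\\.gz$", p)) {
        fp <- tempfile(fileext = ".nex")
        writeLines(readLines(gzfile(p)), fp)
      }
      tr <- ape::read.nexus(fp)
    }
    if (inherits(tr, "phylo")) tr <- list(tr)
    trees <- c(trees, unclass(tr))
  }
  as_tree_set(trees)
}

#' Assemble and validate a posterior tree set from phylo objects
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`).
#' @return A `posterior_trees` object; see [read_tree_set()].
#' @export
as_tree_set <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0) abort("Empty tree set.")
  labs <- lapply(trees, function(t) sort(trimws(t$tip.label)))
  ref <- labs[[1]]
  for (i in seq_along(labs)) {
    if (!identical(labs[[i]], ref)) {
      d <- union(setdiff(labs[[i]], ref), setdiff(ref, labs[[i]]))
      abort(paste0("Tip sets differ across trees; symmetric difference: ",
                   paste(sort(d), collapse = ", ")))
    }
  }
  n_resolved <- 0L
  trees <- lapply(trees, function(t) {
    assert_tree(t)
    t$tip.label <- trimws(t$tip.label)
    if (!ape::is.binary(t)) {
      t <- ape::multi2di(t, random = FALSE)
      t$edge.length[is.na(t$edge.length)] <- 0
      n_resolved <<- n_resolved + 1L
    }
    if (!ape::is.rooted(t)) abort("All trees must be rooted.")
    if (tree_root_depth(t) <= 0) abort("Tree has zero root depth.")
    t
  })
  if (n_resolved > 0) {
    inform(sprintf("Resolved polytomies (zero-length branches) in %d tree(s).",
                   n_resolved))
  }
  structure(trees, class = c("posterior_trees", "multiPhylo"),
            labels = ref, n_resolved = n_resolved)
}

#' Genus-level means from the published Polyneoptera comparison table
#'
#' Returns the 23-genus summary table of mean haploid autosome numbers split
#' by sex chromosome system (XO, XY, multi-XY), as printed in the source
#' comparative study of Polyneoptera karyotypes: 23 genera covering 182
#' sampled taxa in which at least two SCS types co-occur. Feed it to
#' [classify_mechanism()] and [tabulate_mechanisms()] to reproduce the
#' fusion/fission classification.
#'
#' @return A tibble with columns `order`, `genus`, `n_samples`, `mean_xo`,
#'   `mean_xy`, `mean_multixy`.
#' @export
#' @examples
#' tab <- table1_fixture()
#' sum(tab$n_samples)
table1_fixture <- function() {
  path <- system.file("extdata", "table1_genus_scs.csv", package = "karyevo",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = "ccinnn", na = "NA", progress = FALSE)
}

#' Intersect a karyotype table with a tree set's tips
#'
#' Matching is exact and case-sensitive after stripping surrounding
#' whitespace. Taxa present on one side only are dropped with an informative
#' message; analyses proceed on the intersection.
#'
#' @param records Karyotype record tibble.
#' @param trees A `posterior_trees` object.
#' @return A list with `records` (restricted tibble), `trees` (tips pruned to
#'   the intersection) and `dropped` (list with `from_table`, `from_trees`).
#' @export
match_tips <- function(records, trees) {
  labs <- attr(trees, "labels") %||% sort(trees[[1]]$tip.label)
  sp <- trimws(records$species)
  keep <- intersect(sp, labs)
  if (length(keep) == 0) abort("No overlap between table species and tree tips.")
  dropped_table <- setdiff(sp, labs)
  dropped_trees <- setdiff(labs, sp)
  if (length(dropped_table) + length(dropped_trees) > 0) {
    inform(sprintf(
      "match_tips: %d species dropped from table, %d tips pruned from trees.",
      length(dropped_table), length(dropped_trees)))
  }
  trees2 <- lapply(unclass(trees), function(t) {
    drop <- setdiff(t$tip.label, keep)
    if (length(drop) > 0) t <- ape::drop.tip(t, drop)
    t
  })
  list(records = records[sp %in% keep, , drop = FALSE],
       trees = as_tree_set(trees2),
       dropped = list(from_table = dropped_table, from_trees = dropped_trees))
}
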