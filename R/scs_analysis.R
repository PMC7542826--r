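#' Per-genus mean autosome numbers by sex chromosome system
#'
#' For each genus (or a chosen one), averages the haploid autosome number of
#' its species within each SCS class. Species with ambiguous counts
#' contribute their within-species mean; species with unknown SCS are
#' excluded. SCS classes with no species are reported as `NA` means.
#'
#' @param records Karyotype record tibble (see [read_karyotype_table()]).
#' @param genus Optional single genus name; default summarises all genera.
#' @return A tibble with one row per genus: `order`, `genus`, `n_samples`,
#'   `n_xo`, `n_xy`, `n_multixy`, `mean_xo`, `mean_xy`, `mean_multixy`.
#' @export
summarize_genus <- function(records, genus = NULL) {
  if (!is.null(genus)) {
    records <- records[records$genus %in% genus, , drop = FALSE]
    if (nrow(records) == 0) abort(sprintf("Genus '%s' not found.", genus))
  }
  df <- records[records$scs %in% c("XO", "XY", "multiXY"), , drop = FALSE]
  if (nrow(df) == 0) {
    return(tibble::tibble(order = character(), genus = character(),
                          n_samples = integer(), n_xo = integer(),
                          n_xy = integer(), n_multixy = integer(),
                          mean_xo = numeric(), mean_xy = numeric(),
                          mean_multixy = numeric()))
  }
  df$count <- vapply(df$haploid_counts, function(x) mean(as.numeric(x)),
                     numeric(1))
  cell_mean <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  out <- df |>
    dplyr::group_by(.data$order, .data$genus) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_xo = sum(.data$scs == "XO"),
      n_xy = sum(.data$scs == "XY"),
      n_multixy = sum(.data$scs == "multiXY"),
      mean_xo = cell_mean(.data$count[.data$scs == "XO"]),
      mean_xy = cell_mean(.data$count[.data$scs == "XY"]),
      mean_multixy = cell_mean(.data$count[.data$scs == "multiXY"]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$order, .data$genus)
  out
}

#' Classify the mechanism behind SCS transitions within genera
#'
#' Compares mean autosome numbers between SCS classes within each genus. For
#' XO vs XY: a lower XY mean indicates a sex-chromosome-autosome **fusion**
#' (the fused autosome is lost from the autosome count); an XY mean exceeding
#' the XO mean by at least `threshold` indicates **fission**; a small
#' non-negative increase (below `threshold`) is classified as **neither**,
#' since a single fusion or fission must shift the count by a whole
#' chromosome. For transitions to multi-XY the reference is the XY mean when
#' present (else XO): a lower multi-XY mean suggests fusion, a higher or
#' unchanged mean suggests fission of an existing sex chromosome.
#'
#' @param summaries Tibble from [summarize_genus()] (or [table1_fixture()]).
#' @param threshold Minimum increase (in autosomes) to call fission on the
#'   XO-to-XY comparison (default 1).
#' @return The input with columns `classification_xo_xy` and
#'   `classification_to_multixy` added (`"fusion"`, `"fission"`, `"neither"`
#'   or `NA` when the comparison is not possible).
#' @export
classify_mechanism <- function(summaries, threshold = 1.0) {
  xo <- summaries$mean_xo
  xy <- summaries$mean_xy
  mx <- summaries$mean_multixy
  cls_xy <- dplyr::case_when(
    is.na(xo) | is.na(xy) ~ NA_character_,
    xy < xo ~ "fusion",
    xy >= xo + threshold ~ "fission",
    TRUE ~ "neither"
  )
  ref <- ifelse(is.na(xy), xo, xy)
  cls_mx <- dplyr::case_when(
    is.na(mx) | is.na(ref) ~ NA_character_,
    mx < ref ~ "fusion",
    TRUE ~ "fission"
  )
  summaries$classification_xo_xy <- cls_xy
  summaries$classification_to_multixy <- cls_mx
  summaries
}

#' Tabulate fusion/fission classifications across genera
#'
#' @param summaries Classified tibble from [classify_mechanism()].
#' @return A tibble with one row per (transition type, classification):
#'   `transition`, `classification`, `n`, `n_evaluable`, `percent`.
#' @export
tabulate_mechanisms <- function(summaries) {
  one <- function(col, transition) {
    x <- summaries[[col]]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(tibble::tibble(transition = transition,
                            classification = character(0), n = integer(0),
                            n_evaluable = integer(0), percent = numeric(0)))
    }
    tb <- table(factor(x, levels = c("fusion", "fission", "neither")))
    tibble::tibble(transition = transition, classification = names(tb),
                   n = as.integer(tb), n_evaluable = length(x),
                   percent = 100 * as.integer(tb) / length(x))
  }
  dplyr::bind_rows(one("classification_xo_xy", "XO_to_XY"),
                   one("classification_to_multixy", "to_multiXY"))
}

#' Per-order, per-SCS summaries of chromosome number
#'
#' @param records Karyotype record tibble with `order` and `scs` columns.
#' @return Tibble with `order`, `scs`, `n`, `mean`, `variance` (sample
#'   variance with `n - 1` denominator; `NA` for singleton cells).
#' @export
summarize_by_order <- function(records) {
  df <- records[records$scs %in% c("XO", "XY", "multiXY"), , drop = FALSE]
  df$count <- vapply(df$haploid_counts, function(x) mean(as.numeric(x)),
                     numeric(1))
  df |>
    dplyr::group_by(.data$order, .data$scs) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$count),
                     variance = if (dplyr::n() > 1) var(.data$count) else NA_real_,
                     .groups = "drop") |>
    dplyr::arrange(.data$order, .data$scs)
}
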