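#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods for pipeline result objects
#'
#' `tidy()` returns the underlying per-row table of a result object;
#' `glance()` returns a one-row summary.
#'
#' @param x A `pl_enrichment`, `pl_family_enrichment` or `pl_dedup`
#'   object.
#' @param ... Unused.
#' @return A tibble.
#' @name plasmidlead-tidiers
NULL

#' @rdname plasmidlead-tidiers
#' @exportS3Method generics::tidy
tidy.pl_enrichment <- function(x, ...) {
  as_tibble(x)
}

#' @rdname plasmidlead-tidiers
#' @exportS3Method generics::glance
glance.pl_enrichment <- function(x, ...) {
  tb <- as_tibble(x)
  tibble(
    n_positions = dplyr::n_distinct(tb$relative_position),
    n_tested = sum(tb$tested %||% FALSE),
    n_significant = sum(tb$significant, na.rm = TRUE),
    alpha = attr(x, "alpha"),
    min_orfs = attr(x, "min_orfs"))
}

#' @rdname plasmidlead-tidiers
#' @exportS3Method generics::tidy
tidy.pl_family_enrichment <- function(x, ...) {
  as_tibble(x)
}

#' @rdname plasmidlead-tidiers
#' @exportS3Method generics::glance
glance.pl_family_enrichment <- function(x, ...) {
  tb <- as_tibble(x)
  tibble(
    n_families = nrow(tb),
    n_enriched = sum(tb$enriched, na.rm = TRUE),
    n_t_strand = sum(tb$majority_orientation == "t_strand", na.rm = TRUE),
    alpha = attr(x, "alpha"))
}

#' @rdname plasmidlead-tidiers
#' @exportS3Method generics::tidy
tidy.pl_dedup <- function(x, ...) {
  x$removed
}

#' @rdname plasmidlead-tidiers
#' @exportS3Method generics::glance
glance.pl_dedup <- function(x, ...) {
  tibble(
    n_representatives = length(x$representatives),
    n_removed = nrow(x$removed),
    threshold = x$threshold)
}
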