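#' One-sided Fisher exact test (enrichment tail)
#'
#' Upper-tail hypergeometric probability `P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`: the chance of observing at least `k`
#' category ORFs among the `n` ORFs at a position when `K` of the `N`
#' ORFs in the background carry the category. Computed exactly in
#' log-space via [stats::phyper()]. Vectorised over its arguments.
#'
#' @param k Observed category count at the position.
#' @param K Category count in the reference population.
#' @param n ORFs at the position.
#' @param N Total ORFs in the reference population.
#' @return p-value(s) in `[0, 1]`.
#' @export
fisher_one_sided <- function(k, K, n, N) {
  bad <- !(k >= 0 & k <= n & K >= 0 & K <= N & n <= N & k <= K &
             (n - k) <= (N - K))
  if (any(bad)) {
    abort(sprintf("invalid hypergeometric margins (first offender: k=%s K=%s n=%s N=%s)",
                  k[bad][1], K[bad][1], n[bad][1], N[bad][1]))
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up FDR adjustment; a hypothesis is rejected when its adjusted
#' p-value (q-value) is at most `alpha`. q-values are monotone
#' non-decreasing in sorted p order and never smaller than the raw p.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param alpha FDR level (default 0.001).
#' @return A tibble `p_value, q_value, significant` in input order.
#' @export
bh_fdr <- function(p_values, alpha = 0.001) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  q <- p.adjust(p_values, method = "BH")
  tibble(p_value = p_values, q_value = q, significant = q <= alpha)
}

#' Tally ORF counts per oriT-relative position
#'
#' Aggregates a geometry table over contigs into per-position totals and
#' per-category counts, including the combined anti-defence class
#' (anti-CRISPR + anti-restriction + SOS inhibition).
#'
#' @param geometry Geometry table with a `category` column
#'   ([assign_relative_positions()]).
#' @return A tidy tibble `relative_position, category, n, n_total` with
#'   one row per position x category (categories observed anywhere, plus
#'   `anti_defence`), of class `pl_position_table`.
#' @export
tally_positions <- function(geometry) {
  if (!"category" %in% names(geometry)) {
    abort("geometry must carry a 'category' column (see assign_categories)")
  }
  totals <- geometry |>
    count(.data$relative_position, name = "n_total")
  cats <- sort(unique(geometry$category))
  per_cat <- geometry |>
    count(.data$relative_position, .data$category, name = "n")
  anti <- geometry |>
    filter(.data$category %in% PL_ANTI_DEFENCE) |>
    count(.data$relative_position, name = "n") |>
    mutate(category = "anti_defence")
  grid <- tidyr::expand_grid(
    relative_position = totals$relative_position,
    category = c(cats, "anti_defence"))
  out <- grid |>
    left_join(bind_rows(per_cat, anti),
              by = c("relative_position", "category")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    left_join(totals, by = "relative_position") |>
    arrange(.data$category, .data$relative_position)
  structure(out, class = c("pl_position_table", class(out)))
}

#' Smoothed per-position category frequency over an ORF window
#'
#' For each position the frequency is the category count summed over a
#' centred window of `window` positions divided by the total ORF count
#' over the same window; the window is truncated at the ends of the index
#' range. The default five-ORF window matches the reporting convention
#' for anti-defence frequency curves.
#'
#' @param table A `pl_position_table` from [tally_positions()].
#' @param window Odd window width (default 5).
#' @return `table` with an `f_w` column added.
#' @export
windowed_frequency <- function(table, window = 5) {
  if (window %% 2 != 1) abort("window must be odd")
  half <- (window - 1) / 2
  out <- table |>
    group_by(.data$category) |>
    arrange(.data$relative_position, .by_group = TRUE) |>
    mutate(f_w = {
      pos <- .data$relative_position
      vapply(seq_along(pos), function(i) {
        inw <- abs(pos - pos[i]) <= half
        sum(.data$n[inw]) / sum(.data$n_total[inw])
      }, double(1))
    }) |>
    ungroup()
  structure(out, class = unique(c("pl_position_table", class(out))))
}

#' Test per-position enrichment of a gene category
#'
#' For every position with at least `min_orfs` ORFs, the category count at
#' the position is compared with the pooled counts of all other positions
#' by a one-sided (upper tail) Fisher exact test, followed by
#' Benjamini-Hochberg FDR correction across the tested positions of each
#' category. (Testing a position against the pooled complement is
#' identical to drawing the position's `n` ORFs from the grand totals:
#' the hypergeometric margins coincide.)
#'
#' @param table A `pl_position_table`, optionally with `f_w`.
#' @param categories Categories to test (default: the combined
#'   anti-defence class plus each of its three constituent categories).
#' @param min_orfs Minimum ORFs for a position to be tested (default 50).
#' @param alpha FDR level (default 0.001).
#' @return A tibble of class `pl_enrichment`: the rows of `table` for the
#'   requested categories with `tested, p_value, q_value, significant`
#'   columns. Untested positions carry `NA` p/q.
#' @export
test_position_enrichment <- function(table,
                                     categories = c("anti_defence",
                                                    PL_ANTI_DEFENCE),
                                     min_orfs = 50, alpha = 0.001) {
  tab <- table |> filter(.data$category %in% categories)
  if (nrow(tab) == 0) {
    warn("no rows for the requested categories; empty result")
    return(structure(tab, class = c("pl_enrichment", class(tab)),
                     alpha = alpha, min_orfs = min_orfs))
  }
  out <- tab |>
    group_by(.data$category) |>
    mutate(tested = .data$n_total >= min_orfs) |>
    mutate(p_value = {
      K_all <- sum(.data$n)
      N_all <- sum(.data$n_total)
      ifelse(.data$tested,
             fisher_one_sided(.data$n, K_all, .data$n_total, N_all),
             NA_real_)
    }) |>
    mutate(q_value = {
      q <- rep(NA_real_, dplyr::n())
      if (any(.data$tested)) {
        q[.data$tested] <- p.adjust(.data$p_value[.data$tested], "BH")
      }
      q
    },
    significant = !is.na(.data$q_value) & .data$q_value <= alpha) |>
    ungroup()
  if (!any(out$tested)) {
    warn(sprintf("no positions with >= %d ORFs; nothing tested", min_orfs))
  }
  structure(out, class = unique(c("pl_enrichment", class(out))),
            alpha = alpha, min_orfs = min_orfs)
}

#' Test gene-family enrichment in the leading region
#'
#' For each gene family (ORF cluster) the count of members at leading
#' positions `leading_range` is compared with the family's count
#' elsewhere against the same split of all ORFs, by a one-sided Fisher
#' exact test with BH-FDR across families. Families smaller than
#' `min_size` are not analysed. The family's overall orientation is the
#' majority vote of its members' T-strand expressibility, and its
#' annotation the modal member annotation.
#'
#' @param geometry Geometry table.
#' @param families Tibble `gene_id, family_id` (an ORF cluster
#'   membership works directly with `cluster_id` renamed).
#' @param leading_range Inclusive relative-position bounds defining the
#'   leading region genes under test, default `c(0, 27)` (the first 28
#'   leading ORFs).
#' @param alpha FDR level (default 0.001).
#' @param min_size Minimum family size to analyse (default 5).
#' @param annotations Optional tibble `gene_id, annotation` for the
#'   majority annotation.
#' @return A tibble of class `pl_family_enrichment`: `family_id, size,
#'   leading_count, elsewhere_count, p_value, q_value, enriched,
#'   majority_orientation, majority_annotation`.
#' @export
test_family_enrichment <- function(geometry, families,
                                   leading_range = c(0, 27),
                                   alpha = 0.001, min_size = 5,
                                   annotations = NULL) {
  fam <- geometry |>
    inner_join(families, by = "gene_id")
  skipped <- anti_join(families, geometry, by = "gene_id")
  if (nrow(skipped) > 0) {
    warn(sprintf("%d family member(s) absent from the geometry were skipped",
                 nrow(skipped)))
  }
  in_lead <- function(p) p >= leading_range[1] & p <= leading_range[2]
  n_lead <- sum(in_lead(geometry$relative_position))
  n_all <- nrow(geometry)
  res <- fam |>
    group_by(.data$family_id) |>
    summarise(
      size = n(),
      leading_count = sum(in_lead(.data$relative_position)),
      elsewhere_count = .data$size - .data$leading_count,
      majority_orientation = majority_orientation(.data$t_strand_expressible),
      .groups = "drop") |>
    filter(.data$size >= min_size)
  if (nrow(res) == 0) {
    warn("no family reaches min_size; empty result")
    return(structure(res, class = c("pl_family_enrichment", class(res)),
                     alpha = alpha))
  }
  res <- res |>
    mutate(p_value = fisher_one_sided(.data$leading_count, .data$size,
                                      n_lead, n_all))
  fdr <- bh_fdr(res$p_value, alpha)
  res$q_value <- fdr$q_value
  res$enriched <- fdr$significant
  if (!is.null(annotations)) {
    ann <- fam |>
      left_join(annotations, by = "gene_id") |>
      group_by(.data$family_id) |>
      summarise(majority_annotation =
                  family_majority_annotation(.data$annotation),
                .groups = "drop")
    res <- left_join(res, ann, by = "family_id")
  } else {
    res$majority_annotation <- "uncharacterized"
  }
  structure(arrange(res, .data$q_value, .data$family_id),
            class = c("pl_family_enrichment", class(res)), alpha = alpha)
}

#' Majority orientation of a gene family
#'
#' @param t_flags Logical vector of per-member T-strand expressibility.
#' @return `"t_strand"`, `"opposite"` or `"tie"` (exact tie).
#' @export
majority_orientation <- function(t_flags) {
  t_flags <- t_flags[!is.na(t_flags)]
  if (length(t_flags) == 0) return(NA_character_)
  k <- sum(t_flags)
  if (2 * k > length(t_flags)) "t_strand"
  else if (2 * k < length(t_flags)) "opposite"
  else "tie"
}

#' Modal annotation of a gene family
#'
#' Most frequent member annotation; ties resolved to the
#' lexicographically smallest label; no annotations at all yields
#' `"uncharacterized"`.
#'
#' @param labels Character vector of member annotations (`NA` = absent).
#' @return A single label.
#' @export
family_majority_annotation <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) return("uncharacterized")
  tab <- table(labels)
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1]
}
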