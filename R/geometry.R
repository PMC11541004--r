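#' Select the best oriT hit on a contig
#'
#' When a contig has more than one oriT hit the best-scoring hit is taken.
#' Ties are broken by lowest e-value, then leftmost subject start, then
#' lexicographically smallest query id, so selection is deterministic.
#' Scores are bit scores when present (external blast6 input) and raw
#' alignment scores otherwise (built-in aligner).
#'
#' @param hits Hit tibble for a single contig.
#' @return A one-row tibble (the winning hit), or a zero-row tibble when
#'   `hits` is empty (absence signal: the contig is skipped upstream).
#' @export
select_best_orit <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  if (length(unique(hits$subject_id)) > 1) {
    abort("select_best_orit expects hits for a single contig")
  }
  raw <- if ("raw_score" %in% names(hits)) {
    as.double(hits$raw_score)
  } else {
    rep(NA_real_, nrow(hits))
  }
  hits |>
    mutate(.score = dplyr::coalesce(.data$bit_score, .env$raw),
           .evalue = dplyr::coalesce(.data$e_value, 0)) |>
    arrange(desc(.data$.score), .data$.evalue, .data$s_start,
            .data$query_id) |>
    slice(1) |>
    select(-".score", -".evalue")
}

#' Quality-control filter for oriT/relaxase geometry
#'
#' Applies the contig-level filters that make leading/lagging orientation
#' well defined:
#' * contigs with more than `max_relaxase_hits` relaxase/TraM hits are
#'   rejected (`too_many_relaxases`);
#' * contigs without a relaxase hit or without an oriT hit are rejected
#'   (`no_relaxase`, `no_orit`);
#' * the nucleotide distance between the relaxase gene and the oriT
#'   (0 when they overlap) must not exceed `max_distance` (`too_far`);
#' * an oriT entirely contained within the relaxase gene is rejected
#'   (`orit_inside_relaxase`); partial overlap is retained;
#' * contigs where the relaxase gene or the oriT sit at the first or last
#'   annotated position are rejected (`edge_placement`), since the
#'   relative location of oriT and relaxase cannot then be resolved.
#'
#' @param genes Gene table with ordinals (all contigs).
#' @param relaxase_hits Protein-level relaxase/TraM hits (subject = gene id).
#' @param orit_hits Nucleotide oriT hits (subject = contig id, with
#'   subject intervals).
#' @param max_relaxase_hits Maximum relaxase/TraM hits per contig (default 2).
#' @param max_distance Maximum relaxase-to-oriT distance in bp (default 3500).
#' @return A tibble with one row per contig: `contig_id, pass, reason`,
#'   and for passing contigs the oriT assignment columns `orit_start,
#'   orit_end, orit_query, relaxase_gene_id, relaxase_start, relaxase_end,
#'   distance_bp`.
#' @export
qc_filter_contigs <- function(genes, relaxase_hits, orit_hits,
                              max_relaxase_hits = 2, max_distance = 3500) {
  contigs <- unique(genes$contig_id)
  gene2contig <- setNames(genes$contig_id, genes$gene_id)
  genes_df <- as.data.frame(genes)[c("contig_id", "gene_id", "start", "end",
                                     "ordinal")]
  g_split <- split(genes_df, genes_df$contig_id)
  rel_df <- as.data.frame(relaxase_hits)
  rel_split <- split(rel_df, factor(unname(gene2contig[rel_df$subject_id]),
                                    levels = contigs))
  ori_df <- as.data.frame(orit_hits)
  ori_split <- split(ori_df, factor(ori_df$subject_id, levels = contigs))
  rows <- lapply(contigs, function(cid) {
    g <- g_split[[cid]]
    rel <- rel_split[[cid]]
    ori <- ori_split[[cid]]
    fail <- function(reason) list(contig_id = cid, pass = FALSE,
                                  reason = reason)
    if (is.null(rel) || nrow(rel) == 0) return(fail("no_relaxase"))
    if (is.null(ori) || nrow(ori) == 0) return(fail("no_orit"))
    if (nrow(rel) > max_relaxase_hits) return(fail("too_many_relaxases"))
    bo <- best_hit_row(ori)
    # relaxase gene = gene carrying the best relaxase/TraM hit
    br <- rel[order(-rel$bit_score, rel$e_value, rel$query_id)[1], ]
    rg <- g[g$gene_id == br$subject_id, ]
    distance_bp <- max(0L, max(bo$s_start, rg$start) -
                         min(bo$s_end, rg$end))
    if (distance_bp > max_distance) return(fail("too_far"))
    if (bo$s_start >= rg$start && bo$s_end <= rg$end) {
      return(fail("orit_inside_relaxase"))
    }
    orit_mid <- (bo$s_start + bo$s_end) / 2
    gene_mids <- (g$start + g$end) / 2
    edge_rel <- rg$ordinal == 0L || rg$ordinal == max(g$ordinal)
    edge_ori <- orit_mid <= min(gene_mids) || orit_mid >= max(gene_mids)
    if (edge_rel || edge_ori) return(fail("edge_placement"))
    list(contig_id = cid, pass = TRUE, reason = NA_character_,
         orit_start = bo$s_start, orit_end = bo$s_end,
         orit_query = bo$query_id,
         relaxase_gene_id = rg$gene_id,
         relaxase_start = rg$start, relaxase_end = rg$end,
         distance_bp = as.integer(distance_bp))
  })
  out <- bind_rows(rows)
  if (!"orit_start" %in% names(out)) {
    out$orit_start <- NA_integer_
    out$orit_end <- NA_integer_
    out$orit_query <- NA_character_
    out$relaxase_gene_id <- NA_character_
    out$relaxase_start <- NA_integer_
    out$relaxase_end <- NA_integer_
    out$distance_bp <- NA_integer_
  }
  out
}

# fastest-path version of the oriT tie-break rule on a plain data frame
best_hit_row <- function(h) {
  score <- h$bit_score
  if ("raw_score" %in% names(h)) {
    score <- ifelse(is.na(score), as.double(h$raw_score), score)
  }
  ev <- ifelse(is.na(h$e_value), 0, h$e_value)
  h[order(-score, ev, h$s_start, h$query_id)[1], ]
}

#' Assign oriT-relative ORF positions and T-strand expressibility
#'
#' Orients each QC-passing contig: the leading side is the side of the
#' oriT opposite the relaxase (the relaxase marks the lagging, last
#' transferred region), anchored at the oriT midpoint as a proxy for the
#' nic site. Leading-side genes are indexed 0, 1, 2, ... outward from the
#' oriT (0 = first ORF of the leading region); lagging-side genes -1, -2,
#' ... outward. Gene side is decided by the gene midpoint; a midpoint
#' exactly at the oriT midpoint counts as leading (position 0 side).
#'
#' A gene is `t_strand_expressible` when the transferred single strand can
#' serve as its transcription template. Under the default `"toward_oriT"`
#' convention this holds when the gene's transcription direction opposes
#' the leading direction; `"away_from_oriT"` flips the test. Both the
#' relative positions and the flags are invariant under reverse
#' complementing a contig.
#'
#' @param genes Gene table (with `category` column if available).
#' @param assignments QC table from [qc_filter_contigs()]; only passing
#'   rows are used.
#' @param convention `"toward_oriT"` (default) or `"away_from_oriT"`.
#' @return A geometry tibble: gene columns plus `leading_direction`
#'   (+1/-1), `relative_position` and `t_strand_expressible`.
#' @export
assign_relative_positions <- function(genes, assignments,
                                      convention = c("toward_oriT",
                                                     "away_from_oriT")) {
  convention <- match.arg(convention)
  ass <- assignments |> filter(.data$pass)
  geo <- genes |>
    inner_join(select(ass, "contig_id", "orit_start", "orit_end",
                      "relaxase_start", "relaxase_end", "relaxase_gene_id"),
               by = "contig_id") |>
    mutate(
      .mid = (.data$start + .data$end) / 2,
      .orit_mid = (.data$orit_start + .data$orit_end) / 2,
      .rel_mid = (.data$relaxase_start + .data$relaxase_end) / 2,
      leading_direction = as.integer(sign(.data$.orit_mid - .data$.rel_mid))
    )
  if (any(geo$leading_direction == 0L)) {
    bad <- unique(geo$contig_id[geo$leading_direction == 0L])
    abort(sprintf("degenerate geometry (oriT and relaxase midpoints equal) on: %s",
                  paste(head(bad, 3), collapse = ", ")))
  }
  geo <- geo |>
    mutate(
      .along = (.data$.mid - .data$.orit_mid) * .data$leading_direction,
      .leading = .data$.along >= 0
    ) |>
    group_by(.data$contig_id, .data$.leading) |>
    arrange(abs(.data$.along), .data$start, .data$gene_id,
            .by_group = TRUE) |>
    mutate(relative_position = if (.data$.leading[1]) {
      row_number() - 1L
    } else {
      -row_number()
    }) |>
    ungroup()
  sgn <- strand_sign(geo$strand)
  expressible <- sgn == -geo$leading_direction
  if (convention == "away_from_oriT") expressible <- !expressible
  geo |>
    mutate(t_strand_expressible = expressible) |>
    select(-dplyr::starts_with("."), -"orit_start", -"orit_end",
           -"relaxase_start", -"relaxase_end") |>
    mutate(is_relaxase = .data$gene_id == .data$relaxase_gene_id) |>
    select(-"relaxase_gene_id") |>
    arrange(.data$contig_id, .data$relative_position)
}

#' @rdname assign_relative_positions
#' @param geometry A geometry tibble.
#' @param path Output path for the geometry TSV (`contig_id, gene_id,
#'   relative_position, t_strand_expressible, leading_direction`, plus
#'   gene columns).
#' @export
write_geometry <- function(geometry, path) {
  readr::write_tsv(geometry, path, progress = FALSE)
  invisible(path)
}
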