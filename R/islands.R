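#' Delineate anti-defence islands in leading regions
#'
#' Scans each contig's leading region (relative positions 0 upward) for
#' maximal runs of island-qualifying genes (anti-defence categories plus
#' orphan MTases, SSBs and toxin-antitoxin systems by default). A run
#' must start within leading positions `0..leading_end`; up to `max_gap`
#' consecutive non-qualifying genes are tolerated inside a run. A
#' umu-like gene terminates the island and sets its distal boundary to
#' `umu_like_operon`; otherwise the boundary is `none`. The proximal
#' boundary is always the oriT. Islands with fewer than `min_members`
#' qualifying genes are discarded. Runs may extend past `leading_end`
#' when qualifying genes continue; such islands are flagged.
#'
#' @param geometry Geometry table with `category`
#'   ([assign_relative_positions()] + [assign_categories()]).
#' @param qualifying Categories whose genes count as island members.
#' @param max_gap Maximum run of intervening non-qualifying genes (default 2).
#' @param min_members Minimum qualifying genes per island (default 3).
#' @param leading_end Last leading position at which an island may start
#'   (default 27).
#' @return A tibble of class `pl_islands`, one row per island:
#'   `contig_id, start_position, end_position, n_members, boundary_start,
#'   boundary_end, extends_beyond_leading, members` (list column of gene
#'   ids of the qualifying members, in positional order).
#' @export
detect_islands <- function(geometry,
                           qualifying = pl_island_categories(),
                           max_gap = 2, min_members = 3,
                           leading_end = 27) {
  if (!"category" %in% names(geometry)) {
    abort("geometry must carry a 'category' column")
  }
  res <- geometry |>
    filter(.data$relative_position >= 0) |>
    arrange(.data$contig_id, .data$relative_position) |>
    group_by(.data$contig_id) |>
    dplyr::group_map(function(g, key) {
      islands <- scan_island_runs(g, qualifying, max_gap, min_members,
                                  leading_end)
      if (nrow(islands) > 0) islands$contig_id <- key$contig_id
      islands
    }) |>
    bind_rows()
  if (nrow(res) == 0) {
    res <- tibble(contig_id = character(), start_position = integer(),
                  end_position = integer(), n_members = integer(),
                  boundary_start = character(), boundary_end = character(),
                  extends_beyond_leading = logical(), members = list())
  } else {
    res <- select(res, "contig_id", "start_position", "end_position",
                  "n_members", "boundary_start", "boundary_end",
                  "extends_beyond_leading", "members")
  }
  structure(res, class = c("pl_islands", class(res)))
}

# single-contig scan; g has leading genes sorted by relative_position
scan_island_runs <- function(g, qualifying, max_gap, min_members,
                             leading_end) {
  qual <- g$category %in% qualifying
  umu <- g$category == "umu_like"
  islands <- list()
  members <- integer()  # row indices of qualifying members
  gap <- 0L
  close_island <- function(members, boundary_end) {
    if (length(members) < min_members) return(NULL)
    pos <- g$relative_position[members]
    tibble(start_position = min(pos), end_position = max(pos),
           n_members = length(members),
           boundary_start = "oriT", boundary_end = boundary_end,
           extends_beyond_leading = max(pos) > leading_end,
           members = list(g$gene_id[members]))
  }
  for (i in seq_len(nrow(g))) {
    if (umu[i]) {
      if (length(members) > 0) {
        isl <- close_island(members, "umu_like_operon")
        if (!is.null(isl)) islands[[length(islands) + 1]] <- isl
        members <- integer(); gap <- 0L
      }
    } else if (qual[i]) {
      if (length(members) > 0 || g$relative_position[i] <= leading_end) {
        members <- c(members, i)
        gap <- 0L
      }
    } else if (length(members) > 0) {
      gap <- gap + 1L
      if (gap > max_gap) {
        isl <- close_island(members, "none")
        if (!is.null(isl)) islands[[length(islands) + 1]] <- isl
        members <- integer(); gap <- 0L
      }
    }
  }
  if (length(members) > 0) {
    isl <- close_island(members, "none")
    if (!is.null(isl)) islands[[length(islands) + 1]] <- isl
  }
  if (length(islands) == 0) return(tibble())
  bind_rows(islands)
}

#' Summarise island composition
#'
#' Per-island counts of member genes by functional category, the fraction
#' of members expressible from the T-strand, and (when a set of
#' leading-enriched uncharacterized families is supplied) the count of
#' uncharacterized-but-enriched members flagged separately.
#'
#' @param islands A `pl_islands` tibble ([detect_islands()]).
#' @param geometry The geometry table the islands were called on.
#' @param enriched_uncharacterized Optional character vector of gene ids
#'   belonging to leading-enriched but uncharacterized families.
#' @return A tibble, one row per island x category:
#'   `contig_id, start_position, end_position, category, n`, plus
#'   per-island columns `fraction_t_strand` and `n_uncharacterized_enriched`.
#' @export
summarize_island <- function(islands, geometry,
                             enriched_uncharacterized = NULL) {
  if (nrow(islands) == 0) {
    return(tibble(contig_id = character(), start_position = integer(),
                  end_position = integer(), category = character(),
                  n = integer(), fraction_t_strand = double(),
                  n_uncharacterized_enriched = integer()))
  }
  purrr::pmap_dfr(islands, function(contig_id, start_position, end_position,
                                    members, ...) {
    g <- geometry |>
      filter(.data$contig_id == .env$contig_id,
             .data$gene_id %in% members)
    comp <- g |> count(.data$category, name = "n")
    comp |>
      mutate(contig_id = contig_id, start_position = start_position,
             end_position = end_position,
             fraction_t_strand = mean(g$t_strand_expressible),
             n_uncharacterized_enriched = if (is.null(enriched_uncharacterized)) {
               0L
             } else {
               sum(g$gene_id %in% enriched_uncharacterized &
                     g$category == "uncharacterized")
             }) |>
      select("contig_id", "start_position", "end_position", "category",
             "n", "fraction_t_strand", "n_uncharacterized_enriched")
  })
}

#' Write island calls
#'
#' @param islands A `pl_islands` tibble.
#' @param tsv_path Output TSV (members collapsed with commas).
#' @param json_path Optional JSON with full member lists.
#' @return `tsv_path`, invisibly.
#' @export
write_islands <- function(islands, tsv_path, json_path = NULL) {
  flat <- islands |>
    mutate(members = vapply(.data$members, paste, character(1),
                            collapse = ","))
  readr::write_tsv(flat, tsv_path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      purrr::pmap(islands, function(...) list(...)),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(tsv_path)
}
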