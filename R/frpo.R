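#' Extract upstream regulatory regions of leading-region genes
#'
#' For every leading-region gene the intergenic span between the gene's
#' strand-aware start and the previous feature (the adjacent gene in
#' genomic coordinates, or the contig end) is extracted. Spans shorter
#' than `len_min` or longer than `len_max` nucleotides are excluded
#' (default 50-350 bp). The returned sequence is the 5'->3' sequence of
#' the gene's coding orientation, i.e. reverse complemented for
#' minus-strand genes.
#'
#' @param geometry Geometry table ([assign_relative_positions()]).
#' @param sequences Named character vector or `DNAStringSet` of contig
#'   sequences.
#' @param len_min,len_max Inclusive length bounds (defaults 50 and 350).
#' @param leading_only Restrict to genes with `relative_position >= 0`
#'   (default `TRUE`).
#' @return A tibble `contig_id, gene_id, relative_position, r_start,
#'   r_end` (0-based half-open contig coordinates), `strand, length,
#'   sequence`.
#' @export
extract_upstream_regions <- function(geometry, sequences, len_min = 50,
                                     len_max = 350, leading_only = TRUE) {
  sequences <- setNames(as.character(sequences), names(sequences))
  missing_seq <- setdiff(unique(geometry$contig_id), names(sequences))
  if (length(missing_seq) > 0) {
    abort(sprintf("no sequence supplied for contig(s): %s",
                  paste(head(missing_seq, 3), collapse = ", ")))
  }
  g <- geometry |>
    group_by(.data$contig_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(.prev_end = dplyr::lag(.data$end, default = 0L),
           .next_start = dplyr::lead(
             .data$start,
             default = nchar(sequences[[.data$contig_id[1]]]))) |>
    ungroup()
  if (leading_only) g <- filter(g, .data$relative_position >= 0)
  regions <- g |>
    mutate(r_start = ifelse(.data$strand == "+", .data$.prev_end, .data$end),
           r_end = ifelse(.data$strand == "+", .data$start,
                          .data$.next_start),
           length = .data$r_end - .data$r_start) |>
    filter(.data$length >= len_min, .data$length <= len_max)
  seqs <- vapply(seq_len(nrow(regions)), function(i) {
    s <- substring(sequences[[regions$contig_id[i]]],
                   regions$r_start[i] + 1L, regions$r_end[i])
    if (regions$strand[i] == "-") cpp_revcomp(toupper(s)) else toupper(s)
  }, character(1))
  regions |>
    mutate(sequence = seqs) |>
    select("contig_id", "gene_id", "relative_position", "r_start", "r_end",
           "strand", "length", "sequence")
}

#' Homology scan of regulatory regions against known Frpo/ssi sequences
#'
#' Runs the built-in seeded aligner ([seed_and_extend()]) for each region
#' against each known query and keeps the best hit with raw score at or
#' above `scheme$min_score`. Strand-symmetric: the homology outcome is
#' unchanged if a region is reverse complemented.
#'
#' @param regions Tibble from [extract_upstream_regions()].
#' @param known_frpo Named character vector / `DNAStringSet` of known
#'   Frpo/ssi sequences.
#' @param scheme A [scoring_scheme()].
#' @return `regions` with `frpo_query, frpo_score, frpo_identity` columns
#'   (`NA` where no hit reaches the threshold).
#' @export
homology_scan <- function(regions, known_frpo, scheme = scoring_scheme()) {
  known_frpo <- setNames(as.character(known_frpo), names(known_frpo))
  best <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    hits <- purrr::imap_dfr(known_frpo, function(q, qid) {
      h <- seed_and_extend(q, regions$sequence[i], scheme, query_id = qid,
                           subject_id = regions$gene_id[i])
      head(h, 1)
    })
    if (nrow(hits) == 0) {
      return(tibble(frpo_query = NA_character_, frpo_score = NA_integer_,
                    frpo_identity = NA_real_))
    }
    h <- hits |> arrange(desc(.data$raw_score), .data$query_id) |> slice(1)
    tibble(frpo_query = h$query_id, frpo_score = h$raw_score,
           frpo_identity = h$percent_identity)
  })
  bind_cols(regions, best)
}

#' Scan a region for sigma-70 promoter consensus elements
#'
#' Enumerates every pair of hexamer placements where the -35 element
#' matches `TTGACA` with at most `max_mm35` mismatches, the -10 element
#' matches `TATAAT` with at most `max_mm10` mismatches, and the spacer
#' between them lies within `spacer` (inclusive bounds). The AT fraction
#' of the `up_window` nucleotides immediately upstream of the -35
#' placement (truncated at the region start) is reported as UP-element
#' evidence.
#'
#' @param sequence Region sequence (character; 5'->3' coding orientation).
#' @param max_mm35,max_mm10 Per-hexamer mismatch budgets (default 2).
#' @param spacer Inclusive spacer bounds, default `c(15, 19)`.
#' @param up_window UP-element window width (default 20).
#' @return A tibble `minus35_offset, minus10_offset` (0-based offsets in
#'   the region), `mm35, mm10, total_mm, spacer, up_at_fraction`.
#' @export
scan_sigma70_elements <- function(sequence, max_mm35 = 2, max_mm10 = 2,
                                  spacer = c(15, 19), up_window = 20) {
  sequence <- as_plain_seq(sequence)
  n <- nchar(sequence)
  empty <- tibble(minus35_offset = integer(), minus10_offset = integer(),
                  mm35 = integer(), mm10 = integer(), total_mm = integer(),
                  spacer = integer(), up_at_fraction = double())
  if (n < 12 + spacer[1]) return(empty)
  chars <- strsplit(sequence, "")[[1]]
  hex_mm <- function(consensus) {
    cc <- strsplit(consensus, "")[[1]]
    starts <- seq_len(n - 5L)
    vapply(starts, function(s) sum(chars[s:(s + 5L)] != cc), integer(1))
  }
  mm35_all <- hex_mm("TTGACA")
  mm10_all <- hex_mm("TATAAT")
  i35 <- which(mm35_all <= max_mm35)
  i10 <- which(mm10_all <= max_mm10)
  if (length(i35) == 0 || length(i10) == 0) return(empty)
  pairs <- tidyr::expand_grid(i = i35, j = i10) |>
    mutate(spacer = .data$j - (.data$i + 6L)) |>
    filter(.data$spacer >= .env$spacer[1], .data$spacer <= .env$spacer[2])
  if (nrow(pairs) == 0) return(empty)
  at <- chars %in% c("A", "T")
  pairs |>
    mutate(
      minus35_offset = .data$i - 1L,
      minus10_offset = .data$j - 1L,
      mm35 = mm35_all[.data$i],
      mm10 = mm10_all[.data$j],
      total_mm = .data$mm35 + .data$mm10,
      up_at_fraction = vapply(.data$i, function(s) {
        w <- max(1L, s - up_window):(s - 1L)
        if (s == 1L) return(NA_real_)
        mean(at[w])
      }, double(1))
    ) |>
    select("minus35_offset", "minus10_offset", "mm35", "mm10", "total_mm",
           "spacer", "up_at_fraction") |>
    arrange(.data$total_mm, .data$minus35_offset)
}

#' Base-pair maximization secondary structure
#'
#' Nussinov-style base-pair maximization over Watson-Crick pairs plus G:T
#' wobble, with hairpin loops of at least `min_loop` unpaired
#' nucleotides. One optimal structure is recovered by a deterministic
#' traceback (a pairing of the leftmost base is preferred over leaving it
#' unpaired, taking the rightmost admissible partner). This is a
#' combinatorial stand-in for thermodynamic folding: it scores how much
#' of a region can be locked into a duplex, which is the evidence needed
#' for dsDNA-mimicking hairpin elements. A dot-bracket string from an
#' external thermodynamic folder can be supplied to downstream steps
#' instead (see [hairpin_evidence()]).
#'
#' @param sequence DNA sequence (length <= 400).
#' @param min_loop Minimum hairpin loop length (default 3).
#' @return A list of class `pl_structure`: `n_pairs`, `pairs` (tibble
#'   `i, j`, 0-based positions, i < j), `dotbracket`, `length`.
#' @export
max_basepairs <- function(sequence, min_loop = 3) {
  sequence <- as_plain_seq(sequence)
  if (nchar(sequence) > 400) {
    abort("max_basepairs: sequence longer than the 400 nt cap")
  }
  r <- cpp_nussinov(sequence, as.integer(min_loop))
  structure(
    list(n_pairs = r$n_pairs,
         pairs = tibble(i = as.integer(r$pair_i), j = as.integer(r$pair_j)),
         dotbracket = r$dotbracket,
         length = nchar(sequence)),
    class = "pl_structure")
}

#' Parse a dot-bracket string into a `pl_structure`
#'
#' Allows plugging structures predicted by an external folder into
#' [hairpin_evidence()].
#'
#' @param dotbracket A string over `(`, `)` and `.`.
#' @return A `pl_structure`.
#' @export
structure_from_dotbracket <- function(dotbracket) {
  chars <- strsplit(dotbracket, "")[[1]]
  stack <- integer()
  pi <- integer(); pj <- integer()
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (length(stack) == 0) abort("unbalanced dot-bracket string")
      pi <- c(pi, stack[length(stack)] - 1L)
      pj <- c(pj, k - 1L)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0) abort("unbalanced dot-bracket string")
  structure(
    list(n_pairs = length(pi),
         pairs = tibble(i = pi, j = pj) |> arrange(.data$i),
         dotbracket = dotbracket, length = length(chars)),
    class = "pl_structure")
}

#' @export
print.pl_structure <- function(x, ...) {
  cat(sprintf("<pl_structure> %d nt, %d base pairs\n%s\n",
              x$length, x$n_pairs, x$dotbracket))
  invisible(x)
}

#' Hairpin (dsDNA-mimicry) evidence for a promoter element
#'
#' Computes the fraction of the 12 promoter-element nucleotides (the two
#' hexamers) that are paired in the structure, and a stem flag. The stem
#' flag requires (i) at least half of the element nucleotides paired and
#' (ii) a contiguous helix of at least `min_stem` stacked base pairs
#' touching the element - isolated pairs scattered over the hexamers do
#' not mimic double-stranded DNA, a genuine Frpo-like stem does.
#'
#' @param element_hit One row of [scan_sigma70_elements()] output.
#' @param structure A `pl_structure` for the same region sequence.
#' @param min_stem Minimum stacked-helix length for the stem flag
#'   (default 10).
#' @return A list: `paired_fraction`, `stem` (logical),
#'   `max_element_helix` (longest helix touching the element).
#' @export
hairpin_evidence <- function(element_hit, structure, min_stem = 10) {
  el_pos <- c(element_hit$minus35_offset + 0:5,
              element_hit$minus10_offset + 0:5)
  pairs <- structure$pairs
  paired_pos <- c(pairs$i, pairs$j)
  paired_fraction <- mean(el_pos %in% paired_pos)
  max_helix <- 0L
  if (nrow(pairs) > 0) {
    p <- arrange(pairs, .data$i)
    # helix runs: consecutive pairs (i+1, j-1)
    run_id <- cumsum(c(1L, !(diff(p$i) == 1L & diff(p$j) == -1L)))
    runs <- split(seq_len(nrow(p)), run_id)
    for (r in runs) {
      touches <- any(p$i[r] %in% el_pos) || any(p$j[r] %in% el_pos)
      if (touches) max_helix <- max(max_helix, length(r))
    }
  }
  list(paired_fraction = paired_fraction,
       stem = paired_fraction >= 0.5 && max_helix >= min_stem,
       max_element_helix = max_helix)
}

#' Classify an Frpo candidate into similarity tiers
#'
#' * `frpo`: the region has a homology hit to a known Frpo/ssi sequence;
#' * `frpo_prime`: no homology, but consensus elements with at most 2
#'   total mismatches plus hairpin stem evidence;
#' * `frpo_star`: elements with at most 4 total mismatches plus stem
#'   evidence (low-certainty candidate);
#' * `none` otherwise.
#'
#' @param has_homology Logical: region has a qualifying known-Frpo hit.
#' @param element_hit Best element hit (one row of
#'   [scan_sigma70_elements()] output) or `NULL`.
#' @param hairpin Result of [hairpin_evidence()] for that hit, or `NULL`.
#' @param max_mm_prime,max_mm_star Total-mismatch budgets for the two
#'   de novo tiers (defaults 2 and 4).
#' @return One of `"frpo", "frpo_prime", "frpo_star", "none"`.
#' @export
classify_candidate <- function(has_homology, element_hit = NULL,
                               hairpin = NULL, max_mm_prime = 2,
                               max_mm_star = 4) {
  if (isTRUE(has_homology)) return("frpo")
  if (is.null(element_hit) || nrow(element_hit) == 0 || is.null(hairpin)) {
    return("none")
  }
  total <- element_hit$total_mm[1]
  if (!isTRUE(hairpin$stem)) return("none")
  if (total <= max_mm_prime) return("frpo_prime")
  if (total <= max_mm_star) return("frpo_star")
  "none"
}

#' Full Frpo scan over regulatory regions
#'
#' Runs homology search, consensus-element scanning, folding and tier
#' classification for each region. For the de novo tiers the element hit
#' with the fewest total mismatches is evaluated (ties: leftmost -35).
#'
#' @param regions Tibble from [extract_upstream_regions()].
#' @param known_frpo Named known Frpo/ssi sequences (or `NULL` to skip
#'   homology).
#' @param scheme A [scoring_scheme()] for the homology search.
#' @param max_mm35,max_mm10,spacer,up_window See [scan_sigma70_elements()].
#' @param min_loop,min_stem See [max_basepairs()] and [hairpin_evidence()].
#' @param max_mm_prime,max_mm_star See [classify_candidate()].
#' @return `regions` with columns `frpo_query, frpo_score, frpo_identity,
#'   minus35_offset, minus10_offset, mm35, mm10, total_mm, spacer_len,
#'   up_at_fraction, paired_fraction, stem, tier, dotbracket`, of class
#'   `pl_frpo`.
#' @export
scan_frpo <- function(regions, known_frpo = NULL,
                      scheme = scoring_scheme(), max_mm35 = 2, max_mm10 = 2,
                      spacer = c(15, 19), up_window = 20, min_loop = 3,
                      min_stem = 10, max_mm_prime = 2, max_mm_star = 4) {
  if (!is.null(known_frpo) && length(known_frpo) > 0) {
    regions <- homology_scan(regions, known_frpo, scheme)
  } else {
    regions <- regions |>
      mutate(frpo_query = NA_character_, frpo_score = NA_integer_,
             frpo_identity = NA_real_)
  }
  extra <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    seq_i <- regions$sequence[i]
    elements <- scan_sigma70_elements(seq_i, max_mm35, max_mm10, spacer,
                                      up_window)
    out <- tibble(minus35_offset = NA_integer_, minus10_offset = NA_integer_,
                  mm35 = NA_integer_, mm10 = NA_integer_,
                  total_mm = NA_integer_, spacer_len = NA_integer_,
                  up_at_fraction = NA_real_, paired_fraction = NA_real_,
                  stem = FALSE, dotbracket = NA_character_)
    hairpin <- NULL
    best <- NULL
    if (nrow(elements) > 0) {
      best <- slice(elements, 1)
      str <- max_basepairs(seq_i, min_loop)
      hairpin <- hairpin_evidence(best, str, min_stem)
      out <- tibble(minus35_offset = best$minus35_offset,
                    minus10_offset = best$minus10_offset,
                    mm35 = best$mm35, mm10 = best$mm10,
                    total_mm = best$total_mm, spacer_len = best$spacer,
                    up_at_fraction = best$up_at_fraction,
                    paired_fraction = hairpin$paired_fraction,
                    stem = hairpin$stem, dotbracket = str$dotbracket)
    }
    out$tier <- classify_candidate(!is.na(regions$frpo_query[i]), best,
                                   hairpin, max_mm_prime, max_mm_star)
    out
  })
  structure(bind_cols(regions, extra),
            class = c("pl_frpo", class(regions)))
}
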