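#' Scoring scheme for the short-word nucleotide aligner
#'
#' Defaults follow the standard short-query nucleotide search
#' parameterisation (match +1, mismatch -3, gap open -5, gap extend -2,
#' word size 5). Hits are filtered on raw alignment score rather than an
#' e-value model; the default `min_score = 20` corresponds roughly to a
#' 20 nt exact match.
#'
#' @param match,mismatch Per-base match reward (positive) and mismatch
#'   penalty (negative).
#' @param gap_open,gap_extend Gap penalties (negative); a gap of length L
#'   scores `gap_open + L * gap_extend`.
#' @param word_size Exact-match seed length (>= 4).
#' @param min_score Minimum raw score for a reported hit.
#' @param band Half-width of the extension band around a seeded diagonal.
#' @return A list of class `pl_scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -3, gap_open = -5,
                           gap_extend = -2, word_size = 5, min_score = 20,
                           band = 20) {
  if (word_size < 4) abort("word_size must be >= 4")
  if (match <= 0) abort("match reward must be positive")
  if (any(c(mismatch, gap_open, gap_extend) >= 0)) {
    abort("mismatch and gap penalties must be negative")
  }
  structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         word_size = as.integer(word_size), min_score = as.integer(min_score),
         band = as.integer(band)),
    class = "pl_scoring_scheme")
}

as_plain_seq <- function(x, what = "sequence") {
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x)) abort(sprintf("%s must be a character string", what))
  toupper(x)
}

#' Reverse complement of a DNA string
#'
#' @param x A character string over `A,C,G,T,N`.
#' @return The reverse complement (character).
#' @export
revcomp <- function(x) {
  vapply(as_plain_seq(x), cpp_revcomp, character(1), USE.NAMES = FALSE)
}

#' Build an exact-word index of a subject sequence
#'
#' Indexes every `word_size`-mer occurrence on both strands of the
#' subject. Words containing `N` are skipped. Minus-strand entries record
#' the position on the plus-strand reference where the reverse complement
#' of the word occurs.
#'
#' @param subject Subject sequence (character or `DNAString`).
#' @param word_size Word length.
#' @return A tibble `word, start, strand` of class `pl_word_index`;
#'   query it with [lookup_word()].
#' @export
build_word_index <- function(subject, word_size = 5) {
  subject <- as_plain_seq(subject, "subject")
  n <- nchar(subject)
  out <- tibble(word = character(), start = integer(), strand = character())
  if (n >= word_size) {
    starts <- seq_len(n - word_size + 1) - 1L
    words <- substring(subject, starts + 1L, starts + word_size)
    ok <- !grepl("[^ACGT]", words)
    fwd <- tibble(word = words[ok], start = starts[ok], strand = "+")
    rev <- tibble(word = revcomp(words[ok]), start = starts[ok], strand = "-")
    out <- bind_rows(fwd, rev)
  }
  structure(out, class = c("pl_word_index", class(out)))
}

#' @rdname build_word_index
#' @param index A `pl_word_index`.
#' @param word Word to look up (same length as the index word size).
#' @export
lookup_word <- function(index, word) {
  filter(index, .data$word == toupper(.env$word))
}

#' Exact local alignment (test oracle)
#'
#' Full Smith-Waterman dynamic programming with affine gaps under the
#' given scoring scheme; exact optimum, quadratic time and memory, so the
#' product of the sequence lengths is capped at 1e6.
#'
#' @param a,b Sequences (character or `DNAString`).
#' @param scheme A [scoring_scheme()].
#' @return A list: `score`, `a_start`, `a_end`, `b_start`, `b_end`
#'   (0-based half-open), `aligned_length`, `matches`.
#' @export
local_align_oracle <- function(a, b, scheme = scoring_scheme()) {
  a <- as_plain_seq(a, "a"); b <- as_plain_seq(b, "b")
  if (as.double(nchar(a)) * nchar(b) > 1e6) {
    abort("local_align_oracle: |a| * |b| exceeds the 1e6-cell cap")
  }
  cpp_local_align(a, b, scheme$match, scheme$mismatch,
                  -scheme$gap_open, -scheme$gap_extend)
}

#' Seeded local nucleotide search
#'
#' Word-seeded local alignment of a short query against a subject
#' sequence, on both strands. Exact `word_size`-mer seeds are grouped by
#' diagonal; each seeded diagonal band is extended by a banded local
#' alignment of the query against the subject window around the diagonal,
#' and overlapping hits are merged keeping the best score. Hits scoring
#' below `scheme$min_score` are dropped.
#'
#' @param query,subject Sequences (character or `DNAString`).
#' @param scheme A [scoring_scheme()].
#' @param query_id,subject_id Ids carried into the output.
#' @return A tibble of hits: `query_id, subject_id, q_start, q_end,
#'   s_start, s_end` (0-based half-open, subject coordinates always on the
#'   plus strand), `strand, raw_score, percent_identity, aligned_length`,
#'   sorted by decreasing score.
#' @export
seed_and_extend <- function(query, subject, scheme = scoring_scheme(),
                            query_id = "query", subject_id = "subject") {
  query <- as_plain_seq(query, "query")
  subject <- as_plain_seq(subject, "subject")
  if (nchar(query) == 0 || nchar(subject) == 0) {
    abort("query and subject must be non-empty")
  }
  one_strand <- function(q, strand) {
    df <- cpp_seed_extend_strand(q, subject, scheme$word_size, scheme$match,
                                 scheme$mismatch, -scheme$gap_open,
                                 -scheme$gap_extend, scheme$band,
                                 scheme$min_score)
    df <- as_tibble(df)
    if (nrow(df) == 0) return(df)
    df$strand <- strand
    if (strand == "-") {
      # query was reverse-complemented: map query coords back
      n <- nchar(q)
      qs <- n - df$q_end
      qe <- n - df$q_start
      df$q_start <- qs
      df$q_end <- qe
    }
    df
  }
  hits <- bind_rows(one_strand(query, "+"),
                    one_strand(revcomp(query), "-"))
  if (nrow(hits) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  strand = character(), raw_score = integer(),
                  percent_identity = double(), aligned_length = integer()))
  }
  hits |>
    mutate(query_id = query_id, subject_id = subject_id,
           percent_identity = 100 * .data$matches / .data$aligned_length) |>
    select("query_id", "subject_id", "q_start", "q_end", "s_start", "s_end",
           "strand", "raw_score", "percent_identity", "aligned_length") |>
    arrange(desc(.data$raw_score), .data$s_start)
}

#' Search a set of queries against a set of subjects
#'
#' Convenience wrapper running [seed_and_extend()] for every query/subject
#' pair; output rows are blast6-compatible in content so downstream
#' modules are agnostic to internal vs external search.
#'
#' @param queries,subjects Named character vectors or `DNAStringSet`s.
#' @param scheme A [scoring_scheme()].
#' @return A tibble of hits (see [seed_and_extend()]) with an `e_value`
#'   column fixed at `NA` and `bit_score = NA` (scoring here is by raw
#'   score).
#' @export
search_sequences <- function(queries, subjects, scheme = scoring_scheme()) {
  queries <- setNames(as.character(queries), names(queries))
  subjects <- setNames(as.character(subjects), names(subjects))
  if (is.null(names(queries)) || is.null(names(subjects))) {
    abort("queries and subjects must be named")
  }
  grid <- tidyr::expand_grid(query_id = names(queries),
                             subject_id = names(subjects))
  purrr::pmap_dfr(grid, function(query_id, subject_id) {
    seed_and_extend(queries[[query_id]], subjects[[subject_id]], scheme,
                    query_id = query_id, subject_id = subject_id)
  }) |>
    mutate(bit_score = NA_real_, e_value = NA_real_)
}

#' Write search hits as a blast6-compatible TSV
#'
#' @param hits Hit tibble from [search_sequences()] / [seed_and_extend()].
#' @param path Output path.
#' @return `path`, invisibly. Coordinates are written 1-based inclusive
#'   with minus-strand subject intervals reversed, per the blast6
#'   convention; the raw score is written in the bitscore column.
#' @export
write_blast6 <- function(hits, path) {
  score <- dplyr::coalesce(hits$bit_score, as.double(hits$raw_score))
  out <- tibble(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = round(hits$percent_identity, 3),
    length = hits$aligned_length,
    mismatch = hits$aligned_length -
      as.integer(round(hits$aligned_length * hits$percent_identity / 100)),
    gapopen = 0L,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = ifelse(hits$strand == "-", hits$s_end, hits$s_start + 1L),
    send = ifelse(hits$strand == "-", hits$s_start + 1L, hits$s_end),
    evalue = dplyr::coalesce(hits$e_value, 0),
    bitscore = score
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
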