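#' Read gene annotations from GFF3 or the internal gene table
#'
#' Parses per-contig ORF annotations into the package's canonical gene
#' table. Coordinates are converted to 0-based half-open intervals on the
#' plus-strand reference (GFF3 files are 1-based closed). Genes are sorted
#' by start (ties broken by end, then gene id) and given a 0-based
#' `ordinal` rank within each contig.
#'
#' @param path Path to a `.gff`/`.gff3` file, or a TSV with header columns
#'   `contig_id, gene_id, start, end, strand` (0-based half-open, the
#'   package's internal dialect; optional extra columns are carried along).
#' @param contig_id Optional single contig id; other contigs are dropped.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A tibble with columns `contig_id, gene_id, start, end, strand,
#'   ordinal` (plus any extra TSV columns such as `category`).
#' @export
read_gene_annotations <- function(path, contig_id = NULL,
                                  format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    genes <- read_genes_gff3(path)
  } else {
    genes <- read_genes_tsv(path)
  }
  if (!is.null(contig_id)) {
    genes <- filter(genes, .data$contig_id %in% .env$contig_id)
  }
  if (nrow(genes) == 0) {
    warn(sprintf("no gene records read from '%s'", path))
  }
  validate_gene_intervals(genes)
  assign_ordinals(genes)
}

read_genes_gff3 <- function(path) {
  # light pre-validation so malformed lines are reported with a line number
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^(#|\\s*$)", lines))
  for (ln in body) {
    nf <- length(strsplit(lines[ln], "\t", fixed = TRUE)[[1]])
    if (nf < 8) {
      abort(sprintf("malformed GFF3 line %d in '%s': %d fields (expected 9)",
                    ln, path, nf))
    }
  }
  if (length(body) == 0) {
    return(tibble(contig_id = character(), gene_id = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  keep_types <- c("CDS", "gene", "ORF")
  if (length(gr) > 0 && "type" %in% names(S4Vectors::mcols(gr))) {
    typed <- gr[as.character(gr$type) %in% keep_types]
    if (length(typed) > 0) gr <- typed
  }
  meta <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(meta) && !all(is.na(meta$ID))) {
    as.character(meta$ID)
  } else if ("Name" %in% names(meta)) {
    as.character(meta$Name)
  } else {
    sprintf("gene_%06d", seq_along(gr))
  }
  tibble(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = ids,
    start = GenomicRanges::start(gr) - 1L,  # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

read_genes_tsv <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("contig_id", "gene_id", "start", "end", "strand")
  missing_cols <- setdiff(req, names(tb))
  if (length(missing_cols) > 0) {
    abort(sprintf("gene table '%s' lacks required columns: %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  mutate(tb,
         contig_id = as.character(.data$contig_id),
         gene_id = as.character(.data$gene_id),
         start = as.integer(.data$start),
         end = as.integer(.data$end))
}

validate_gene_intervals <- function(genes) {
  if (nrow(genes) == 0) return(invisible(genes))
  assert_strand(genes$strand, "gene strand")
  bad <- which(!(genes$start >= 0 & genes$end > genes$start))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid gene interval(s): %s",
      paste(sprintf("%s [%d,%d)", genes$gene_id[bad], genes$start[bad],
                    genes$end[bad])[seq_len(min(3, length(bad)))],
            collapse = "; ")))
  }
  invisible(genes)
}

assign_ordinals <- function(genes) {
  genes |>
    arrange(.data$contig_id, .data$start, .data$end, .data$gene_id) |>
    group_by(.data$contig_id) |>
    mutate(ordinal = row_number() - 1L) |>
    ungroup()
}

#' Read homology hit tables (BLAST outfmt 6 or HMMER tblout)
#'
#' Hits with an e-value above `e_threshold` (default `1e-6`, the search
#' threshold used throughout the pipeline) are dropped; the number dropped
#' is reported as a message. BLAST subject coordinates are normalised to
#' 0-based half-open intervals with an explicit strand (a subject start
#' greater than the end denotes a minus-strand hit). HMMER tblout rows are
#' protein-level hits keyed by gene id and carry no subject interval; the
#' full-sequence e-value and score columns are used.
#'
#' @param path Path to the tabular file.
#' @param kind `"blast6"` (12 standard columns, no header) or
#'   `"hmm_tblout"` (HMMER3 `--tblout`).
#' @param e_threshold Hits with `e_value` strictly above this are dropped.
#' @return A tibble with columns `query_id, subject_id, s_start, s_end,
#'   strand, percent_identity, aligned_length, bit_score, e_value`
#'   (interval columns are `NA` for tblout hits).
#' @export
read_homology_hits <- function(path, kind = c("blast6", "hmm_tblout"),
                               e_threshold = 1e-6) {
  kind <- match.arg(kind)
  hits <- if (kind == "blast6") read_blast6(path) else read_tblout(path)
  n0 <- nrow(hits)
  hits <- filter(hits, .data$e_value <= e_threshold)
  if (n0 > nrow(hits)) {
    inform(sprintf("dropped %d/%d hits with e-value > %g",
                   n0 - nrow(hits), n0, e_threshold))
  }
  hits
}

read_blast6 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tb <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                        progress = FALSE,
                        col_types = "ccdiiiiiiidd")
  probs <- readr::problems(tb)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed blast6 line %d in '%s'", probs$row[1], path))
  }
  if (nrow(tb) == 0) {
    return(empty_hits())
  }
  minus <- tb$sstart > tb$send
  tibble(
    query_id = tb$qseqid,
    subject_id = tb$sseqid,
    s_start = as.integer(ifelse(minus, tb$send, tb$sstart)) - 1L,
    s_end = as.integer(ifelse(minus, tb$sstart, tb$send)),
    strand = ifelse(minus, "-", "+"),
    percent_identity = tb$pident,
    aligned_length = tb$length,
    bit_score = tb$bitscore,
    e_value = tb$evalue
  )
}

read_tblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_hits())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 6) {
      abort(sprintf("malformed tblout line %d in '%s': %d fields",
                    i, path, length(f)))
    }
    # tblout: target, t-acc, query, q-acc, full E-value, full score, ...
    tibble(query_id = f[3], subject_id = f[1],
           e_value = as.numeric(f[5]), bit_score = as.numeric(f[6]))
  })
  bind_rows(rows) |>
    mutate(s_start = NA_integer_, s_end = NA_integer_, strand = NA_character_,
           percent_identity = NA_real_, aligned_length = NA_integer_) |>
    select("query_id", "subject_id", "s_start", "s_end", "strand",
           "percent_identity", "aligned_length", "bit_score", "e_value")
}

empty_hits <- function() {
  tibble(query_id = character(), subject_id = character(),
         s_start = integer(), s_end = integer(), strand = character(),
         percent_identity = double(), aligned_length = integer(),
         bit_score = double(), e_value = double())
}

#' Read a profile-to-category map
#'
#' @param path TSV with header columns `profile_id, category`.
#' @return A tibble validated so each profile maps to exactly one category.
#' @export
read_category_map <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_category_map(tb)
}

validate_category_map <- function(map) {
  req <- c("profile_id", "category")
  if (!all(req %in% names(map))) {
    abort("category map needs columns profile_id, category")
  }
  dup <- map |> count(.data$profile_id) |> filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("profile(s) mapped to more than one category: %s",
                  paste(head(dup$profile_id, 3), collapse = ", ")))
  }
  unknown <- setdiff(unique(map$category), PL_CATEGORIES)
  if (length(unknown) > 0) {
    abort(sprintf("unknown categor%s in map: %s",
                  if (length(unknown) > 1) "ies" else "y",
                  paste(unknown, collapse = ", ")))
  }
  as_tibble(map[c("profile_id", "category")])
}

#' Assign a functional category to each gene from its homology hits
#'
#' Each gene receives the category of its best-scoring qualifying hit;
#' conflicts are resolved by highest bit score, then lowest e-value, then
#' lexicographically smallest profile id. Genes without hits are labelled
#' `uncharacterized`. Protein-level hits are keyed by gene id; nucleotide
#' hits (those carrying a subject interval on a contig) are attributed to
#' the gene whose interval overlaps the hit most.
#'
#' @param genes Gene table (see [read_gene_annotations()]).
#' @param hits Hit table (see [read_homology_hits()]).
#' @param category_map Tibble `profile_id, category` ([read_category_map()]).
#' @return `genes` with a `category` column.
#' @export
assign_categories <- function(genes, hits, category_map) {
  category_map <- validate_category_map(category_map)
  hits <- left_join(hits, category_map,
                    by = c(query_id = "profile_id"))
  unmapped <- filter(hits, is.na(.data$category))
  if (nrow(unmapped) > 0) {
    warn(sprintf("skipping %d hit(s) with profiles absent from category map",
                 nrow(unmapped)))
    hits <- filter(hits, !is.na(.data$category))
  }
  # nucleotide hits: subject is a contig, attribute to the overlapping gene
  is_nt <- !is.na(hits$s_start) & hits$subject_id %in% genes$contig_id
  nt <- hits[is_nt, ]
  if (nrow(nt) > 0) {
    nt <- purrr::pmap_dfr(nt, function(subject_id, s_start, s_end, ...) {
      g <- genes[genes$contig_id == subject_id, ]
      ov <- pmin(g$end, s_end) - pmax(g$start, s_start)
      if (!any(ov > 0)) return(tibble())
      gi <- which.max(ov)
      tibble(subject_id = g$gene_id[gi], s_start = s_start, s_end = s_end, ...)
    })
  }
  hits <- bind_rows(hits[!is_nt, ], nt)
  unknown <- !hits$subject_id %in% genes$gene_id
  if (any(unknown)) {
    warn(sprintf("skipping %d hit(s) referencing unknown gene ids",
                 sum(unknown)))
    hits <- hits[!unknown, ]
  }
  best <- hits |>
    arrange(.data$subject_id, desc(.data$bit_score), .data$e_value,
            .data$query_id) |>
    distinct(.data$subject_id, .keep_all = TRUE) |>
    select(gene_id = "subject_id", "category")
  genes$category <- NULL
  genes |>
    left_join(best, by = "gene_id") |>
    mutate(category = dplyr::coalesce(.data$category, "uncharacterized"))
}

#' Write / read the internal gene table
#'
#' The internal dialect is a TSV with header `contig_id, gene_id, start,
#' end, strand, ordinal` plus any extra columns (e.g. `category`);
#' coordinates 0-based half-open. Writing then reading reproduces the
#' table exactly.
#'
#' @param genes Gene table.
#' @param path Output path.
#' @return `write_gene_table()` returns `path` invisibly;
#'   `read_gene_table()` returns the tibble.
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  tb <- read_genes_tsv(path)
  validate_gene_intervals(tb)
  if (!"ordinal" %in% names(tb)) tb <- assign_ordinals(tb)
  tb
}

#' Read an ORF cluster-membership table
#'
#' @param path TSV with header columns `gene_id, cluster_id` (CD-HIT
#'   `.clstr` converted form / MMseqs2 cluster TSV compatible).
#' @return Tibble `gene_id, cluster_id`.
#' @export
read_cluster_membership <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "cluster_id") %in% names(tb))) {
    abort("membership table needs columns gene_id, cluster_id")
  }
  mutate(as_tibble(tb[c("gene_id", "cluster_id")]),
         gene_id = as.character(.data$gene_id),
         cluster_id = as.character(.data$cluster_id))
}
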