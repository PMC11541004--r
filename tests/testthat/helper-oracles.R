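# Independent oracles used across the suite. Each one recomputes a
# quantity by a route separate from the package implementation
# (enumeration, naive definitions, direct summation).

# Hypergeometric upper-tail by direct log-binomial summation.
hyper_tail_oracle <- function(k, K, n, N) {
  lo <- max(0, n + K - N)
  hi <- min(K, n)
  if (k > hi) return(0)
  ks <- max(k, lo):hi
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Naive Benjamini-Hochberg step-up applied from the definition: find the
# largest i with p_(i) <= i/m * alpha, reject the i smallest p-values.
bh_reject_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  thr <- (seq_len(m) / m) * alpha
  imax <- suppressWarnings(max(which(ps <= thr)))
  reject <- rep(FALSE, m)
  if (is.finite(imax)) reject[ord[seq_len(imax)]] <- TRUE
  reject
}

# Exhaustive base-pair maximization by recursive enumeration over all
# non-crossing structures (right-end recursion, no shared code with the
# package's DP).
can_pair_oracle <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

nussinov_oracle <- function(seq, min_loop = 3) {
  chars <- strsplit(toupper(seq), "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i, j - 1)  # j unpaired
    for (l in i:(j - min_loop - 1)) {
      if (can_pair_oracle(chars[l], chars[j])) {
        inner <- if (l > i) rec(i, l - 1) else 0L
        best <- max(best, 1L + inner + rec(l + 1, j - 1))
      }
    }
    best
  }
  n <- length(chars)
  if (n < min_loop + 2) return(0L)
  rec(1, n)
}

# Brute-force island delineation: all maximal valid qualifying-gene
# segments (no umu-like gene inside, internal non-qualifying runs
# <= max_gap, first member at a leading position <= leading_end,
# >= min_members qualifying members).
islands_oracle <- function(pos, category, qualifying, max_gap = 2,
                           min_members = 3, leading_end = 27) {
  ord <- order(pos)
  pos <- pos[ord]; category <- category[ord]
  qual_idx <- which(category %in% qualifying)
  valid_segment <- function(a, b) {
    # a, b indices into qual_idx
    i0 <- qual_idx[a]; i1 <- qual_idx[b]
    if (pos[qual_idx[a]] > leading_end) return(FALSE)
    seg <- i0:i1
    if (any(category[seg] == "umu_like")) return(FALSE)
    # runs of non-qualifying genes between consecutive members
    gaps <- diff(qual_idx[a:b]) - 1L
    all(gaps <= max_gap)
  }
  segs <- list()
  if (length(qual_idx) > 0) {
    for (a in seq_along(qual_idx)) {
      for (b in a:length(qual_idx)) {
        if (valid_segment(a, b)) {
          segs[[length(segs) + 1]] <- c(a, b)
        }
      }
    }
  }
  # keep maximal segments only
  maximal <- Filter(function(s) {
    !any(vapply(segs, function(t) {
      (t[1] < s[1] && t[2] >= s[2]) || (t[1] <= s[1] && t[2] > s[2])
    }, logical(1)))
  }, segs)
  out <- lapply(maximal, function(s) qual_idx[s[1]:s[2]])
  out <- Filter(function(m) length(m) >= min_members, out)
  lapply(out, function(m) pos[m])
}

# Pairwise shared-fraction matrix computed straight from the definition.
shared_fraction_oracle <- function(cluster_list) {
  ids <- names(cluster_list)
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      a <- cluster_list[[i]]; b <- cluster_list[[j]]
      shared <- 0
      bb <- b
      for (x in a) {
        hit <- match(x, bb)
        if (!is.na(hit)) { shared <- shared + 1; bb <- bb[-hit] }
      }
      m[i, j] <- shared / min(length(a), length(b))
    }
  }
  m
}

# Small deterministic gene/geometry fixture builders -----------------------

make_genes <- function(contig_id, starts, ends, strands,
                       ids = sprintf("%s_g%02d", contig_id,
                                     seq_along(starts))) {
  tibble::tibble(contig_id = contig_id, gene_id = ids, start = starts,
                 end = ends, strand = strands) |>
    plasmidlead:::assign_ordinals()
}

protein_hit <- function(query, gene, bit = 100, e = 1e-20) {
  tibble::tibble(query_id = query, subject_id = gene,
                 s_start = NA_integer_, s_end = NA_integer_,
                 strand = NA_character_, percent_identity = NA_real_,
                 aligned_length = NA_integer_, bit_score = bit, e_value = e)
}

orit_hit <- function(contig, s_start, s_end, bit = 150, e = 1e-30,
                     query = "oriT_q") {
  tibble::tibble(query_id = query, subject_id = contig,
                 s_start = s_start, s_end = s_end, strand = "+",
                 percent_identity = 99, aligned_length = s_end - s_start,
                 bit_score = bit, e_value = e)
}

# geometry for a toy contig directly from explicit positions
toy_geometry <- function(pos, category,
                         t_strand = rep(TRUE, length(pos)),
                         contig = "c1") {
  tibble::tibble(
    contig_id = contig,
    gene_id = sprintf("%s_g%02d", contig, seq_along(pos)),
    start = (seq_along(pos) - 1L) * 1000L,
    end = (seq_along(pos) - 1L) * 1000L + 900L,
    strand = ifelse(t_strand, "-", "+"),
    ordinal = seq_along(pos) - 1L,
    category = category,
    leading_direction = 1L,
    relative_position = as.integer(pos),
    t_strand_expressible = t_strand,
    is_relaxase = FALSE)
}

# reverse-complement transform of a whole simulated fixture contig
mirror_fixture <- function(sim) {
  lens <- setNames(sim$truth$contigs$contig_length,
                   sim$truth$contigs$contig_id)
  genes <- sim$genes |>
    dplyr::mutate(L = lens[.data$contig_id],
                  new_start = .data$L - .data$end,
                  new_end = .data$L - .data$start,
                  start = as.integer(.data$new_start),
                  end = as.integer(.data$new_end),
                  strand = ifelse(.data$strand == "+", "-", "+")) |>
    dplyr::select(-"L", -"new_start", -"new_end") |>
    plasmidlead:::assign_ordinals()
  orit <- sim$hits$orit |>
    dplyr::mutate(L = lens[.data$subject_id],
                  new_start = .data$L - .data$s_end,
                  s_end = as.integer(.data$L - .data$s_start),
                  s_start = as.integer(.data$new_start)) |>
    dplyr::select(-"L", -"new_start")
  list(genes = genes, orit = orit)
}
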