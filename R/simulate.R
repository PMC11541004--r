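#' Simulation configuration
#'
#' Defines the conditions the simulator emulates: contigs carrying a
#' relaxase ORF adjacent to a planted oriT, ORFs with strand and category
#' labels showing configurable leading-region enrichment of anti-defence
#' genes, optional redundant contig groups, planted anti-defence islands
#' terminated by umu-like operons, and intergenic Frpo-like elements.
#'
#' @param n_contigs Number of contigs.
#' @param genes_per_contig Inclusive range of ORFs per contig.
#' @param gene_len,intergenic_len Inclusive ranges (nt).
#' @param leading_freq Anti-defence frequency at `enriched_positions`.
#' @param background_freq Anti-defence frequency elsewhere.
#' @param enriched_positions Leading positions carrying the enrichment
#'   (default `0:9`).
#' @param t_strand_prob Probability an anti-defence gene is placed in the
#'   T-strand-expressible orientation (default 1).
#' @param island_prob Per-contig probability of a planted anti-defence
#'   island starting at position 0, terminated by a umu-like operon.
#' @param island_size Inclusive range of island gene counts.
#' @param frpo_prob Per-contig probability of a planted Frpo-like element
#'   in a leading intergenic region.
#' @param frpo_tier Tier targetted by planted elements
#'   (`"frpo_prime"` by default).
#' @param frpo_region_length Length of the planted regulatory region.
#' @param duplicate_groups List `k` (groups), `copies` (contigs per
#'   group including the base) and `mutation_rate` (fraction of copied
#'   ORFs reassigned to fresh clusters).
#' @param orit_mutation Substitution rate applied to the planted oriT
#'   copy.
#' @param mob_weights Named sampling weights over MOB types.
#' @param emit_sequences Emit nucleotide sequences (`TRUE`) or tables
#'   only.
#' @param seed RNG seed (mandatory).
#' @return A list of class `pl_sim_config`.
#' @export
sim_config <- function(n_contigs = 100,
                       genes_per_contig = c(60, 80),
                       gene_len = c(600, 1200),
                       intergenic_len = c(80, 250),
                       leading_freq = 0.2,
                       background_freq = 0.01,
                       enriched_positions = 0:9,
                       t_strand_prob = 1,
                       island_prob = 0.25,
                       island_size = c(3, 6),
                       frpo_prob = 0,
                       frpo_tier = "frpo_prime",
                       frpo_region_length = 160,
                       duplicate_groups = list(k = 0, copies = 3,
                                               mutation_rate = 0),
                       orit_mutation = 0.05,
                       mob_weights = c(MOB_F = 0.3, MOB_P1 = 0.2,
                                       MOB_Q = 0.15, MOB_V = 0.1,
                                       MOB_H = 0.1, MOB_B = 0.05,
                                       MOB_T = 0.04, MOB_P2 = 0.03,
                                       MOB_C = 0.03),
                       emit_sequences = TRUE,
                       seed = NULL) {
  cfg <- as.list(environment())
  if (is.null(seed)) abort("sim_config: a seed is mandatory")
  freqs <- c(leading_freq, background_freq, t_strand_prob, island_prob,
             frpo_prob)
  if (any(freqs < 0 | freqs > 1)) abort("frequencies must lie in [0, 1]")
  if (genes_per_contig[1] < 8) {
    abort("contigs need at least 8 genes for a workable geometry")
  }
  structure(cfg, class = "pl_sim_config")
}

# bundled synthetic query sets -------------------------------------------

#' Bundled synthetic query sequences and category map
#'
#' Stand-in oriT and known-Frpo/ssi query sets (synthetic sequences, not
#' the external databases) plus the profile-to-category map used by the
#' simulator's hit tables.
#'
#' @return Named character vectors / a tibble.
#' @export
synthetic_orit_queries <- function() {
  fa <- system.file("extdata", "synthetic_orit_queries.fasta",
                    package = "plasmidlead", mustWork = TRUE)
  x <- Biostrings::readDNAStringSet(fa)
  setNames(as.character(x), names(x))
}

#' @rdname synthetic_orit_queries
#' @export
synthetic_frpo_queries <- function() {
  fa <- system.file("extdata", "synthetic_frpo_known.fasta",
                    package = "plasmidlead", mustWork = TRUE)
  x <- Biostrings::readDNAStringSet(fa)
  setNames(as.character(x), names(x))
}

#' @rdname synthetic_orit_queries
#' @export
default_category_map <- function() {
  read_category_map(system.file("extdata", "category_map.tsv",
                                package = "plasmidlead", mustWork = TRUE))
}

random_dna <- function(n, at = 0.5) {
  if (n <= 0) return("")
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

mutate_hexamer <- function(consensus, n_mm) {
  chars <- strsplit(consensus, "")[[1]]
  if (n_mm > 0) {
    idx <- sample(6, n_mm)
    chars[idx] <- vapply(chars[idx], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Dinucleotide shuffle
#'
#' Random permutation of a sequence preserving its dinucleotide counts
#' (Altschul-Erickson Eulerian-path shuffle). Used for null controls in
#' promoter scanning.
#'
#' @param seq DNA string.
#' @return A shuffled DNA string of the same length.
#' @export
dinuc_shuffle <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (n <= 2) return(seq)
  verts <- unique(chars)
  # adjacency lists of the dinucleotide multigraph
  adj <- split(chars[-1], chars[-n])
  last <- chars[n]
  for (attempt in seq_len(1000)) {
    # pick a random last edge for every non-terminal vertex, check the
    # last-edge graph leads every vertex to the terminal one
    lasts <- vapply(verts, function(v) {
      if (v == last) NA_character_
      else if (length(adj[[v]]) == 0) NA_character_
      else sample(adj[[v]], 1)
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(lasts[[v]])) next
      seen <- character()
      cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(lasts[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- lasts[[cur]]
      }
      if (!ok) break
    }
    if (!ok) next
    # shuffle the remaining edges, append the chosen last edge
    out_edges <- lapply(verts, function(v) {
      e <- adj[[v]]
      if (!is.na(lasts[[v]])) {
        drop <- match(lasts[[v]], e)
        e <- e[-drop]
      }
      c(sample(e), if (!is.na(lasts[[v]])) lasts[[v]])
    })
    names(out_edges) <- verts
    ptr <- setNames(rep(1L, length(verts)), verts)
    walk <- character(n)
    walk[1] <- chars[1]
    cur <- chars[1]
    for (i in 2:n) {
      nxt <- out_edges[[cur]][ptr[[cur]]]
      if (is.na(nxt)) break
      ptr[[cur]] <- ptr[[cur]] + 1L
      walk[i] <- nxt
      cur <- nxt
    }
    if (!any(walk == "")) return(paste(walk, collapse = ""))
  }
  abort("dinuc_shuffle failed to find an Eulerian path (degenerate input)")
}

#' Construct a regulatory region with a planted Frpo-like element
#'
#' Emits a region containing an AT-rich UP element, a -35 hexamer, a
#' random spacer, a -10 hexamer, a short loop and a downstream reverse
#' complement of the whole element block, so the elements fold into a
#' perfect stem. `tier_target` controls the consensus mismatches
#' injected: `"frpo_prime"` plants 0-2 total mismatches, `"frpo_star"`
#' 3-4, `"frpo"` plants a mutated copy of a known query, and `"none"`
#' dinucleotide-shuffles the finished region.
#'
#' @param region_length Total region length (>= 120).
#' @param tier_target One of `"frpo"`, `"frpo_prime"`, `"frpo_star"`,
#'   `"none"`.
#' @param known_query Known-Frpo sequence used for `tier_target = "frpo"`.
#' @param seed Optional seed (otherwise uses the current RNG stream).
#' @return A list: `sequence`, `minus35_offset`, `minus10_offset`
#'   (0-based offsets in the region; `NA` for shuffled/homology plants),
#'   `tier_target`.
#' @export
plant_frpo <- function(region_length = 160,
                       tier_target = c("frpo_prime", "frpo_star", "frpo",
                                       "none"),
                       known_query = NULL, seed = NULL) {
  tier_target <- match.arg(tier_target)
  with_rng(seed, {
    if (tier_target == "frpo") {
      if (is.null(known_query)) known_query <- synthetic_frpo_queries()[[1]]
      core <- mutate_seq(known_query, 0.1)
      pad <- region_length - nchar(core)
      if (pad < 0) abort("region_length too short for the known query")
      f5 <- sample(0:pad, 1)
      seq <- paste0(random_dna(f5), core, random_dna(pad - f5))
      return(list(sequence = seq, minus35_offset = NA_integer_,
                  minus10_offset = NA_integer_, tier_target = tier_target))
    }
    total_mm <- switch(tier_target,
                       frpo_prime = sample(0:2, 1),
                       frpo_star = sample(3:4, 1),
                       none = sample(0:2, 1))
    mm35 <- max(0, total_mm - 2):min(2, total_mm)
    mm35 <- if (length(mm35) > 1) sample(mm35, 1) else mm35
    mm10 <- total_mm - mm35
    up <- random_dna(20, at = 0.9)
    m35 <- mutate_hexamer("TTGACA", mm35)
    spacer_len <- sample(15:19, 1)
    spacer <- random_dna(spacer_len)
    m10 <- mutate_hexamer("TATAAT", mm10)
    core <- paste0(up, m35, spacer, m10)
    loop <- random_dna(4)
    stem <- cpp_revcomp(core)
    block <- paste0(core, loop, stem)
    pad <- region_length - nchar(block)
    if (pad < 0) {
      abort("region_length too short for the element block (needs >= 120)")
    }
    f5 <- if (pad > 0) sample(0:pad, 1) else 0L
    seq <- paste0(random_dna(f5), block, random_dna(pad - f5))
    m35_off <- f5 + 20L
    m10_off <- f5 + 20L + 6L + spacer_len
    if (tier_target == "none") {
      seq <- dinuc_shuffle(seq)
      m35_off <- NA_integer_
      m10_off <- NA_integer_
    }
    list(sequence = seq, minus35_offset = m35_off, minus10_offset = m10_off,
         tier_target = tier_target)
  })
}

# one simulated contig (tables only); returns a list of plain vectors
sim_one_contig <- function(cid, cfg, orit_queries) {
  n_genes <- sample(cfg$genes_per_contig[1]:cfg$genes_per_contig[2], 1)
  n_lead <- sample(ceiling(0.4 * n_genes):floor(0.6 * n_genes), 1)
  n_lag <- n_genes - n_lead
  dir <- sample(c(1L, -1L), 1)
  orit_q <- sample(names(orit_queries), 1)
  orit_len <- nchar(orit_queries[[orit_q]])

  # truth relative positions in contig (left-to-right) order
  if (dir == 1L) {
    rel_pos <- c(rev(-seq_len(n_lag)), 0:(n_lead - 1))
    orit_after_gene <- n_lag  # oriT sits after this (1-based) gene
  } else {
    rel_pos <- c(rev(0:(n_lead - 1)), -seq_len(n_lag))
    orit_after_gene <- n_lead
  }
  relaxase_idx <- if (dir == 1L) n_lag else n_lead + 1L

  lens <- sample(cfg$gene_len[1]:cfg$gene_len[2], n_genes, replace = TRUE)
  gaps <- sample(cfg$intergenic_len[1]:cfg$intergenic_len[2], n_genes + 1L,
                 replace = TRUE)

  # categories by truth position
  is_enriched <- rel_pos %in% cfg$enriched_positions
  p_anti <- ifelse(is_enriched, cfg$leading_freq, cfg$background_freq)
  anti <- runif(n_genes) < p_anti
  category <- rep("uncharacterized", n_genes)
  category[anti] <- sample(PL_ANTI_DEFENCE, sum(anti), replace = TRUE,
                           prob = c(0.4, 0.3, 0.3))
  other_draw <- runif(n_genes)
  plain <- !anti
  category[plain & other_draw < 0.02] <- "mobility"
  category[plain & other_draw >= 0.02 & other_draw < 0.03] <- "transposase"
  category[plain & other_draw >= 0.03 & other_draw < 0.10] <- "other"
  planted_island <- FALSE
  island_n <- 0L
  if (runif(1) < cfg$island_prob) {
    planted_island <- TRUE
    island_n <- sample(cfg$island_size[1]:cfg$island_size[2], 1)
    isl_genes <- which(rel_pos >= 0 & rel_pos < island_n)
    umu_genes <- which(rel_pos >= island_n & rel_pos < island_n + 2)
    category[isl_genes] <- sample(PL_ISLAND_QUALIFYING, length(isl_genes),
                                  replace = TRUE)
    category[umu_genes] <- "umu_like"
  }
  category[relaxase_idx] <- "relaxase"

  # gene-family labels (a second, coarser clustering: families recur
  # across contigs, as protein families do; singletons stay NA)
  family <- rep(NA_character_, n_genes)
  categorized <- !category %in% c("uncharacterized")
  family[categorized] <- sprintf("fam_%s_%02d", category[categorized],
                                 sample.int(3, sum(categorized),
                                            replace = TRUE))
  family[category == "relaxase"] <- "fam_relaxase_01"
  unchar <- which(!categorized)
  pooled <- unchar[runif(length(unchar)) < 0.4]
  family[pooled] <- sprintf("fam_unchar_%02d",
                            sample.int(40, length(pooled), replace = TRUE))

  # strands: anti-defence (and island members) on the expressible strand
  expressible_strand <- if (dir == 1L) "-" else "+"
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  forced <- category %in% PL_ANTI_DEFENCE |
    (planted_island & seq_len(n_genes) %in% which(rel_pos >= 0 &
                                                    rel_pos < island_n))
  force_on <- forced & runif(n_genes) < cfg$t_strand_prob
  strand[force_on] <- expressible_strand

  # frpo planting: widen the gap upstream of one early leading gene
  frpo <- NULL
  if (runif(1) < cfg$frpo_prob) {
    cand <- which(rel_pos >= 1 & rel_pos <= 5 & category != "umu_like")
    if (length(cand) > 0) {
      fg <- cand[sample.int(length(cand), 1)]
      el <- plant_frpo(cfg$frpo_region_length, cfg$frpo_tier)
      # the upstream gap of gene fg must hold exactly the planted region;
      # the gene is oriented on the expressible strand so the region is
      # strand-aware below when sequences are emitted
      strand[fg] <- expressible_strand
      frpo <- list(gene_index = fg, element = el)
    }
  }

  # coordinates: genes left to right with the oriT inserted in its gap
  starts <- integer(n_genes); ends <- integer(n_genes)
  orit_start <- NA_integer_
  # which genomic gap holds the frpo region (upstream of gene fg in its
  # coding orientation); gap i sits after gene i-1
  frpo_gap_after <- -1L
  if (!is.null(frpo)) {
    fg <- frpo$gene_index
    frpo_gap_after <- if (strand[fg] == "+") fg - 1L else fg
  }
  pos <- 0L
  for (i in seq_len(n_genes + 1)) {
    gap_i <- gaps[i]
    if (!is.null(frpo) && (i - 1L) == frpo_gap_after) {
      gap_i <- nchar(frpo$element$sequence)
    }
    pos <- pos + gap_i
    if (i == orit_after_gene + 1L) {
      orit_start <- pos
      pos <- pos + orit_len + sample(40:200, 1)
    }
    if (i <= n_genes) {
      starts[i] <- pos
      ends[i] <- pos + lens[i]
      pos <- pos + lens[i]
    }
  }
  contig_len <- pos + gaps[n_genes + 1]

  list(
    contig_id = cid,
    n_genes = n_genes,
    gene_id = sprintf("%s_g%03d", cid, seq_len(n_genes)),
    start = starts, end = ends, strand = strand, category = category,
    family = family, rel_pos = rel_pos, dir = dir,
    relaxase_idx = relaxase_idx,
    orit_q = orit_q, orit_start = orit_start,
    orit_end = orit_start + orit_len,
    contig_len = contig_len,
    planted_island = planted_island, island_n = island_n,
    frpo = frpo, frpo_gap_after = frpo_gap_after
  )
}

#' Simulate contigs with planted ground truth
#'
#' Generates a fully self-contained fixture: gene tables, homology-hit
#' tables (relaxase/TraM tblout-style, per-category tblout-style, oriT
#' blast6-style), an ORF cluster membership, contig metadata with MOB
#' labels, optional nucleotide sequences with the oriT and Frpo elements
#' physically planted, and a truth table for every pipeline stage.
#' Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `pl_sim`: `contigs`, `genes`, `hits`
#'   (`relaxase`, `category`, `orit`), `membership` (dedup clustering),
#'   `families` (a second, coarser clustering into recurring gene
#'   families), `category_map`, `sequences` (named character or `NULL`),
#'   `truth` (`contigs`, `genes`, `duplicates`, `frpo`), `config`.
#' @export
simulate_contigs <- function(config) {
  stopifnot(inherits(config, "pl_sim_config"))
  cfg <- config
  with_rng(cfg$seed, {
    orit_queries <- synthetic_orit_queries()
    cmap <- default_category_map()
    n_base <- cfg$n_contigs
    sims <- lapply(seq_len(n_base), function(i) {
      sim_one_contig(sprintf("ctg%04d", i), cfg, orit_queries)
    })
    mob <- sample(names(cfg$mob_weights), n_base, replace = TRUE,
                  prob = cfg$mob_weights)

    # duplicate groups: clone the first k contigs
    dg <- cfg$duplicate_groups
    dup_truth <- list()
    if (dg$k > 0) {
      if (dg$k > n_base) abort("more duplicate groups than contigs")
      for (g in seq_len(dg$k)) {
        base <- sims[[g]]
        dup_truth[[length(dup_truth) + 1]] <-
          tibble(contig_id = base$contig_id, dup_group = g, is_base = TRUE)
        for (cp in seq_len(dg$copies - 1)) {
          cl <- clone_contig(base, cp, cfg)
          sims[[length(sims) + 1]] <- cl
          mob <- c(mob, mob[g])
          dup_truth[[length(dup_truth) + 1]] <-
            tibble(contig_id = cl$contig_id, dup_group = g, is_base = FALSE)
        }
      }
    }

    genes <- build_gene_table(sims)
    hits <- build_hit_tables(sims, cmap)
    membership <- build_membership(sims, dg)
    fam_id <- unlist(lapply(sims, `[[`, "family"))
    families <- tibble(gene_id = unlist(lapply(sims, `[[`, "gene_id")),
                       family_id = fam_id) |>
      filter(!is.na(.data$family_id))
    sequences <- if (cfg$emit_sequences) build_sequences(sims, orit_queries,
                                                         cfg) else NULL
    truth_contigs <- tibble(
      contig_id = vapply(sims, `[[`, character(1), "contig_id"),
      leading_direction = vapply(sims, `[[`, integer(1), "dir"),
      orit_start = vapply(sims, `[[`, integer(1), "orit_start"),
      orit_end = vapply(sims, `[[`, integer(1), "orit_end"),
      relaxase_gene_id = vapply(sims, function(s) {
        s$gene_id[s$relaxase_idx]
      }, character(1)),
      contig_length = vapply(sims, `[[`, integer(1), "contig_len"),
      planted_island = vapply(sims, `[[`, logical(1), "planted_island"),
      island_size = vapply(sims, `[[`, integer(1), "island_n")
    )
    truth_contigs$mob_type <- mob
    truth_genes <- tibble(
      contig_id = rep(truth_contigs$contig_id,
                      vapply(sims, `[[`, integer(1), "n_genes")),
      gene_id = unlist(lapply(sims, `[[`, "gene_id")),
      true_position = unlist(lapply(sims, `[[`, "rel_pos")),
      true_category = unlist(lapply(sims, `[[`, "category"))
    )
    truth_frpo <- purrr::map_dfr(sims, function(s) {
      if (is.null(s$frpo)) return(tibble())
      tibble(contig_id = s$contig_id,
             gene_id = s$gene_id[s$frpo$gene_index],
             tier_target = s$frpo$element$tier_target,
             region_length = nchar(s$frpo$element$sequence),
             minus35_offset = s$frpo$element$minus35_offset,
             minus10_offset = s$frpo$element$minus10_offset)
    })
    structure(
      list(contigs = truth_contigs |>
             select("contig_id", "contig_length", "mob_type"),
           genes = genes,
           hits = hits,
           membership = membership,
           families = families,
           category_map = cmap,
           sequences = sequences,
           truth = list(contigs = truth_contigs, genes = truth_genes,
                        duplicates = if (length(dup_truth)) {
                          bind_rows(dup_truth)
                        } else {
                          tibble(contig_id = character(),
                                 dup_group = integer(), is_base = logical())
                        },
                        frpo = truth_frpo),
           config = cfg),
      class = "pl_sim")
  })
}

# a duplicate copy: drop the cp outermost leading genes
clone_contig <- function(base, cp, cfg) {
  cl <- base
  cl$contig_id <- sprintf("%s_dup%d", base$contig_id, cp)
  drop_n <- min(cp, base$n_genes - 8L)
  # drop the genes with the highest leading positions
  ord <- order(cl$rel_pos, decreasing = TRUE)
  drop_idx <- ord[seq_len(drop_n)]
  keep <- !(seq_len(cl$n_genes) %in% drop_idx)
  for (f in c("start", "end", "strand", "category", "family", "rel_pos")) {
    cl[[f]] <- cl[[f]][keep]
  }
  cl$n_genes <- sum(keep)
  cl$gene_id <- sprintf("%s_g%03d", cl$contig_id, seq_len(cl$n_genes))
  cl$relaxase_idx <- which(cl$category == "relaxase")[1]
  cl["frpo"] <- list(NULL)  # plain NULL assignment would drop the element
  cl$frpo_gap_after <- -1L
  # remember the base ordinals that survive, for cluster sharing
  cl$base_slots <- which(keep)
  cl$mutated <- runif(cl$n_genes) < cfg$duplicate_groups$mutation_rate
  cl
}

build_gene_table <- function(sims) {
  tibble(
    contig_id = rep(vapply(sims, `[[`, character(1), "contig_id"),
                    vapply(sims, `[[`, integer(1), "n_genes")),
    gene_id = unlist(lapply(sims, `[[`, "gene_id")),
    start = unlist(lapply(sims, `[[`, "start")),
    end = unlist(lapply(sims, `[[`, "end")),
    strand = unlist(lapply(sims, `[[`, "strand"))
  ) |>
    assign_ordinals()
}

build_hit_tables <- function(sims, cmap) {
  protein_tbl <- function(query_id, subject_id, bit, e) {
    tibble(query_id = query_id, subject_id = subject_id,
           s_start = NA_integer_, s_end = NA_integer_,
           strand = NA_character_, percent_identity = NA_real_,
           aligned_length = NA_integer_, bit_score = bit, e_value = e)
  }
  rel <- protein_tbl(
    "hmm_relaxase",
    vapply(sims, function(s) s$gene_id[s$relaxase_idx], character(1)),
    200, 1e-20)
  cat_q <- unlist(lapply(sims, function(s) {
    idx <- !s$category %in% c("uncharacterized", "relaxase")
    sprintf("hmm_%s", s$category[idx])  # sprintf keeps zero-length inputs
  }))
  cat_s <- unlist(lapply(sims, function(s) {
    s$gene_id[!s$category %in% c("uncharacterized", "relaxase")]
  }))
  cat_hits <- protein_tbl(cat_q %||% character(0),
                          cat_s %||% character(0), 100, 1e-15)
  ori_start <- vapply(sims, `[[`, integer(1), "orit_start")
  ori_end <- vapply(sims, `[[`, integer(1), "orit_end")
  ori <- tibble(
    query_id = vapply(sims, `[[`, character(1), "orit_q"),
    subject_id = vapply(sims, `[[`, character(1), "contig_id"),
    s_start = ori_start, s_end = ori_end,
    strand = "+", percent_identity = 98,
    aligned_length = ori_end - ori_start,
    bit_score = 1.8 * (ori_end - ori_start), e_value = 1e-30)
  list(relaxase = rel, category = cat_hits, orit = ori)
}

build_membership <- function(sims, dg) {
  parts <- lapply(sims, function(s) {
    if (!is.null(s$base_slots)) {
      base_id <- sub("_dup\\d+$", "", s$contig_id)
      cl <- sprintf("cl_%s_%03d", base_id, s$base_slots)
      if (any(s$mutated)) {
        cl[s$mutated] <- sprintf("cl_%s_%03d", s$contig_id,
                                 which(s$mutated))
      }
    } else {
      cl <- sprintf("cl_%s_%03d", s$contig_id, seq_len(s$n_genes))
    }
    list(gene_id = s$gene_id, cluster_id = cl)
  })
  tibble(gene_id = unlist(lapply(parts, `[[`, "gene_id")),
         cluster_id = unlist(lapply(parts, `[[`, "cluster_id")))
}

build_sequences <- function(sims, orit_queries, cfg) {
  seqs <- vapply(sims, function(s) {
    chars <- sample(c("A", "C", "G", "T"), s$contig_len, replace = TRUE)
    splice <- function(chars, start0, seq) {
      v <- strsplit(seq, "")[[1]]
      chars[(start0 + 1):(start0 + length(v))] <- v
      chars
    }
    ori_seq <- mutate_seq(orit_queries[[s$orit_q]], cfg$orit_mutation)
    chars <- splice(chars, s$orit_start, ori_seq)
    if (!is.null(s$frpo)) {
      fg <- s$frpo$gene_index
      region <- s$frpo$element$sequence
      genomic <- if (s$strand[fg] == "+") region else cpp_revcomp(region)
      gap_start <- if (s$frpo_gap_after == 0L) 0L else {
        if (s$strand[fg] == "+") s$end[fg - 1L] else s$end[fg]
      }
      # the gap was sized to the region length during layout
      chars <- splice(chars, gap_start, genomic)
    }
    paste(chars, collapse = "")
  }, character(1))
  setNames(seqs, vapply(sims, `[[`, character(1), "contig_id"))
}

#' Simulate a fixture with no positional structure
#'
#' Type-I-error harness: identical category frequency at every position
#' (the background frequency), no planted islands, duplicates or
#' promoter elements, tables only.
#'
#' @param config A [sim_config()]; positional structure fields are
#'   overridden.
#' @return A `pl_sim` (see [simulate_contigs()]).
#' @export
simulate_null <- function(config) {
  cfg <- config
  cfg$leading_freq <- cfg$background_freq
  cfg$enriched_positions <- integer(0)
  cfg$island_prob <- 0
  cfg$frpo_prob <- 0
  cfg$duplicate_groups <- list(k = 0, copies = 0, mutation_rate = 0)
  cfg$emit_sequences <- FALSE
  simulate_contigs(cfg)
}

#' Write a simulated fixture to disk in external dialects
#'
#' Emits the exact dialects the readers consume: `genes.gff3`,
#' `contigs.fasta` (when sequences were simulated), `relaxase.tblout`,
#' `category.tblout`, `orit.blast6.tsv`, `membership.tsv`,
#' `families.tsv`, `category_map.tsv`, `contigs.tsv` (MOB metadata) and
#' `truth.json`.
#'
#' @param sim A `pl_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gff3(sim$genes, p("genes.gff3"))
  write_tblout(sim$hits$relaxase, p("relaxase.tblout"))
  write_tblout(sim$hits$category, p("category.tblout"))
  write_blast6_hits(sim$hits$orit, p("orit.blast6.tsv"))
  readr::write_tsv(sim$membership, p("membership.tsv"), progress = FALSE)
  readr::write_tsv(sim$families, p("families.tsv"), progress = FALSE)
  readr::write_tsv(sim$category_map, p("category_map.tsv"), progress = FALSE)
  readr::write_tsv(sim$contigs, p("contigs.tsv"), progress = FALSE)
  if (!is.null(sim$sequences)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$sequences), p("contigs.fasta"))
  }
  jsonlite::write_json(
    list(contigs = sim$truth$contigs, genes = sim$truth$genes,
         duplicates = sim$truth$duplicates, frpo = sim$truth$frpo),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- "CDS"
  gr$ID <- genes$gene_id
  gr$phase <- 0L
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

write_tblout <- function(hits, path) {
  lines <- c(
    "# target name        accession  query name           accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target",
    sprintf("%-20s -          %-20s -          %9.2g %6.1f   0.0 %9.2g %6.1f   0.0   1.0   1   0   0   1   1   1   1 -",
            hits$subject_id, hits$query_id, hits$e_value, hits$bit_score,
            hits$e_value, hits$bit_score))
  writeLines(lines, path)
  invisible(path)
}

write_blast6_hits <- function(hits, path) {
  out <- tibble(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = hits$percent_identity, length = hits$aligned_length,
    mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = hits$aligned_length,
    sstart = ifelse(hits$strand == "-", hits$s_end, hits$s_start + 1L),
    send = ifelse(hits$strand == "-", hits$s_start + 1L, hits$s_end),
    evalue = hits$e_value, bitscore = hits$bit_score)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
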