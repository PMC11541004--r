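test_that("upstream regions are strand-aware intergenic spans within 50-350 bp", {
  # + strand gene at [1000,2000) with previous feature ending at 800
  geo <- tibble::tibble(
    contig_id = "c1",
    gene_id = c("g1", "g2", "g3"),
    start = c(300L, 1000L, 2100L),
    end = c(800L, 2000L, 2700L),
    strand = c("+", "+", "-"),
    ordinal = 0:2,
    category = "uncharacterized",
    leading_direction = 1L,
    relative_position = c(-1L, 0L, 1L),
    t_strand_expressible = FALSE,
    is_relaxase = c(TRUE, FALSE, FALSE))
  seqs <- c(c1 = paste(rep("ACGT", 725), collapse = ""))  # 2,900 nt
  regions <- extract_upstream_regions(geo, seqs)
  g2 <- regions[regions$gene_id == "g2", ]
  expect_equal(g2$r_start, 800L)
  expect_equal(g2$r_end, 1000L)
  expect_equal(g2$length, 200L)
  # minus-strand gene g3: upstream is [2700, next_start) reverse
  # complemented; next feature is the contig end here
  g3 <- regions[regions$gene_id == "g3", ]
  expect_equal(g3$r_start, 2700L)
  expect_equal(g3$sequence,
               revcomp(substring(seqs[["c1"]], 2701, g3$r_end)))
  # a 40 nt gap is excluded
  geo40 <- geo |> dplyr::mutate(start = c(300L, 840L, 2100L))
  expect_false("g2" %in%
                 extract_upstream_regions(geo40, seqs)$gene_id)
  expect_error(extract_upstream_regions(geo, c(cX = "ACGT")), "c1")
})

test_that("sigma-70 element scan finds consensus pairs with mismatch and spacer accounting", {
  region <- paste0(strrep("AT", 10), "TTGACA", strrep("C", 17), "TATAAT",
                   strrep("G", 10))
  hits <- scan_sigma70_elements(region)
  expect_gte(nrow(hits), 1)
  top <- hits[1, ]
  expect_equal(top$mm35, 0L)
  expect_equal(top$mm10, 0L)
  expect_equal(top$spacer, 17L)
  expect_equal(top$minus35_offset, 20L)
  expect_equal(top$up_at_fraction, 1.0)
  # one substitution in the -10 hexamer
  region2 <- sub("TATAAT", "TACAAT", region)
  top2 <- scan_sigma70_elements(region2)[1, ]
  expect_equal(top2$mm35, 0L)
  expect_equal(top2$mm10, 1L)
  # poly-G has no hits
  expect_equal(nrow(scan_sigma70_elements(strrep("G", 100))), 0)
})

test_that("base-pair maximization matches enumeration on canonical cases", {
  st <- max_basepairs("GGGAAACCC")
  expect_equal(st$n_pairs, 3L)
  expect_equal(st$dotbracket, "(((...)))")
  expect_equal(max_basepairs("AAAAAA")$n_pairs, 0L)
  # a sequence joined to its reverse complement pairs its full length
  set.seed(12)
  s <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  full <- paste0(s, "AAA", revcomp(s))
  expect_gte(max_basepairs(full)$n_pairs, 20L)
  expect_error(max_basepairs(strrep("A", 500)), "cap")
})

test_that("hairpin evidence reports the paired fraction of the element hexamers", {
  el <- plant_frpo(160, "frpo_prime", seed = 41)
  hit <- tibble::tibble(minus35_offset = el$minus35_offset,
                        minus10_offset = el$minus10_offset)
  st <- max_basepairs(el$sequence)
  hp <- hairpin_evidence(hit, st)
  expect_gte(hp$paired_fraction, 0.9)
  expect_true(hp$stem)
  # an element placed in an unpaired context has fraction 0
  st0 <- structure_from_dotbracket(strrep(".", 160))
  hp0 <- hairpin_evidence(hit, st0)
  expect_equal(hp0$paired_fraction, 0)
  expect_false(hp0$stem)
})

test_that("tier classification follows the homology/element/stem rules", {
  expect_equal(classify_candidate(TRUE), "frpo")
  hit1 <- tibble::tibble(total_mm = 2L)
  hit2 <- tibble::tibble(total_mm = 4L)
  stem_yes <- list(stem = TRUE); stem_no <- list(stem = FALSE)
  expect_equal(classify_candidate(FALSE, hit1, stem_yes), "frpo_prime")
  expect_equal(classify_candidate(FALSE, hit2, stem_yes), "frpo_star")
  expect_equal(classify_candidate(FALSE, hit1, stem_no), "none")
  expect_equal(classify_candidate(FALSE, NULL, NULL), "none")
})

test_that("a planted exact known-Frpo copy is recovered by homology at 100% identity", {
  known <- synthetic_frpo_queries()
  region <- tibble::tibble(
    contig_id = "c1", gene_id = "g1", relative_position = 1L,
    r_start = 0L, r_end = 200L, strand = "+", length = 200L,
    sequence = paste0(strrep("C", 30), known[[2]],
                      strrep("T", 200 - 30 - nchar(known[[2]]))))
  out <- homology_scan(region, known)
  expect_equal(out$frpo_query, names(known)[2])
  expect_equal(out$frpo_identity, 100)
  # a mutated copy (~80% identity) is still detected
  set.seed(8)
  mut <- mutate_seq(known[[2]], 0.2)
  region$sequence <- paste0(strrep("C", 30), mut,
                            strrep("T", 200 - 30 - nchar(mut)))
  out2 <- homology_scan(region, known)
  expect_false(is.na(out2$frpo_query))
  sw <- local_align_oracle(known[[out2$frpo_query]], region$sequence)
  expect_gte(sw$score, scoring_scheme()$min_score)
})

test_that("homology tier is invariant to reverse complementing the region", {
  known <- synthetic_frpo_queries()
  set.seed(21)
  base <- plant_frpo(180, "frpo", known_query = known[[1]])
  region <- tibble::tibble(
    contig_id = "c1", gene_id = "g1", relative_position = 1L,
    r_start = 0L, r_end = 180L, strand = "+", length = 180L,
    sequence = base$sequence)
  fwd <- homology_scan(region, known)
  region_rc <- region |> dplyr::mutate(sequence = revcomp(sequence))
  rev <- homology_scan(region_rc, known)
  expect_equal(is.na(fwd$frpo_query), is.na(rev$frpo_query))
  expect_equal(fwd$frpo_score, rev$frpo_score)
})

test_that("planted elements classify at their target tier and shuffles do not", {
  set.seed(55)
  n <- 25
  planted <- replicate(n, plant_frpo(160, "frpo_prime")$sequence)
  shuffled <- vapply(planted, dinuc_shuffle, character(1))
  regions <- tibble::tibble(
    contig_id = "c", gene_id = sprintf("g%02d", seq_len(2 * n)),
    relative_position = 1L, r_start = 0L, r_end = 160L, strand = "+",
    length = 160L, sequence = c(planted, shuffled))
  res <- scan_frpo(regions, known_frpo = NULL)
  tier_planted <- res$tier[seq_len(n)]
  tier_shuffled <- res$tier[n + seq_len(n)]
  expect_gte(mean(tier_planted %in% c("frpo", "frpo_prime")), 0.9)
  expect_lt(mean(tier_shuffled != "none"), 0.1)
})

test_that("dinucleotide shuffles preserve dinucleotide composition", {
  set.seed(31)
  s <- plant_frpo(140, "frpo_prime")$sequence
  dinucs <- function(x) {
    ch <- strsplit(x, "")[[1]]
    sort(paste0(ch[-length(ch)], ch[-1]))
  }
  sh <- dinuc_shuffle(s)
  expect_equal(nchar(sh), nchar(s))
  expect_equal(dinucs(sh), dinucs(s))
  expect_false(sh == s)
})
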