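test_that("local alignment oracle reproduces hand-checked scores", {
  s <- scoring_scheme()
  expect_equal(local_align_oracle("ACGT", "ACGT", s)$score, 4)
  expect_equal(local_align_oracle("AAAA", "TTTT", s)$score, 0)
  # 5x5 DP by hand: best local alignment of ACGTT / ACGAT is the exact
  # 3-mer ACG (a 5-long alignment with one mismatch scores 4 - 3 = 1,
  # gaps cost at least 7)
  expect_equal(local_align_oracle("ACGTT", "ACGAT", s)$score, 3)
  expect_error(local_align_oracle(strrep("A", 2000), strrep("A", 2000), s),
               "cap")
})

test_that("local alignment oracle agrees with an independent aligner on random pairs", {
  s <- scoring_scheme()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                  baseOnly = TRUE)
  set.seed(11)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(local_align_oracle(a, b, s)$score, max(0, ref))
  }
})

test_that("word index covers both strands and skips N words", {
  idx <- build_word_index("ACGTACGT", 5)
  hit <- lookup_word(idx, "ACGTA")
  expect_equal(hit$start[hit$strand == "+"], 0L)
  # TACGT occurs at position 3 on + and its reverse complement (ACGTA)
  # at position 0, recorded as a minus-strand entry
  hit2 <- lookup_word(idx, "TACGT")
  expect_setequal(hit2$start[hit2$strand == "+"], 3L)
  expect_setequal(hit2$start[hit2$strand == "-"], 0L)
  expect_equal(nrow(build_word_index("NNNNN", 5)), 0)
  expect_equal(nrow(build_word_index("ACG", 5)), 0)
})

test_that("a verbatim planted query is found at full identity and score", {
  set.seed(3)
  q <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  subj <- paste0(paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                       collapse = ""), q,
                 paste(sample(c("A", "C", "G", "T"), 150, TRUE),
                       collapse = ""))
  hits <- seed_and_extend(q, subj)
  top <- hits[1, ]
  expect_equal(top$raw_score, 80L)
  expect_equal(top$percent_identity, 100)
  expect_equal(top$s_start, 200L)
  expect_equal(top$s_end, 280L)
  expect_equal(top$strand, "+")
})

test_that("a mutated planted query is recovered with the oracle-optimal score", {
  set.seed(17)
  scheme <- scoring_scheme()
  for (i in 1:10) {
    q <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    mq <- strsplit(q, "")[[1]]
    flip <- sample(100, 20)  # 20% substitutions
    mq[flip] <- vapply(mq[flip], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    planted <- paste(mq, collapse = "")
    subj <- paste0(paste(sample(c("A", "C", "G", "T"), 120, TRUE),
                         collapse = ""), planted,
                   paste(sample(c("A", "C", "G", "T"), 120, TRUE),
                         collapse = ""))
    hits <- seed_and_extend(q, subj, scheme)
    expect_gt(nrow(hits), 0)
    top <- hits[1, ]
    # identical score and query span as the exhaustive oracle alignment
    oracle <- local_align_oracle(q, subj, scheme)
    expect_equal(top$raw_score, oracle$score)
    expect_equal(top$q_start, oracle$a_start)
    expect_equal(top$q_end, oracle$a_end)
  }
})

test_that("unrelated random query/subject pairs rarely produce hits", {
  set.seed(23)
  n_hit <- 0
  for (i in 1:100) {
    q <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    subj <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    if (nrow(seed_and_extend(q, subj)) > 0) n_hit <- n_hit + 1
  }
  expect_lte(n_hit, 5)
})

test_that("search is strand symmetric: reverse-complemented subject mirrors intervals with equal scores", {
  set.seed(31)
  q <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  subj <- paste0(paste(sample(c("A", "C", "G", "T"), 100, TRUE),
                       collapse = ""), q,
                 paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                       collapse = ""))
  L <- nchar(subj)
  fwd <- seed_and_extend(q, subj)
  rev <- seed_and_extend(q, revcomp(subj))
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(fwd$raw_score), sort(rev$raw_score))
  top_f <- fwd[1, ]; top_r <- rev[1, ]
  expect_equal(top_r$s_start, L - top_f$s_end)
  expect_equal(top_r$s_end, L - top_f$s_start)
  expect_true(top_f$strand != top_r$strand)
})

test_that("hits written as blast6 round-trip through the reader", {
  set.seed(5)
  q <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  subj <- paste0(strrep("C", 80), q, strrep("G", 60))
  hits <- search_sequences(c(q1 = q), c(s1 = subj))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_blast6(hits, path)
  back <- read_homology_hits(path, "blast6", e_threshold = 1)
  expect_equal(back$s_start, hits$s_start)
  expect_equal(back$s_end, hits$s_end)
  expect_equal(back$strand, hits$strand)
})
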