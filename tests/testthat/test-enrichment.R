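test_that("one-sided Fisher matches trivial and oracle-derived values", {
  expect_equal(fisher_one_sided(0, 10, 5, 100), 1.0)
  expect_equal(fisher_one_sided(1, 1, 1, 2), 0.5)
  expect_equal(fisher_one_sided(5, 105, 50, 10050),
               hyper_tail_oracle(5, 105, 50, 10050), tolerance = 1e-12)
  expect_error(fisher_one_sided(6, 5, 10, 100), "margins")
  expect_error(fisher_one_sided(-1, 5, 10, 100), "margins")
})

test_that("BH-FDR reproduces hand-applied step-up decisions", {
  expect_false(any(bh_fdr(rep(1, 20), alpha = 0.05)$significant))
  expect_true(bh_fdr(0.0005, alpha = 0.001)$significant)
  res <- bh_fdr(c(0.001, 0.01, 0.02, 0.8), alpha = 0.05)
  expect_equal(sum(res$significant), 3)
  expect_false(res$significant[4])
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  # q >= p and monotone in sorted order
  set.seed(2)
  p <- runif(50)
  q <- bh_fdr(p)$q_value
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("position tallies aggregate contigs and pool the anti-defence class", {
  geo <- dplyr::bind_rows(
    toy_geometry(c(0, 1), c("anti_crispr", "uncharacterized"), contig = "c1"),
    toy_geometry(c(0, 1), c("anti_crispr", "sos_inhibitor"), contig = "c2"))
  tab <- tally_positions(geo)
  a0 <- tab[tab$category == "anti_defence" & tab$relative_position == 0, ]
  expect_equal(a0$n, 2L)
  expect_equal(a0$n_total, 2L)
  a1 <- tab[tab$category == "anti_defence" & tab$relative_position == 1, ]
  expect_equal(a1$n, 1L)
  # permutation invariance over contigs
  tab2 <- tally_positions(geo[sample(nrow(geo)), ])
  expect_equal(as.data.frame(tab), as.data.frame(tab2))
})

test_that("windowed frequency uses a centred truncated window", {
  tab <- tibble::tibble(relative_position = 0:4,
                        category = "anti_defence",
                        n = c(0L, 0L, 5L, 0L, 0L),
                        n_total = rep(10L, 5))
  out <- windowed_frequency(tab, window = 5)
  expect_equal(out$f_w[out$relative_position == 2], 5 / 50)
  # truncation at the edge: position 0 windows over positions 0..2
  expect_equal(out$f_w[out$relative_position == 0], 5 / 30)
  # saturated counts give frequency 1 everywhere
  sat <- tab |> dplyr::mutate(n = n_total)
  expect_true(all(windowed_frequency(sat)$f_w == 1))
  expect_error(windowed_frequency(tab, window = 4), "odd")
})

test_that("positions below the ORF floor are not tested", {
  geo <- dplyr::bind_rows(lapply(sprintf("c%02d", 1:60), function(cid) {
    toy_geometry(c(0, 1), c("anti_crispr", "uncharacterized"), contig = cid)
  }))
  # position 1 present on only 49 contigs
  geo <- geo[!(geo$relative_position == 1 &
                 geo$contig_id %in% sprintf("c%02d", 1:11)), ]
  tab <- tally_positions(geo)
  res <- test_position_enrichment(tab, categories = "anti_defence",
                                  min_orfs = 50)
  expect_true(res$tested[res$relative_position == 0])
  expect_false(res$tested[res$relative_position == 1])
  expect_true(is.na(res$p_value[res$relative_position == 1]))
})

test_that("planted positional enrichment is flagged and uniform background is not", {
  cfg <- sim_config(n_contigs = 250, genes_per_contig = c(40, 50),
                    leading_freq = 0.3, background_freq = 0.01,
                    enriched_positions = 0:4, island_prob = 0,
                    seed = 424, emit_sequences = FALSE)
  sim <- simulate_contigs(cfg)
  genes <- assign_categories(sim$genes,
                             dplyr::bind_rows(sim$hits$relaxase,
                                              sim$hits$category),
                             sim$category_map)
  qc <- qc_filter_contigs(genes, sim$hits$relaxase, sim$hits$orit)
  geo <- assign_relative_positions(genes, qc)
  res <- test_position_enrichment(tally_positions(geo),
                                  categories = "anti_defence",
                                  min_orfs = 50, alpha = 0.001)
  flagged <- res$relative_position[res$significant]
  expect_setequal(flagged, 0:4)

  # null: no positional structure -> nothing flagged
  null_sim <- simulate_null(sim_config(n_contigs = 250,
                                       genes_per_contig = c(40, 50),
                                       background_freq = 0.02, seed = 523))
  genes_n <- assign_categories(null_sim$genes,
                               dplyr::bind_rows(null_sim$hits$relaxase,
                                                null_sim$hits$category),
                               null_sim$category_map)
  qc_n <- qc_filter_contigs(genes_n, null_sim$hits$relaxase,
                            null_sim$hits$orit)
  geo_n <- assign_relative_positions(genes_n, qc_n)
  res_n <- test_position_enrichment(tally_positions(geo_n),
                                    categories = "anti_defence",
                                    min_orfs = 50, alpha = 0.001)
  expect_equal(sum(res_n$significant), 0)
})

test_that("family enrichment flags leading-concentrated families only", {
  # 30 contigs x 100 ORFs; family 'lead' present at positions 0-5 on each
  # contig, family 'flat' scattered uniformly
  geos <- lapply(sprintf("c%02d", 1:30), function(cid) {
    pos <- c(0:59, -1:-40)
    toy_geometry(pos, rep("uncharacterized", 100), contig = cid)
  })
  geo <- dplyr::bind_rows(geos)
  lead_members <- geo$gene_id[geo$relative_position %in% 0:5]
  set.seed(9)
  flat_members <- sample(geo$gene_id, length(lead_members))
  fams <- dplyr::bind_rows(
    tibble::tibble(gene_id = lead_members, family_id = "lead"),
    tibble::tibble(gene_id = setdiff(flat_members, lead_members),
                   family_id = "flat"))
  res <- test_family_enrichment(geo, fams, leading_range = c(0, 27),
                                alpha = 0.001, min_size = 5)
  expect_true(res$enriched[res$family_id == "lead"])
  expect_false(res$enriched[res$family_id == "flat"])
  # oracle equivalence for the leading family
  lead_row <- res[res$family_id == "lead", ]
  n_lead <- sum(geo$relative_position >= 0 & geo$relative_position <= 27)
  expect_equal(lead_row$p_value,
               hyper_tail_oracle(lead_row$leading_count, lead_row$size,
                                 n_lead, nrow(geo)), tolerance = 1e-12)
  # zero leading occurrences -> p = 1 branch
  lag_members <- geo$gene_id[geo$relative_position < -20][1:20]
  res2 <- test_family_enrichment(
    geo, tibble::tibble(gene_id = lag_members, family_id = "lagfam"),
    min_size = 5)
  expect_equal(res2$p_value[res2$family_id == "lagfam"], 1)
  expect_false(res2$enriched[res2$family_id == "lagfam"])
})

test_that("family orientation votes and majority annotation follow the stated rules", {
  expect_equal(majority_orientation(c(TRUE, TRUE, TRUE, FALSE, FALSE)),
               "t_strand")
  expect_equal(majority_orientation(c(TRUE, TRUE, FALSE, FALSE)), "tie")
  expect_equal(majority_orientation(rep(FALSE, 4)), "opposite")
  expect_equal(family_majority_annotation(c("A", "A", "B")), "A")
  expect_equal(family_majority_annotation(character()), "uncharacterized")
  expect_equal(family_majority_annotation(c("A", "B")), "A")
})
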