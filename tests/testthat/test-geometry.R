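test_that("best oriT selection maximises score with deterministic tie-breaks", {
  h <- dplyr::bind_rows(orit_hit("c1", 100L, 200L, bit = 40),
                        orit_hit("c1", 500L, 600L, bit = 55))
  expect_equal(select_best_orit(h)$s_start, 500L)
  one <- orit_hit("c1", 10L, 60L)
  expect_equal(select_best_orit(one)$s_start, 10L)
  tie <- dplyr::bind_rows(orit_hit("c1", 900L, 1000L, bit = 50),
                          orit_hit("c1", 100L, 200L, bit = 50))
  expect_equal(select_best_orit(tie)$s_start, 100L)
  expect_equal(nrow(select_best_orit(h[0, ])), 0)
})

test_that("QC rejects contigs per the geometry filters with named reasons", {
  # a well-formed contig: 5 genes, relaxase 3rd, oriT right after it
  genes <- make_genes("ok", c(0L, 1000L, 2000L, 3300L, 4300L),
                      c(900L, 1900L, 2900L, 4200L, 5200L),
                      rep("+", 5))
  rel <- protein_hit("hmm_relaxase", "ok_g03")
  ori <- orit_hit("ok", 2950L, 3100L)
  qc <- qc_filter_contigs(genes, rel, ori)
  expect_true(qc$pass)
  expect_equal(qc$relaxase_gene_id, "ok_g03")
  expect_equal(qc$distance_bp, 50L)

  # three relaxase hits -> too_many_relaxases
  rel3 <- dplyr::bind_rows(rel, protein_hit("hmm_relaxase", "ok_g02"),
                           protein_hit("hmm_traM", "ok_g04"))
  expect_equal(qc_filter_contigs(genes, rel3, ori)$reason,
               "too_many_relaxases")

  # distance above 3,500 bp -> too_far (oriT far right of the relaxase)
  genes_far <- make_genes("far", c(0L, 1000L, 2000L, 8000L, 9000L),
                          c(900L, 1900L, 2900L, 8900L, 9900L),
                          rep("+", 5))
  qc_far <- qc_filter_contigs(genes_far,
                              protein_hit("hmm_relaxase", "far_g02"),
                              orit_hit("far", 5500L, 5600L))
  expect_equal(qc_far$reason, "too_far")
  # exactly at the boundary passes (strict 'more than')
  qc_edge <- qc_filter_contigs(genes_far,
                               protein_hit("hmm_relaxase", "far_g02"),
                               orit_hit("far", 5400L, 5500L))
  expect_true(qc_edge$pass)

  # oriT inside the relaxase gene -> rejected; partial overlap retained
  genes_in <- make_genes("in", c(0L, 1000L, 3000L, 4000L),
                         c(900L, 2000L, 3900L, 4900L), rep("+", 4))
  rel_in <- protein_hit("hmm_relaxase", "in_g02")
  expect_equal(qc_filter_contigs(genes_in, rel_in,
                                 orit_hit("in", 1200L, 1300L))$reason,
               "orit_inside_relaxase")
  expect_true(qc_filter_contigs(genes_in, rel_in,
                                orit_hit("in", 1900L, 2100L))$pass)

  # relaxase at the first annotated gene -> edge_placement
  expect_equal(qc_filter_contigs(genes, protein_hit("hmm_relaxase", "ok_g01"),
                                 orit_hit("ok", 950L, 990L))$reason,
               "edge_placement")
  # missing inputs
  expect_equal(qc_filter_contigs(genes, rel[0, ], ori)$reason, "no_relaxase")
  expect_equal(qc_filter_contigs(genes, rel, ori[0, ])$reason, "no_orit")
})

test_that("relative positions index outward from the oriT with the relaxase lagging", {
  # relaxase [1000,2000), oriT [2100,2200), gene midpoints 2400, 2800, 600
  genes <- make_genes("c1", c(550L, 1000L, 2350L, 2750L),
                      c(650L, 2000L, 2450L, 2850L), rep("+", 4),
                      ids = c("far_lag", "rel", "lead0", "lead1"))
  qc <- qc_filter_contigs(genes, protein_hit("hmm_relaxase", "rel"),
                          orit_hit("c1", 2100L, 2200L))
  expect_true(qc$pass)
  geo <- assign_relative_positions(genes, qc)
  got <- setNames(geo$relative_position, geo$gene_id)
  expect_equal(got[["lead0"]], 0L)
  expect_equal(got[["lead1"]], 1L)
  expect_equal(got[["rel"]], -1L)
  expect_equal(got[["far_lag"]], -2L)
  expect_true(all(geo$leading_direction == 1L))
  expect_true(geo$is_relaxase[geo$gene_id == "rel"])
})

test_that("T-strand expressibility follows the toward_oriT convention", {
  genes <- make_genes("c1", c(550L, 1000L, 2350L, 2750L),
                      c(650L, 2000L, 2450L, 2850L),
                      c("+", "+", "-", "+"))
  qc <- qc_filter_contigs(genes, protein_hit("hmm_relaxase", "c1_g02"),
                          orit_hit("c1", 2100L, 2200L))
  geo <- assign_relative_positions(genes, qc)
  # leading_direction +1: minus-strand genes transcribe toward the oriT
  # and can be expressed from the transferred strand
  expect_equal(geo$t_strand_expressible[geo$strand == "-"], TRUE)
  expect_equal(unique(geo$t_strand_expressible[geo$strand == "+"]), FALSE)
  # opposite convention flips every flag
  geo2 <- assign_relative_positions(genes, qc,
                                    convention = "away_from_oriT")
  expect_equal(geo2$t_strand_expressible, !geo$t_strand_expressible)
})

test_that("reverse complementing a contig leaves positions and flags unchanged", {
  set.seed(99)
  cfg <- sim_config(n_contigs = 30, genes_per_contig = c(20, 30),
                    seed = 99, emit_sequences = FALSE)
  sim <- simulate_contigs(cfg)
  qc <- qc_filter_contigs(sim$genes, sim$hits$relaxase, sim$hits$orit)
  geo <- assign_relative_positions(sim$genes, qc)
  mir <- mirror_fixture(sim)
  qc_m <- qc_filter_contigs(mir$genes, sim$hits$relaxase, mir$orit)
  geo_m <- assign_relative_positions(mir$genes, qc_m)
  a <- geo |> dplyr::arrange(gene_id) |>
    dplyr::select(gene_id, relative_position, t_strand_expressible)
  b <- geo_m |> dplyr::arrange(gene_id) |>
    dplyr::select(gene_id, relative_position, t_strand_expressible)
  expect_equal(a, b)
  # the mirrored contig transfers in the mirrored direction
  dirs <- dplyr::distinct(geo, contig_id, leading_direction) |>
    dplyr::inner_join(dplyr::distinct(geo_m, contig_id, leading_direction),
                      by = "contig_id")
  expect_equal(dirs$leading_direction.x, -dirs$leading_direction.y)
})

test_that("simulator geometry is recovered exactly (truth check)", {
  cfg <- sim_config(n_contigs = 40, genes_per_contig = c(15, 25),
                    seed = 1234, emit_sequences = FALSE)
  sim <- simulate_contigs(cfg)
  qc <- qc_filter_contigs(sim$genes, sim$hits$relaxase, sim$hits$orit)
  expect_true(all(qc$pass))
  geo <- assign_relative_positions(sim$genes, qc)
  truth <- sim$truth$genes
  cmp <- dplyr::inner_join(geo, truth, by = c("contig_id", "gene_id"))
  expect_equal(cmp$relative_position, cmp$true_position)
  dirs <- dplyr::distinct(geo, contig_id, leading_direction) |>
    dplyr::inner_join(
      dplyr::select(sim$truth$contigs, contig_id,
                    true_dir = leading_direction),
      by = "contig_id")
  expect_equal(dirs$leading_direction, dirs$true_dir)
})
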