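#' Pipeline run configuration
#'
#' All stage parameters with defaults set to the pipeline's reference
#' parameterisation: e-value threshold 1e-6, at most 2 relaxase/TraM hits
#' per contig, relaxase-oriT distance at most 3,500 bp, dedup threshold
#' 0.9, five-ORF frequency window, positions tested at >= 50 ORFs, FDR
#' alpha 0.001, leading range 0-27 (the first 28 leading ORFs),
#' regulatory regions 50-350 bp, aligner word size 5.
#'
#' @param e_threshold,max_relaxase_hits,max_distance,dedup_threshold
#'   Stage parameters (see the respective stage functions).
#' @param window,min_orfs,alpha,leading_range Enrichment parameters.
#' @param region_len_min,region_len_max,word_size Frpo-scan parameters.
#' @param min_island_members,max_island_gap Island parameters.
#' @param family_min_size Minimum gene-family size analysed.
#' @param mob_exclude MOB types excluded from the enrichment tables
#'   (default none).
#' @param convention T-strand convention (see
#'   [assign_relative_positions()]).
#' @param seed Seed for any stage using randomness.
#' @return A list of class `pl_run_config`.
#' @export
run_config <- function(e_threshold = 1e-6, max_relaxase_hits = 2,
                       max_distance = 3500, dedup_threshold = 0.9,
                       window = 5, min_orfs = 50, alpha = 0.001,
                       leading_range = c(0, 27), region_len_min = 50,
                       region_len_max = 350, word_size = 5,
                       min_island_members = 3, max_island_gap = 2,
                       family_min_size = 5, mob_exclude = character(0),
                       convention = "toward_oriT", seed = 1L) {
  cfg <- list(
    e_threshold = as.numeric(e_threshold),
    max_relaxase_hits = as.integer(max_relaxase_hits),
    max_distance = as.integer(max_distance),
    dedup_threshold = as.numeric(dedup_threshold),
    window = as.integer(window),
    min_orfs = as.integer(min_orfs),
    alpha = as.numeric(alpha),
    leading_range = as.integer(leading_range),
    region_len_min = as.integer(region_len_min),
    region_len_max = as.integer(region_len_max),
    word_size = as.integer(word_size),
    min_island_members = as.integer(min_island_members),
    max_island_gap = as.integer(max_island_gap),
    family_min_size = as.integer(family_min_size),
    mob_exclude = as.character(mob_exclude),
    convention = as.character(convention),
    seed = as.integer(seed))
  structure(cfg, class = "pl_run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return `read_run_config()` returns a `pl_run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
  cfg
}

#' @rdname read_run_config
#' @param config A `pl_run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline on a fixture
#'
#' Stages, in order: category annotation -> oriT selection and
#' geometry QC -> relative-position assignment -> deduplication ->
#' positional and family enrichment -> island detection -> Frpo scan
#' (when sequences are available). Deterministic given the fixture and
#' config; rerunning writes byte-identical outputs.
#'
#' @param fixture A `pl_sim` from [simulate_contigs()], or a list with
#'   the same components built from files (`genes`, `hits` =
#'   `list(relaxase, category, orit)`, `membership`, `category_map`,
#'   optional `families` (gene_id, family_id; falls back to the dedup
#'   membership), `sequences` and `contigs` metadata with `mob_type`).
#' @param config A [run_config()].
#' @param out_dir Output directory; created if needed. Tables written:
#'   `qc.tsv, geometry.tsv, dedup.tsv, positions.tsv, families.tsv,
#'   islands.tsv, frpo.tsv` plus `manifest.json`.
#' @param known_frpo Known Frpo/ssi query set for the homology tier
#'   (default: the bundled synthetic stand-ins).
#' @return Invisibly, a list with every stage result (`genes, qc,
#'   geometry, dedup, positions, enrichment, families, islands, frpo,
#'   manifest`).
#' @export
run_pipeline <- function(fixture, config = run_config(), out_dir = NULL,
                         known_frpo = synthetic_frpo_queries()) {
  stopifnot(inherits(config, "pl_run_config"))
  genes <- assign_categories(fixture$genes,
                             bind_rows(fixture$hits$relaxase,
                                       fixture$hits$category),
                             fixture$category_map)
  qc <- qc_filter_contigs(genes, fixture$hits$relaxase, fixture$hits$orit,
                          max_relaxase_hits = config$max_relaxase_hits,
                          max_distance = config$max_distance)
  geometry <- assign_relative_positions(genes, qc,
                                        convention = config$convention)
  dedup <- deduplicate(filter(genes,
                              .data$contig_id %in% qc$contig_id[qc$pass]),
                       fixture$membership,
                       threshold = config$dedup_threshold)
  geometry <- filter(geometry, .data$contig_id %in% dedup$representatives)
  if (length(config$mob_exclude) > 0 && !is.null(fixture$contigs)) {
    keep <- fixture$contigs$contig_id[
      !fixture$contigs$mob_type %in% config$mob_exclude]
    geometry <- filter(geometry, .data$contig_id %in% keep)
  }
  positions <- tally_positions(geometry) |>
    windowed_frequency(window = config$window)
  enrichment <- test_position_enrichment(positions,
                                         min_orfs = config$min_orfs,
                                         alpha = config$alpha)
  fam_tbl <- if (!is.null(fixture$families)) {
    fixture$families
  } else {
    rename(fixture$membership, family_id = "cluster_id")
  }
  fam_tbl <- filter(fam_tbl, .data$gene_id %in% geometry$gene_id)
  families <- test_family_enrichment(geometry, fam_tbl,
                                     leading_range = config$leading_range,
                                     alpha = config$alpha,
                                     min_size = config$family_min_size)
  islands <- detect_islands(geometry, max_gap = config$max_island_gap,
                            min_members = config$min_island_members,
                            leading_end = config$leading_range[2])
  frpo <- NULL
  if (!is.null(fixture$sequences)) {
    scheme <- scoring_scheme(word_size = config$word_size)
    regions <- extract_upstream_regions(geometry, fixture$sequences,
                                        len_min = config$region_len_min,
                                        len_max = config$region_len_max)
    frpo <- scan_frpo(regions, known_frpo = known_frpo, scheme = scheme)
  }
  manifest <- list(
    package = "plasmidlead",
    version = as.character(utils::packageVersion("plasmidlead")),
    seed = config$seed,
    parameters = unclass(config),
    parameter_hash = rlang::hash(unclass(config)),
    n_contigs_input = length(unique(fixture$genes$contig_id)),
    n_contigs_pass_qc = sum(qc$pass),
    n_representatives = length(dedup$representatives))
  result <- list(genes = genes, qc = qc, geometry = geometry, dedup = dedup,
                 positions = positions, enrichment = enrichment,
                 families = families, islands = islands, frpo = frpo,
                 manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(result$qc, p("qc.tsv"), progress = FALSE)
  write_geometry(result$geometry, p("geometry.tsv"))
  readr::write_tsv(result$dedup$removed, p("dedup.tsv"), progress = FALSE)
  readr::write_tsv(result$enrichment, p("positions.tsv"), progress = FALSE)
  readr::write_tsv(result$families, p("families.tsv"), progress = FALSE)
  write_islands(result$islands, p("islands.tsv"), p("islands.json"))
  if (!is.null(result$frpo)) {
    readr::write_tsv(result$frpo, p("frpo.tsv"), progress = FALSE)
  } else {
    readr::write_tsv(tibble(), p("frpo.tsv"), progress = FALSE)
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Display filter for the positional enrichment table
#'
#' Restricts a positions table to positions represented by at least
#' `min_sequences` ORFs. A report-layer filter only: statistics are
#' computed on the full table.
#'
#' @param positions A positions/enrichment tibble with `n_total`.
#' @param min_sequences Display threshold (default 500).
#' @return The filtered tibble.
#' @export
report_positions <- function(positions, min_sequences = 500) {
  out <- filter(positions, .data$n_total >= min_sequences)
  if (nrow(out) == 0) {
    warn(sprintf("no position is represented by >= %d sequences",
                 min_sequences))
  }
  out
}
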