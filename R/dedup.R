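#' Shared-ORF fraction between two contigs
#'
#' The fraction of ORFs shared by two contigs according to an ORF
#' cluster membership: the multiset intersection of their cluster-id
#' multisets divided by the smaller contig's ORF count. Using the smaller
#' contig as denominator makes containment (a sub-plasmid) score 1, so
#' redundant smaller elements are removed by [deduplicate()]. Genes absent
#' from the membership table count as singleton clusters.
#'
#' @param clusters_a,clusters_b Character vectors of cluster ids, one per
#'   ORF of each contig.
#' @return A fraction in `[0, 1]`.
#' @export
shared_orf_fraction <- function(clusters_a, clusters_b) {
  if (length(clusters_a) == 0 || length(clusters_b) == 0) {
    abort("shared_orf_fraction is undefined for a contig with no genes")
  }
  ta <- table(clusters_a)
  tb <- table(clusters_b)
  common <- intersect(names(ta), names(tb))
  shared <- sum(pmin(ta[common], tb[common]))
  shared / min(length(clusters_a), length(clusters_b))
}

contig_cluster_list <- function(genes, membership) {
  mem <- setNames(membership$cluster_id, membership$gene_id)
  cl <- unname(mem[genes$gene_id])
  # unmapped genes become singleton clusters
  miss <- is.na(cl)
  cl[miss] <- paste0("singleton:", genes$gene_id[miss])
  split(cl, genes$contig_id)
}

#' Remove redundant contigs by shared-ORF fraction
#'
#' Greedy deduplication: contigs are visited sorted by decreasing ORF
#' count (ties by contig id), and a contig is removed when it shares
#' strictly more than `threshold` of its ORFs (per
#' [shared_orf_fraction()], denominator = smaller contig) with an
#' already-kept contig. A pair sharing exactly the threshold fraction is
#' kept. The result is invariant under permutation of the input and
#' idempotent.
#'
#' @param genes Gene table covering all contigs.
#' @param membership Tibble `gene_id, cluster_id`
#'   ([read_cluster_membership()]).
#' @param threshold Strict shared-fraction threshold (default 0.9).
#' @return A list of class `pl_dedup`: `representatives` (character),
#'   `removed` (tibble `removed_id, kept_id, fraction`), `threshold`.
#' @export
deduplicate <- function(genes, membership, threshold = 0.9) {
  clusters <- contig_cluster_list(genes, membership)
  ord <- order(-lengths(clusters), names(clusters))
  ids <- names(clusters)[ord]
  kept <- character()
  removed <- list()
  for (cid in ids) {
    partner <- NA_character_
    frac <- NA_real_
    for (k in kept) {
      f <- shared_orf_fraction(clusters[[cid]], clusters[[k]])
      if (f > threshold) { partner <- k; frac <- f; break }
    }
    if (is.na(partner)) {
      kept <- c(kept, cid)
    } else {
      removed[[length(removed) + 1]] <-
        tibble(removed_id = cid, kept_id = partner, fraction = frac)
    }
  }
  structure(
    list(representatives = kept,
         removed = if (length(removed)) bind_rows(removed) else
           tibble(removed_id = character(), kept_id = character(),
                  fraction = double()),
         threshold = threshold),
    class = "pl_dedup")
}

#' @export
print.pl_dedup <- function(x, ...) {
  cat(sprintf("<pl_dedup> %d representative contig(s), %d removed (threshold %.2f)\n",
              length(x$representatives), nrow(x$removed), x$threshold))
  invisible(x)
}
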