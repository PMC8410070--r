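# Per-cluster marker discovery, EC-enrichment, and core-vs-periphery
# differential splits. All tests go through the package's rank-sum
# machinery; multiplicity correction is Bonferroni within each comparison
# (the number of genes tested there). Markers are up-regulated-only: the
# two-sided p is retained but a positive-direction filter is applied.

#' Find cluster markers by rank-sum tests
#'
#' Tests every gene cluster-vs-all-other-cells on the normalized values,
#' Bonferroni-corrects within the comparison, and retains genes with
#' `p_adj < alpha`, `lfc > min_lfc` and positive direction. Singleton
#' clusters are skipped with a warning.
#'
#' @param nm a [normalize_counts()] result.
#' @param labels a [cluster_cells()] result or integer/character vector.
#' @param alpha significance cutoff on the Bonferroni-adjusted p (0.05).
#' @param min_lfc minimum natural-log fold-change (0; strict).
#' @param pseudocount pseudocount of [log_fold_change()].
#' @return A `marker_table` data.frame (gene, cluster, lfc, p_raw, p_adj,
#'   pct_in, pct_out, rank), sorted within cluster by ascending p, ties by
#'   descending lfc then symbol. The full per-gene scan is attached as
#'   attribute `"scan"`.
#' @export
find_all_markers <- function(nm, labels, alpha = 0.05, min_lfc = 0,
                             pseudocount = 1) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  values <- values_of(nm)
  if (length(lab) != ncol(values))
    stop("labels length does not match the number of cells")
  clusters <- sort(unique(lab))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  pre <- rank_precompute(values)
  out <- list(); scans <- list()
  for (cl in clusters) {
    ind <- lab == cl
    if (sum(ind) < 2) {
      warning("cluster ", cl, " has fewer than 2 cells; skipped")
      next
    }
    scan <- ranksum_scan(pre, ind, pseudocount)
    scan$cluster <- cl
    scan$p_adj <- adjust_bonferroni(scan$p_raw, nrow(scan))
    scans[[as.character(cl)]] <- scan
    keep <- scan[scan$p_adj < alpha & scan$lfc > min_lfc, , drop = FALSE]
    keep <- keep[order(keep$p_raw, -keep$lfc, keep$gene), , drop = FALSE]
    keep$rank <- seq_len(nrow(keep))
    out[[as.character(cl)]] <- keep
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene = character(), cluster = integer(), lfc = numeric(),
                      p_raw = numeric(), p_adj = numeric(), pct_in = numeric(),
                      pct_out = numeric(), rank = integer())
  rownames(res) <- NULL
  res <- res[, c("gene", "cluster", "lfc", "p_raw", "p_adj",
                 "pct_in", "pct_out", "rank")]
  attr(res, "scan") <- do.call(rbind, scans)
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Top-k marker sets per cluster
#'
#' @param mt a [find_all_markers()] table.
#' @param k set size cap (default 50, the usual cross-atlas convention).
#' @return Named list of [marker_set()] objects; clusters with fewer than
#'   `k` significant genes contribute all of them, with the count recorded
#'   in `n_available`.
#' @export
top_k_markers <- function(mt, k = 50) {
  stopifnot(inherits(mt, "marker_table") || is.data.frame(mt))
  out <- list()
  for (cl in unique(mt$cluster)) {
    rows <- mt[mt$cluster == cl, , drop = FALSE]
    rows <- rows[order(rows$p_raw, -rows$lfc, rows$gene), , drop = FALSE]
    take <- head(rows$gene, k)
    out[[as.character(cl)]] <- marker_set(cl, take, n_available = nrow(rows))
  }
  out
}

#' EC-enriched genes (EC cells versus all other cell classes)
#'
#' Two-group version of the marker machinery: genes significantly
#' up-regulated in cells of EC-annotated clusters versus all remaining
#' cells, Bonferroni-corrected within the comparison.
#'
#' @param nm a [normalize_counts()] result over all (post-QC) cells.
#' @param labels cluster labels for those cells.
#' @param annotation an [annotate_clusters()] result.
#' @param alpha adjusted-p cutoff.
#' @param ec_class EC class name.
#' @param pseudocount pseudocount of [log_fold_change()].
#' @return A [gene_set()] of EC-enriched genes; the full scan is attached
#'   as attribute `"scan"`.
#' @export
ec_enriched_genes <- function(nm, labels, annotation, alpha = 0.05,
                              ec_class = "EC", pseudocount = 1) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  ec_clusters <- names(annotation$cluster_class)[
    annotation$cluster_class == ec_class]
  if (!length(ec_clusters)) stop("no cluster annotated as '", ec_class, "'")
  ind <- as.character(lab) %in% ec_clusters
  if (all(ind)) stop("no non-EC cells to compare against")
  values <- values_of(nm)
  pre <- rank_precompute(values)
  scan <- ranksum_scan(pre, ind, pseudocount)
  scan$p_adj <- adjust_bonferroni(scan$p_raw, nrow(scan))
  hits <- scan[scan$p_adj < alpha & scan$lfc > 0, , drop = FALSE]
  hits <- hits[order(hits$p_raw, -hits$lfc, hits$gene), , drop = FALSE]
  out <- gene_set("EC_enriched", hits$gene,
                  description = "up in EC cells vs other CD31+ classes")
  attr(out, "scan") <- scan
  out
}

#' Core-versus-periphery split of EC-enriched genes
#'
#' Within the EC-enriched set only, tests each gene tumor-core versus
#' periphery among EC cells, Bonferroni-corrected over the tested set, and
#' splits the significant genes by the sign of the core-vs-periphery fold
#' change.
#'
#' @param nm_ec EC-restricted [normalize_counts()] result (its `cell_meta`
#'   supplies the region labels) or a plain matrix plus `regions`.
#' @param ec_enriched the [ec_enriched_genes()] set (or character vector).
#' @param alpha adjusted-p cutoff.
#' @param regions optional explicit region vector (`"core"`/`"periphery"`).
#' @param pseudocount pseudocount of [log_fold_change()].
#' @return List with `up_in_core` and `down_in_core` ([gene_set()]s, or
#'   `NULL` when a side is empty) and `table` (the per-gene scan restricted
#'   to the tested set). The two sides are always disjoint and contained in
#'   the EC-enriched set.
#' @export
differential_ec_genes <- function(nm_ec, ec_enriched, alpha = 0.05,
                                  regions = NULL, pseudocount = 1) {
  values <- values_of(nm_ec)
  if (is.null(regions)) {
    if (!inherits(nm_ec, "normalized_matrix"))
      stop("regions must be given when nm_ec is a plain matrix")
    regions <- nm_ec$cell_meta$region
  }
  if (!all(c("core", "periphery") %in% regions))
    stop("both regions must be represented among the EC cells")
  genes <- intersect(genes_of(ec_enriched), rownames(values))
  if (!length(genes)) stop("no EC-enriched genes present in the matrix")
  pre <- rank_precompute(values[genes, , drop = FALSE])
  scan <- ranksum_scan(pre, regions == "core", pseudocount)
  scan$p_adj <- adjust_bonferroni(scan$p_raw, nrow(scan))
  sig <- scan[scan$p_adj < alpha, , drop = FALSE]
  up <- sig$gene[sig$lfc > 0]
  down <- sig$gene[sig$lfc < 0]
  list(up_in_core = if (length(up))
         gene_set("up_in_core", up, "EC-enriched, up in tumor core"),
       down_in_core = if (length(down))
         gene_set("down_in_core", down, "EC-enriched, down in tumor core"),
       table = scan)
}
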