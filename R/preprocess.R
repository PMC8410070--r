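# QC filtering, scale-factor normalization, clustering, cluster annotation
# by canonical class panels, and in-silico EC selection with heterotypic
# doublet flagging.

#' Quality-control thresholds
#'
#' Cells with a mitochondrial count fraction strictly greater than
#' `max_mito_fraction` or strictly fewer than `min_genes_detected` detected
#' genes are removed; both inequalities are strict, matching the usual
#' "greater than 10% / fewer than 200" phrasing of droplet QC.
#'
#' @param max_mito_fraction maximum tolerated mitochondrial fraction
#'   (default 0.10).
#' @param min_genes_detected minimum detected genes per cell (default 200).
#' @param scale_factor per-cell normalization scale factor (default 10000).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_mito_fraction = 0.10, min_genes_detected = 200,
                          scale_factor = 10000) {
  if (max_mito_fraction <= 0 || max_mito_fraction >= 1)
    stop("max_mito_fraction must lie in (0, 1)")
  if (min_genes_detected < 1) stop("min_genes_detected must be >= 1")
  if (scale_factor <= 0) stop("scale_factor must be positive")
  structure(list(max_mito_fraction = max_mito_fraction,
                 min_genes_detected = as.integer(min_genes_detected),
                 scale_factor = scale_factor),
            class = "qc_thresholds")
}

#' Filter cells failing quality control
#'
#' @param cm a [count_matrix()].
#' @param thr a [qc_thresholds()].
#' @return List with elements `counts` (the filtered [count_matrix()], gene
#'   panel unchanged) and `report` (data.frame of removed barcodes with
#'   columns `barcode`, `reason` in mito / min_genes / both, `mito_fraction`,
#'   `genes_detected`).
#' @export
qc_filter <- function(cm, thr = qc_thresholds()) {
  stopifnot(inherits(cm, "count_matrix"), inherits(thr, "qc_thresholds"))
  totals <- Matrix::colSums(cm$values)
  mito <- Matrix::colSums(cm$values[cm$mito_flag, , drop = FALSE])
  frac <- ifelse(totals > 0, mito / totals, 1)
  detected <- Matrix::colSums(cm$values > 0)
  fail_mito <- frac > thr$max_mito_fraction
  fail_genes <- detected < thr$min_genes_detected
  drop <- fail_mito | fail_genes
  if (all(drop))
    stop("QC removed every cell (", length(drop), " of ", length(drop), ")")
  report <- data.frame(
    barcode = cm$barcodes[drop],
    reason = ifelse(fail_mito[drop] & fail_genes[drop], "both",
                    ifelse(fail_mito[drop], "mito", "min_genes")),
    mito_fraction = frac[drop],
    genes_detected = as.integer(detected[drop]),
    stringsAsFactors = FALSE)
  list(counts = subset_cells(cm, !drop), report = report)
}

#' Scale-factor log-normalization
#'
#' Each count is divided by its cell's total, multiplied by the scale
#' factor, and log-transformed: `value = ln(1 + count / total * scale)`.
#' Zero counts map to exactly zero; the transform is invariant to scaling
#' all counts of a cell.
#'
#' @param cm a [count_matrix()] (post-QC; every cell must have positive
#'   total counts).
#' @param thr a [qc_thresholds()] supplying the scale factor.
#' @return An object of class `normalized_matrix`: sparse genes x cells
#'   values plus symbols, barcodes, metadata and provenance.
#' @export
normalize_counts <- function(cm, thr = qc_thresholds()) {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- Matrix::colSums(cm$values)
  if (any(totals == 0))
    stop("cells with zero total counts cannot be normalized: ",
         fmt_list(cm$barcodes[totals == 0]))
  v <- cm$values
  percell <- rep.int(totals, diff(v@p))
  v@x <- log1p(v@x / percell * thr$scale_factor)
  structure(list(values = v,
                 gene_symbols = cm$gene_symbols,
                 barcodes = cm$barcodes,
                 cell_meta = cm$cell_meta,
                 mito_flag = cm$mito_flag,
                 provenance = list(scale_factor = thr$scale_factor,
                                   qc = unclass(thr))),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix: ", length(x$gene_symbols), " genes x ",
      length(x$barcodes), " cells (scale factor ",
      x$provenance$scale_factor, ", natural log)\n", sep = "")
  invisible(x)
}

#' @noRd
subset_nm <- function(nm, keep) {
  out <- nm
  out$values <- nm$values[, keep, drop = FALSE]
  out$barcodes <- nm$barcodes[keep]
  out$cell_meta <- nm$cell_meta[keep, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  out
}

#' Cluster cells on principal components
#'
#' Computes the top principal components of the centered normalized values
#' (cells as observations) and clusters them either with k-means (`k`
#' given) or by Louvain community detection on a shared k-nearest-neighbour
#' graph (`resolution` given). Deterministic for a fixed seed; labels are
#' relabelled contiguously 1..K by decreasing cluster size.
#'
#' @param nm a [normalize_counts()] result.
#' @param n_pcs number of principal components (must be < min(genes, cells)).
#' @param k number of k-means clusters (mutually exclusive with
#'   `resolution`).
#' @param resolution Louvain resolution parameter.
#' @param knn neighbours for the kNN graph (graph method only).
#' @param seed RNG seed.
#' @return List of class `cluster_labels` with `labels` (named integer
#'   vector, 1-based, contiguous), `n_clusters`, `method`, `pcs`.
#' @export
cluster_cells <- function(nm, n_pcs = 20, k = NULL, resolution = NULL,
                          knn = 15, seed = 1) {
  stopifnot(inherits(nm, "normalized_matrix"))
  n_cells <- length(nm$barcodes)
  if (n_pcs >= min(nrow(nm$values), n_cells))
    stop("n_pcs must be smaller than both the gene and cell counts")
  if (is.null(k) == is.null(resolution))
    stop("give exactly one of k (k-means) or resolution (graph communities)")
  if (!is.null(k) && k > n_cells)
    stop("k (", k, ") exceeds the number of cells (", n_cells, ")")
  x <- t(as.matrix(nm$values))
  set.seed(seed)
  pcs <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  if (!is.null(k)) {
    fit <- kmeans(pcs, centers = k, nstart = 10, iter.max = 100)
    raw <- fit$cluster
    method <- "pca_kmeans"
  } else {
    d <- as.matrix(dist(pcs))
    diag(d) <- Inf
    edges <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
      nb <- order(d[i, ])[seq_len(min(knn, n_cells - 1))]
      cbind(i, nb)
    }))
    g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    raw <- igraph::membership(comm)
    method <- "pca_knn_louvain"
  }
  sizes <- table(raw)
  order_ids <- names(sizes)[order(-as.integer(sizes), names(sizes))]
  labels <- as.integer(factor(as.character(raw), levels = order_ids))
  names(labels) <- nm$barcodes
  structure(list(labels = labels, n_clusters = length(order_ids),
                 method = method, seed = seed, pcs = pcs),
            class = "cluster_labels")
}

#' Annotate clusters by canonical class-marker panels
#'
#' For every cluster and class panel, the score is the mean (over panel
#' genes) of the mean normalized expression in the cluster; the assigned
#' class is the argmax, with ties broken by panel order and recorded.
#'
#' @param nm a [normalize_counts()] result.
#' @param labels a [cluster_cells()] result (or an integer vector).
#' @param class_panels named list of [gene_set()] panels, one per class.
#' @return List of class `class_annotation` with `cluster_class` (named by
#'   cluster), `scores` (clusters x classes), `ties` (data.frame).
#' @export
annotate_clusters <- function(nm, labels, class_panels) {
  stopifnot(inherits(nm, "normalized_matrix"))
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  values <- nm$values
  rownames(values) <- nm$gene_symbols
  classes <- vapply(class_panels, function(p) p$name, character(1))
  names(class_panels) <- classes
  panel_genes <- lapply(class_panels, function(p) {
    present <- intersect(p$genes, nm$gene_symbols)
    miss <- setdiff(p$genes, nm$gene_symbols)
    if (length(miss))
      warning("panel '", p$name, "' genes missing from matrix: ",
              fmt_list(miss))
    if (!length(present))
      stop("no genes of panel '", p$name, "' are present in the matrix")
    present
  })
  clusters <- sort(unique(lab))
  scores <- matrix(0, length(clusters), length(classes),
                   dimnames = list(as.character(clusters), classes))
  for (ci in seq_along(clusters)) {
    in_cl <- lab == clusters[ci]
    gene_means <- Matrix::rowSums(values[, in_cl, drop = FALSE]) / sum(in_cl)
    for (cl in classes)
      scores[ci, cl] <- mean(gene_means[panel_genes[[cl]]])
  }
  assigned <- character(length(clusters))
  ties <- list()
  for (ci in seq_along(clusters)) {
    best <- max(scores[ci, ])
    winners <- classes[scores[ci, ] == best]
    assigned[ci] <- winners[1]       # declared panel order breaks ties
    if (length(winners) > 1)
      ties[[length(ties) + 1]] <- data.frame(cluster = clusters[ci],
                                             tied = paste(winners,
                                                          collapse = ","))
  }
  structure(list(cluster_class = setNames(assigned, as.character(clusters)),
                 scores = scores,
                 ties = if (length(ties)) do.call(rbind, ties)
                        else data.frame(cluster = integer(),
                                        tied = character())),
            class = "class_annotation")
}

#' Select EC cells in silico and flag heterotypic doublets
#'
#' Retains cells of EC-annotated clusters, then flags cells co-expressing a
#' non-EC program as heterotypic doublets. A 50:50 heterotypic doublet
#' carries about half of each parent's marker dose, so under the default
#' `"midpoint"` rule a cell is flagged when, for some non-EC class, its
#' panel score exceeds the midpoint between the median score of EC-cluster
#' cells and the median score of that class's own cluster cells (falling
#' back to median + 5 MAD when the class has no annotated cluster). Robust
#' MAD and within-population quantile cutoffs are available as
#' alternatives; all flagged cells are reported, never silently dropped.
#'
#' @param nm a [normalize_counts()] result covering all cells.
#' @param labels a [cluster_cells()] result for those cells.
#' @param annotation an [annotate_clusters()] result.
#' @param class_panels the panels used for annotation.
#' @param ec_class name of the EC class (default `"EC"`).
#' @param method `"midpoint"` (default), `"mad"`, or `"quantile"`.
#' @param mad_mult MAD multiplier for `method = "mad"` and the fallback.
#' @param doublet_quantile cutoff quantile for `method = "quantile"`.
#' @return List with `nm_ec` (the EC-restricted [normalize_counts()]
#'   object, doublets removed), `report` (flagged barcodes with the
#'   offending class and scores), `ec_clusters`, `thresholds`.
#' @export
select_ecs <- function(nm, labels, annotation, class_panels, ec_class = "EC",
                       method = c("midpoint", "mad", "quantile"),
                       mad_mult = 5, doublet_quantile = 0.99) {
  method <- match.arg(method)
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(annotation, "class_annotation"))
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  ec_clusters <- as.integer(names(annotation$cluster_class)[
    annotation$cluster_class == ec_class])
  if (!length(ec_clusters)) stop("no cluster was annotated as '", ec_class, "'")
  values <- nm$values
  rownames(values) <- nm$gene_symbols
  classes <- vapply(class_panels, function(p) p$name, character(1))
  names(class_panels) <- classes
  cell_scores <- sapply(class_panels, function(p) {
    genes <- intersect(p$genes, nm$gene_symbols)
    Matrix::colSums(values[genes, , drop = FALSE]) / length(genes)
  })
  rownames(cell_scores) <- nm$barcodes
  in_ec <- lab %in% ec_clusters
  non_ec <- setdiff(classes, ec_class)
  thresholds <- vapply(non_ec, function(cl) {
    s_ec <- cell_scores[in_ec, cl]
    own_clusters <- names(annotation$cluster_class)[
      annotation$cluster_class == cl]
    in_own <- as.character(lab) %in% own_clusters
    switch(method,
      midpoint = if (any(in_own))
          (median(s_ec) + median(cell_scores[in_own, cl])) / 2
        else median(s_ec) + mad_mult * mad(s_ec),
      mad = median(s_ec) + mad_mult * mad(s_ec),
      quantile = quantile(s_ec, doublet_quantile, names = FALSE))
  }, numeric(1))
  exceed <- sweep(cell_scores[, non_ec, drop = FALSE], 2, thresholds, ">")
  flagged <- in_ec & rowSums(exceed) > 0
  offending <- apply(exceed[flagged, , drop = FALSE], 1, function(z)
    paste(non_ec[z], collapse = ","))
  report <- data.frame(barcode = nm$barcodes[flagged],
                       offending_class = as.character(offending),
                       ec_score = cell_scores[flagged, ec_class],
                       stringsAsFactors = FALSE)
  keep <- in_ec & !flagged
  if (!any(keep)) stop("doublet flagging removed every EC cell")
  list(nm_ec = subset_nm(nm, keep), report = report,
       ec_clusters = ec_clusters, thresholds = thresholds)
}
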