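# Microvascular-score normalization of region-labelled bulk transcriptomes
# and marker-set enrichment per anatomic region. Vascular abundance differs
# strongly between glioblastoma anatomic structures (microvascular
# proliferation most of all), so raw marker expression confounds EC
# phenotype with vessel density; dividing each sample by a vascular score
# removes the per-sample abundance factor exactly.

#' Per-sample microvascular score
#'
#' The score of a sample is the arithmetic mean of its linear-scale
#' expression over a vascular-enriched gene panel, estimating the relative
#' abundance of vasculature in the sample. If the panel values are on a
#' log2 scale, set `input_log2 = TRUE` to unlog them first; the function
#' never auto-detects the scale.
#'
#' @param panel a [region_panel()].
#' @param vascular_panel a [gene_set()] of vascular-enriched genes (panel
#'   genes missing from the matrix are warned about and skipped).
#' @param input_log2 unlog (2^x - 1) before scoring (default FALSE).
#' @param mean_fun `"arithmetic"` (default) or `"geometric"`.
#' @return Named numeric vector of strictly positive per-sample scores.
#' @export
microvascular_score <- function(panel, vascular_panel, input_log2 = FALSE,
                                mean_fun = c("arithmetic", "geometric")) {
  mean_fun <- match.arg(mean_fun)
  stopifnot(inherits(panel, "region_panel"))
  genes <- genes_of(vascular_panel)
  missing <- setdiff(genes, rownames(panel$values))
  if (length(missing))
    warning("vascular panel genes missing from panel: ", fmt_list(missing))
  genes <- intersect(genes, rownames(panel$values))
  if (!length(genes)) stop("no vascular panel gene is present in the panel")
  v <- panel$values[genes, , drop = FALSE]
  if (input_log2) v <- 2^v - 1
  scores <- if (mean_fun == "arithmetic") colMeans(v)
            else exp(colMeans(log(v)))
  zero <- names(scores)[!(scores > 0)]
  if (length(zero))
    stop("zero microvascular score blocks normalization for sample(s): ",
         fmt_list(zero))
  scores
}

#' Normalize a region panel by microvascular scores
#'
#' Divides every sample's column by its score. Scaling a sample's raw
#' column by any c > 0 scales its score by c too, so the normalized column
#' is exactly invariant to per-sample vascular abundance.
#'
#' @param panel a [region_panel()].
#' @param scores a [microvascular_score()] vector aligned to the panel's
#'   samples (same names).
#' @return A new [region_panel()] with normalized values.
#' @export
normalize_by_score <- function(panel, scores) {
  stopifnot(inherits(panel, "region_panel"))
  if (!setequal(names(scores), colnames(panel$values)) ||
      is.null(names(scores)))
    stop("scores are not aligned to the panel's samples")
  scores <- scores[colnames(panel$values)]
  if (any(!(scores > 0))) stop("scores must be strictly positive")
  region_panel(sweep(panel$values, 2, scores, "/"), panel$sample_meta)
}

#' Marker-set enrichment profile across anatomic regions
#'
#' For every marker set and region, the mean over set genes of the mean
#' normalized expression across that region's samples. Optionally each row
#' is z-scaled across regions for display; rows that are constant across
#' regions cannot be z-scaled and are reported as zeros with a flag.
#'
#' @param panel_norm a (typically score-normalized) [region_panel()].
#' @param marker_sets list of marker/gene sets; every set must have at
#'   least one gene present in the panel.
#' @param z_scale z-scale rows across regions for display (default FALSE).
#' @return List of class `enrichment_matrix` with `values` (sets x
#'   regions), `scaling` (`"none"` or `"row_z"`), `degenerate_rows`
#'   (constant rows zeroed under z-scaling), `missing_genes` per set.
#' @export
region_enrichment_profile <- function(panel_norm, marker_sets,
                                      z_scale = FALSE) {
  stopifnot(inherits(panel_norm, "region_panel"))
  regions <- unique(panel_norm$sample_meta$region)
  set_names <- vapply(marker_sets, function(s)
    if (inherits(s, "marker_set")) s$cluster else s$name, character(1))
  missing_genes <- list()
  m <- matrix(0, length(marker_sets), length(regions),
              dimnames = list(set_names, regions))
  gene_region_mean <- sapply(regions, function(r) {
    j <- panel_norm$sample_meta$region == r
    rowMeans(panel_norm$values[, j, drop = FALSE])
  })
  for (i in seq_along(marker_sets)) {
    genes <- genes_of(marker_sets[[i]])
    present <- intersect(genes, rownames(panel_norm$values))
    missing_genes[[set_names[i]]] <- setdiff(genes, present)
    if (!length(present))
      stop("no gene of set '", set_names[i], "' is present in the panel")
    m[i, ] <- colMeans(gene_region_mean[present, , drop = FALSE])
  }
  degenerate <- character()
  scaling <- "none"
  if (z_scale) {
    scaling <- "row_z"
    for (i in seq_len(nrow(m))) {
      s <- sd(m[i, ])
      if (s == 0) {
        degenerate <- c(degenerate, rownames(m)[i])
        m[i, ] <- 0
      } else m[i, ] <- (m[i, ] - mean(m[i, ])) / s
    }
  }
  structure(list(values = m, scaling = scaling,
                 degenerate_rows = degenerate,
                 missing_genes = missing_genes),
            class = "enrichment_matrix")
}
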