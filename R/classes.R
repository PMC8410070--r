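#' Single-cell count matrix container
#'
#' Bundles a sparse genes x cells matrix of nonnegative integer UMI counts
#' with gene symbols, cell barcodes, per-cell metadata (patient and region of
#' origin) and a per-gene mitochondrial flag. This is the object every
#' downstream stage consumes; it is validated on construction so failures
#' surface at the boundary, not deep in an analysis.
#'
#' @param values genes x cells matrix (dense or sparse) of nonnegative
#'   integer counts.
#' @param gene_symbols character vector of unique gene symbols, one per row.
#' @param barcodes character vector of unique cell barcodes, one per column.
#' @param cell_meta data.frame with columns `barcode`, `patient` and `region`
#'   (`"core"` or `"periphery"`), covering every barcode.
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes
#'   (default `"MT-"`, the human convention).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(values, gene_symbols, barcodes, cell_meta,
                         mito_prefix = "MT-") {
  values <- as_dgc(values)
  gene_symbols <- as.character(gene_symbols)
  barcodes <- as.character(barcodes)
  if (nrow(values) != length(gene_symbols))
    stop("count matrix has ", nrow(values), " rows but ",
         length(gene_symbols), " gene symbols")
  if (ncol(values) != length(barcodes))
    stop("count matrix has ", ncol(values), " columns but ",
         length(barcodes), " barcodes")
  dup_g <- unique(gene_symbols[duplicated(gene_symbols)])
  if (length(dup_g))
    stop("duplicate gene symbols: ", fmt_list(dup_g))
  dup_b <- unique(barcodes[duplicated(barcodes)])
  if (length(dup_b))
    stop("duplicate barcodes: ", fmt_list(dup_b))
  if (length(values@x) && (min(values@x) < 0 || any(values@x != floor(values@x))))
    stop("counts must be nonnegative integers")
  if (!is.data.frame(cell_meta) ||
      !all(c("barcode", "patient", "region") %in% names(cell_meta)))
    stop("cell_meta must be a data.frame with columns barcode, patient, region")
  missing_meta <- setdiff(barcodes, cell_meta$barcode)
  if (length(missing_meta))
    stop("cell_meta does not cover barcodes: ", fmt_list(missing_meta))
  bad_region <- setdiff(unique(cell_meta$region), c("core", "periphery"))
  if (length(bad_region))
    stop("unknown region labels: ", fmt_list(bad_region))
  cell_meta <- cell_meta[match(barcodes, cell_meta$barcode),
                         c("barcode", "patient", "region"), drop = FALSE]
  rownames(cell_meta) <- NULL
  dimnames(values) <- list(gene_symbols, barcodes)
  structure(list(values = values,
                 gene_symbols = gene_symbols,
                 barcodes = barcodes,
                 cell_meta = cell_meta,
                 mito_flag = startsWith(gene_symbols, mito_prefix),
                 mito_prefix = mito_prefix),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", length(x$gene_symbols), " genes x ",
      length(x$barcodes), " cells (",
      length(x$values@x), " nonzeros, ",
      sum(x$mito_flag), " mitochondrial genes)\n", sep = "")
  invisible(x)
}

# Column subset preserving metadata alignment.
#' @noRd
subset_cells <- function(cm, keep) {
  count_matrix(cm$values[, keep, drop = FALSE],
               cm$gene_symbols,
               cm$barcodes[keep],
               cm$cell_meta[keep, , drop = FALSE],
               mito_prefix = cm$mito_prefix)
}

#' Named gene set
#'
#' @param name set name (e.g. a cluster or module label).
#' @param description free-text description (second GMT field).
#' @param genes character vector of gene symbols; duplicates are collapsed
#'   with a warning, preserving first-occurrence order.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- as.character(genes)
  if (!length(genes)) stop("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) {
    warning("gene set '", name, "' contains duplicate symbols: ",
            fmt_list(unique(genes[duplicated(genes)])))
    genes <- genes[!duplicated(genes)]
  }
  structure(list(name = as.character(name),
                 description = as.character(description),
                 genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$genes), " genes (",
      fmt_list(x$genes, 4), ")\n", sep = "")
  invisible(x)
}

#' Ranked marker set for one cluster
#'
#' A thin wrapper pairing a cluster identifier with its ranked top-k
#' [gene_set()]; produced by [top_k_markers()] and consumed by the
#' cross-atlas similarity functions.
#'
#' @param cluster cluster identifier (coerced to character).
#' @param genes ranked character vector of marker symbols.
#' @param n_available number of significant genes the set was drawn from.
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(cluster, genes, n_available = length(genes)) {
  structure(list(cluster = as.character(cluster),
                 genes = gene_set(cluster, genes),
                 n_available = as.integer(n_available)),
            class = "marker_set")
}

#' Bulk expression panel (genes x samples, CPM scale)
#'
#' @param values genes x samples numeric matrix on the counts-per-million
#'   scale; every column must sum to 1e6 (relative tolerance 1e-6).
#' @param sample_meta data.frame with columns `sample`, `group`, `replicate`.
#' @param groups_required character vector of groups that must be present
#'   (set to `NULL` to skip the check).
#' @return An object of class `bulk_panel`.
#' @export
bulk_panel <- function(values, sample_meta,
                       groups_required = c("brain_EC", "kidney_EC", "lung_EC",
                                           "heart_EC", "liver_EC",
                                           "brain_vasculature")) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("bulk panel values need gene rownames")
  if (!all(c("sample", "group", "replicate") %in% names(sample_meta)))
    stop("sample_meta must have columns sample, group, replicate")
  if (ncol(values) != nrow(sample_meta))
    stop("bulk panel has ", ncol(values), " samples but metadata has ",
         nrow(sample_meta), " rows")
  colnames(values) <- sample_meta$sample
  cs <- colSums(values)
  off <- abs(cs - 1e6) / 1e6
  if (any(off > 1e-6))
    stop("samples are not CPM-closed (column sums differ from 1e6): ",
         fmt_list(sample_meta$sample[off > 1e-6]))
  if (!is.null(groups_required)) {
    missing <- setdiff(groups_required, unique(sample_meta$group))
    if (length(missing)) stop("bulk panel is missing groups: ", fmt_list(missing))
  }
  structure(list(values = values, sample_meta = sample_meta),
            class = "bulk_panel")
}

#' Region-labelled bulk panel (anatomic structures)
#'
#' @param values genes x samples nonnegative numeric matrix (linear scale).
#' @param sample_meta data.frame with columns `sample` and `region`; regions
#'   must come from the five named glioblastoma anatomic structures.
#' @return An object of class `region_panel`.
#' @export
region_panel <- function(values, sample_meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("region panel values need gene rownames")
  if (!all(c("sample", "region") %in% names(sample_meta)))
    stop("sample_meta must have columns sample, region")
  if (ncol(values) != nrow(sample_meta))
    stop("region panel has ", ncol(values), " samples but metadata has ",
         nrow(sample_meta), " rows")
  bad <- setdiff(unique(sample_meta$region), anatomic_regions())
  if (length(bad)) stop("unknown anatomic regions: ", fmt_list(bad))
  if (any(!is.finite(values)) || any(values < 0))
    stop("region panel values must be finite and nonnegative")
  colnames(values) <- sample_meta$sample
  structure(list(values = values, sample_meta = sample_meta),
            class = "region_panel")
}

#' The five glioblastoma anatomic-region labels
#' @return Character vector of region names.
#' @export
anatomic_regions <- function() {
  c("leading_edge", "infiltrating_tumor", "cellular_tumor",
    "microvascular_proliferation", "pseudopalisading_necrosis")
}

#' The four brain-disease model labels of the dysfunction module
#' @return Character vector of model names.
#' @export
disease_models <- function() {
  c("stroke", "multiple_sclerosis", "traumatic_brain_injury", "seizure")
}
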