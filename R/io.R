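# Readers and writers for every on-disk format the pipeline touches, so the
# analysis modules stay format-agnostic. Matrix Market coordinate files are
# 1-based on disk (handled by Matrix::readMM/writeMM); all tables are TSV
# with a header row; gene sets use the standard GMT dialect; manifests and
# module audits are JSON.

#' Read a Cell-Ranger-style count triple
#'
#' Reads a Matrix Market counts file plus its features/barcodes sidecars and
#' a per-cell metadata table into a validated [count_matrix()]. Gene and
#' barcode order on disk is preserved.
#'
#' @param matrix_path Matrix Market coordinate file (genes x cells).
#' @param features_path one feature per line; first tab-separated field is
#'   the gene symbol.
#' @param barcodes_path one barcode per line.
#' @param meta_path TSV keyed by `barcode` with columns `patient`, `region`.
#' @param mito_prefix symbol prefix marking mitochondrial genes.
#' @return A [count_matrix()].
#' @export
read_counts <- function(matrix_path, features_path, barcodes_path, meta_path,
                        mito_prefix = "MT-") {
  for (p in c(matrix_path, features_path, barcodes_path, meta_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  m <- as_dgc(Matrix::readMM(matrix_path))
  feats <- readLines(features_path)
  feats <- feats[nzchar(feats)]
  symbols <- vapply(strsplit(feats, "\t", fixed = TRUE), `[[`, character(1), 1)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != length(symbols))
    stop("dimension mismatch: ", matrix_path, " has ", nrow(m),
         " rows but ", features_path, " lists ", length(symbols), " features")
  if (ncol(m) != length(barcodes))
    stop("dimension mismatch: ", matrix_path, " has ", ncol(m),
         " columns but ", barcodes_path, " lists ", length(barcodes),
         " barcodes")
  meta <- read.delim(meta_path, sep = "\t", stringsAsFactors = FALSE,
                     colClasses = "character")
  count_matrix(m, symbols, barcodes, meta, mito_prefix = mito_prefix)
}

#' Write a count matrix as a Cell-Ranger-style triple
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(cm))` reproduces
#' `cm` exactly (values, symbols, barcodes and metadata).
#'
#' @param cm a [count_matrix()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_counts <- function(cm, out_dir) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             features = file.path(out_dir, "features.tsv"),
             barcodes = file.path(out_dir, "barcodes.tsv"),
             meta = file.path(out_dir, "cell_meta.tsv"))
  v <- cm$values
  dimnames(v) <- NULL
  Matrix::writeMM(v, paths[["matrix"]])
  writeLines(cm$gene_symbols, paths[["features"]])
  writeLines(cm$barcodes, paths[["barcodes"]])
  write.table(cm$cell_meta, paths[["meta"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then gene symbols, tab-separated.
#' Within-set duplicate symbols are collapsed with a warning.
#'
#' @param gmt_path path to a GMT file.
#' @return List of [gene_set()] objects (empty list for an empty file).
#' @export
read_gene_sets <- function(gmt_path) {
  if (!file.exists(gmt_path)) stop("input file not found: ", gmt_path)
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line ", i, " in ", gmt_path,
           ": expected >= 3 tab-separated fields, got ", length(fields))
    sets[[i]] <- gene_set(fields[1], fields[-(1:2)], description = fields[2])
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] (or [marker_set()]) objects.
#' @param gmt_path output path.
#' @return `gmt_path`, invisibly.
#' @export
write_gene_sets <- function(sets, gmt_path) {
  lines <- vapply(sets, function(s) {
    if (inherits(s, "marker_set")) s <- s$genes
    paste(c(s$name, if (nzchar(s$description)) s$description else ".",
            s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, gmt_path)
  invisible(gmt_path)
}

#' Write a manifest (or any JSON-serializable list) to disk
#'
#' @param x named list; scalars, vectors and nested lists of character /
#'   numeric / logical values.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a manifest written by [write_manifest()]
#' @param path JSON path.
#' @return The deserialized list.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

# --- generic TSV helpers -----------------------------------------------------

#' @noRd
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' @noRd
write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' @noRd
read_matrix_tsv <- function(path, id_col = "gene") {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# --- typed panels ------------------------------------------------------------

#' Write / read a multi-organ bulk EC panel
#'
#' The panel is stored as a genes x samples TSV plus a `<path>.meta.tsv`
#' sidecar holding sample, group and replicate columns.
#'
#' @param panel a [bulk_panel()].
#' @param path values TSV path.
#' @return `path` invisibly (writer); a [bulk_panel()] (reader).
#' @export
write_bulk_panel <- function(panel, path) {
  stopifnot(inherits(panel, "bulk_panel"))
  write_matrix_tsv(panel$values, path)
  write_tsv(panel$sample_meta, paste0(path, ".meta.tsv"))
  invisible(path)
}

#' @rdname write_bulk_panel
#' @export
read_bulk_panel <- function(path) {
  bulk_panel(read_matrix_tsv(path), read_tsv(paste0(path, ".meta.tsv")))
}

#' Write / read a region-labelled anatomic panel
#'
#' @param panel a [region_panel()].
#' @param path values TSV path (a `<path>.meta.tsv` sidecar carries regions).
#' @return `path` invisibly (writer); a [region_panel()] (reader).
#' @export
write_region_panel <- function(panel, path) {
  stopifnot(inherits(panel, "region_panel"))
  write_matrix_tsv(panel$values, path)
  write_tsv(panel$sample_meta, paste0(path, ".meta.tsv"))
  invisible(path)
}

#' @rdname write_region_panel
#' @export
read_region_panel <- function(path) {
  region_panel(read_matrix_tsv(path), read_tsv(paste0(path, ".meta.tsv")))
}

#' Write / read a disease-model differential table
#'
#' Long TSV with columns `gene`, `model`, `direction` (up / down / ns);
#' every gene must carry a call for each of the four brain-disease models.
#'
#' @param tbl data.frame in the long format above.
#' @param path TSV path.
#' @return `path` invisibly (writer); the validated data.frame (reader).
#' @export
write_disease_table <- function(tbl, path) {
  validate_disease_table(tbl)
  write_tsv(tbl, path)
}

#' @rdname write_disease_table
#' @export
read_disease_table <- function(path) {
  validate_disease_table(read_tsv(path))
}

#' @noRd
validate_disease_table <- function(tbl) {
  if (!all(c("gene", "model", "direction") %in% names(tbl)))
    stop("disease table needs columns gene, model, direction")
  bad_model <- setdiff(unique(tbl$model), disease_models())
  if (length(bad_model)) stop("unknown disease models: ", fmt_list(bad_model))
  bad_dir <- setdiff(unique(tbl$direction), c("up", "down", "ns"))
  if (length(bad_dir)) stop("unknown directions: ", fmt_list(bad_dir))
  counts <- table(tbl$gene)
  if (any(counts != 4))
    stop("every gene needs exactly 4 model calls; offending genes: ",
         fmt_list(names(counts)[counts != 4]))
  dup <- tbl[duplicated(tbl[c("gene", "model")]), ]
  if (nrow(dup)) stop("duplicate (gene, model) rows: ", fmt_list(dup$gene))
  tbl
}

#' Write / read a two-column homolog map
#'
#' @param map data.frame with columns `source` and `target` symbols.
#' @param path TSV path.
#' @return `path` invisibly (writer); the data.frame (reader).
#' @export
write_homolog_map <- function(map, path) {
  if (!all(c("source", "target") %in% names(map)))
    stop("homolog map needs columns source, target")
  write_tsv(map[c("source", "target")], path)
}

#' @rdname write_homolog_map
#' @export
read_homolog_map <- function(path) {
  map <- read_tsv(path)
  if (!all(c("source", "target") %in% names(map)))
    stop("homolog map needs columns source, target")
  map
}
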