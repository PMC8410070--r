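# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
as_dgc <- function(x) {
  if (inherits(x, "dgCMatrix")) return(x)
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

# Deterministic per-stage seed derived from the run seed; kept below 2^31.
#' @noRd
stage_seed <- function(seed, stage) {
  ch <- utf8ToInt(stage)
  h <- sum(ch * seq_along(ch))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483629)
}

#' @noRd
file_digest <- function(path) unname(tools::md5sum(path))

# Largest-remainder apportionment: integer counts summing to round(sum(x)).
#' @noRd
exact_counts <- function(x) {
  n <- round(sum(x))
  base <- floor(x)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- x - base
    take <- order(frac, seq_along(x), decreasing = c(TRUE, FALSE),
                  method = "radix")[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' @noRd
fmt_list <- function(x, limit = 5) {
  x <- as.character(x)
  if (length(x) > limit) {
    paste0(paste(x[seq_len(limit)], collapse = ", "), ", ... (",
           length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}

# Extract a genes x cells values matrix plus symbols from the containers the
# analysis functions accept (normalized_matrix, count_matrix, plain matrix).
#' @noRd
values_of <- function(x) {
  if (inherits(x, c("normalized_matrix", "count_matrix"))) {
    v <- x$values
    rownames(v) <- x$gene_symbols
    colnames(v) <- x$barcodes
    return(v)
  }
  if (is.matrix(x) || inherits(x, "Matrix")) {
    if (is.null(rownames(x))) stop("matrix input must carry gene symbols as rownames")
    return(x)
  }
  stop("unsupported matrix container of class ", paste(class(x), collapse = "/"))
}

#' @noRd
genes_of <- function(x) {
  if (inherits(x, "gene_set")) return(x$genes)
  if (inherits(x, "marker_set")) return(x$genes$genes)
  if (inherits(x, "module_definition")) return(x$genes)
  if (is.character(x)) return(x)
  stop("cannot extract genes from class ", paste(class(x), collapse = "/"))
}
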