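# Construction of the core blood-brain-barrier (BBB) module from a
# multi-organ bulk EC panel, the BBB dysfunction module from disease-model
# differential calls, homolog mapping, restriction to genes detected in a
# single-cell dataset, and module coexpression analysis. Every gene ever
# considered carries a full audit of which criteria it passed, and the
# provenance chain (raw -> homolog-mapped -> detected) is preserved.

#' @noRd
module_definition <- function(name, genes, audit, provenance) {
  structure(list(name = name, genes = genes, audit = audit,
                 provenance = provenance),
            class = "module_definition")
}

#' @export
print.module_definition <- function(x, ...) {
  cat("module '", x$name, "': ", length(x$genes), " genes after ",
      length(x$provenance), " stage(s) [",
      paste(vapply(x$provenance, `[[`, character(1), "stage"),
            collapse = " -> "), "]\n", sep = "")
  invisible(x)
}

#' Build the core BBB module from a multi-organ bulk EC panel
#'
#' A gene enters the module iff it passes all three criteria:
#' (a) mean brain-EC expression of at least `min_cpm` CPM (inclusive);
#' (b) for each of the four peripheral organs individually, a brain/organ
#' mean ratio strictly greater than `min_fold` AND a rank-sum p below
#' `alpha` on the replicate values;
#' (c) mean brain-EC expression no less than mean brain-vasculature
#' expression (inclusive; excludes mural-cell contamination).
#'
#' @param panel a [bulk_panel()] with >= 2 replicates per group.
#' @param min_cpm criterion (a) floor, inclusive (default 100 CPM).
#' @param min_fold criterion (b) ratio, strict (default 2).
#' @param alpha criterion (b) p cutoff (default 0.05).
#' @param test `"ranksum"` (default) or `"ttest"` for criterion (b).
#' @return A `module_definition`; its `audit` data.frame has one row per
#'   input gene with per-criterion outcomes and, for rejected genes, the
#'   first failing criterion (`"a"`, `"b:<organ>"`, or `"c"`).
#' @export
build_core_module <- function(panel, min_cpm = 100, min_fold = 2,
                              alpha = 0.05, test = c("ranksum", "ttest")) {
  test <- match.arg(test)
  stopifnot(inherits(panel, "bulk_panel"))
  meta <- panel$sample_meta
  organs <- c("kidney_EC", "lung_EC", "heart_EC", "liver_EC")
  reps <- table(meta$group)
  if (any(reps < 2))
    stop("criterion (b) needs >= 2 replicates per group; short groups: ",
         fmt_list(names(reps)[reps < 2]))
  v <- panel$values
  grp_cols <- split(seq_len(ncol(v)), meta$group)
  means <- sapply(grp_cols, function(j) rowMeans(v[, j, drop = FALSE]))
  genes <- rownames(v)
  pass_a <- means[, "brain_EC"] >= min_cpm
  pass_c <- means[, "brain_EC"] >= means[, "brain_vasculature"]
  audit <- data.frame(gene = genes, pass_a = pass_a,
                      brain_mean = means[, "brain_EC"],
                      vasc_mean = means[, "brain_vasculature"],
                      pass_c = pass_c, stringsAsFactors = FALSE)
  brain_j <- grp_cols[["brain_EC"]]
  for (org in organs) {
    fold <- means[, "brain_EC"] / means[, org]
    fold[is.nan(fold)] <- 0   # 0/0: no evidence of enrichment
    pv <- numeric(length(genes))
    org_j <- grp_cols[[org]]
    for (g in seq_along(genes)) {
      pv[g] <- if (test == "ranksum")
        rank_sum_test(v[g, brain_j], v[g, org_j])$p_value
      else stats::t.test(v[g, brain_j], v[g, org_j])$p.value
    }
    audit[[paste0("fold_", org)]] <- fold
    audit[[paste0("p_", org)]] <- pv
    audit[[paste0("pass_b_", org)]] <- fold > min_fold & pv < alpha
  }
  pass_b_all <- Reduce(`&`, lapply(organs, function(org)
    audit[[paste0("pass_b_", org)]]))
  audit$included <- pass_a & pass_b_all & pass_c
  fail <- rep(NA_character_, length(genes))
  for (g in which(!audit$included)) {
    fail[g] <- if (!pass_a[g]) "a" else {
      bad <- organs[!vapply(organs, function(org)
        audit[[paste0("pass_b_", org)]][g], logical(1))]
      if (length(bad)) paste0("b:", bad[1]) else "c"
    }
  }
  audit$fail_reason <- fail
  module_definition(
    "BBB_core", genes[audit$included], audit,
    list(list(stage = "raw",
              genes = genes[audit$included],
              params = list(min_cpm = min_cpm, min_fold = min_fold,
                            alpha = alpha, test = test))))
}

#' Build the BBB dysfunction module from disease-model calls
#'
#' A gene enters the module iff it is called "up" in at least `min_models`
#' of the four brain-disease models (stroke, multiple sclerosis, traumatic
#' brain injury, seizure).
#'
#' @param tbl long data.frame (gene, model, direction) covering all four
#'   models per gene.
#' @param min_models vote threshold (default 3).
#' @return A `module_definition`; the audit lists the voting models per gene.
#' @export
build_dysfunction_module <- function(tbl, min_models = 3) {
  tbl <- validate_disease_table(tbl)
  genes <- unique(tbl$gene)
  up_models <- lapply(setNames(genes, genes), function(g)
    tbl$model[tbl$gene == g & tbl$direction == "up"])
  n_up <- vapply(up_models, length, integer(1))
  audit <- data.frame(gene = genes, n_up = n_up,
                      voting_models = vapply(up_models, paste,
                                             character(1), collapse = ","),
                      included = n_up >= min_models,
                      stringsAsFactors = FALSE)
  module_definition(
    "BBB_dysfunction", genes[audit$included], audit,
    list(list(stage = "raw", genes = genes[audit$included],
              params = list(min_models = min_models))))
}

#' Map module genes across species
#'
#' Renames module genes through a source-to-target homolog map. Genes
#' without a map entry are moved to the stage's `dropped` list (never
#' silently discarded). One-to-many source rows are resolved by keeping the
#' lexicographically smallest target and logging the alternatives; mappings
#' that would collide on a target symbol raise an error.
#'
#' @param m a `module_definition`.
#' @param hm data.frame with columns `source`, `target`.
#' @return The module with renamed genes and an appended provenance stage.
#' @export
map_homologs <- function(m, hm) {
  stopifnot(inherits(m, "module_definition"))
  if (!all(c("source", "target") %in% names(hm)))
    stop("homolog map needs columns source, target")
  alternatives <- list()
  if (anyDuplicated(hm$source)) {
    keep <- unlist(lapply(split(seq_len(nrow(hm)), hm$source), function(i) {
      i <- i[order(hm$target[i])]
      if (length(i) > 1)
        alternatives[[hm$source[i[1]]]] <<- hm$target[i[-1]]
      i[1]
    }), use.names = FALSE)
    hm <- hm[keep, , drop = FALSE]
  }
  idx <- match(m$genes, hm$source)
  dropped <- m$genes[is.na(idx)]
  mapped <- hm$target[idx[!is.na(idx)]]
  dup <- unique(mapped[duplicated(mapped)])
  if (length(dup))
    stop("homolog mapping collides on target symbols: ", fmt_list(dup))
  prov <- c(m$provenance,
            list(list(stage = "homolog_mapped", genes = mapped,
                      dropped = dropped,
                      source_genes = m$genes[!is.na(idx)],
                      one_to_many_alternatives = alternatives)))
  module_definition(m$name, mapped, m$audit, prov)
}

#' Restrict a module to genes detected in a single-cell dataset
#'
#' @param m a `module_definition`.
#' @param nm a [normalize_counts()] result (or genes x cells matrix).
#' @param min_cells a gene is "detected" when nonzero in at least this many
#'   cells (default 1).
#' @return The module restricted to detected genes, with removed genes
#'   recorded in the appended provenance stage.
#' @export
restrict_to_detected <- function(m, nm, min_cells = 1) {
  stopifnot(inherits(m, "module_definition"))
  values <- values_of(nm)
  n_cells_expr <- setNames(rep(0L, length(m$genes)), m$genes)
  present <- intersect(m$genes, rownames(values))
  if (length(present))
    n_cells_expr[present] <-
      as.integer(Matrix::rowSums(values[present, , drop = FALSE] > 0))
  detected <- m$genes[n_cells_expr[m$genes] >= min_cells]
  removed <- setdiff(m$genes, detected)
  prov <- c(m$provenance,
            list(list(stage = "detected", genes = detected, dropped = removed,
                      params = list(min_cells = min_cells))))
  module_definition(m$name, detected, m$audit, prov)
}

#' Module coexpression analysis on EC single cells
#'
#' Correlates all genes of the core and dysfunction modules across EC
#' cells, orders them by average-linkage hierarchical clustering of
#' `1 - r` for stable block display, and reports the mean off-diagonal
#' correlation within each module and across the two.
#'
#' @param nm_ec EC-restricted [normalize_counts()] result (or genes x cells
#'   matrix), >= 3 cells.
#' @param core,dysf `module_definition`s (or gene vectors) with >= 2 usable
#'   genes each.
#' @param method correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @return List of class `coexpression_summary` with the
#'   [correlation_matrix()], the display `gene_order`, and
#'   `mean_within_core`, `mean_within_dysf`, `mean_cross`.
#' @export
module_coexpression <- function(nm_ec, core, dysf,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  core_genes <- genes_of(core)
  dysf_genes <- genes_of(dysf)
  cm <- correlation_matrix(nm_ec, unique(c(core_genes, dysf_genes)), method)
  usable <- rownames(cm$r)
  core_u <- intersect(core_genes, usable)
  dysf_u <- intersect(dysf_genes, usable)
  if (length(core_u) < 2)
    stop("core module has fewer than 2 usable (present, varying) genes")
  if (length(dysf_u) < 2)
    stop("dysfunction module has fewer than 2 usable (present, varying) genes")
  off_mean <- function(rows, cols) {
    block <- cm$r[rows, cols, drop = FALSE]
    if (identical(rows, cols)) {
      n <- length(rows)
      (sum(block) - n) / (n * (n - 1))
    } else mean(block)
  }
  hc <- hclust(as.dist(1 - cm$r), method = "average")
  structure(list(correlation = cm,
                 gene_order = rownames(cm$r)[hc$order],
                 core_genes = core_u, dysf_genes = dysf_u,
                 mean_within_core = off_mean(core_u, core_u),
                 mean_within_dysf = off_mean(dysf_u, dysf_u),
                 mean_cross = off_mean(core_u, dysf_u),
                 method = method),
            class = "coexpression_summary")
}

#' @export
print.coexpression_summary <- function(x, ...) {
  cat("module coexpression (", x$method, "): within-core ",
      round(x$mean_within_core, 3), ", within-dysfunction ",
      round(x$mean_within_dysf, 3), ", cross ",
      round(x$mean_cross, 3), "\n", sep = "")
  invisible(x)
}

#' Serialize a module with its audit sidecar
#'
#' Writes the gene set as a one-line GMT and the audit plus provenance
#' chain as JSON next to it.
#'
#' @param m a `module_definition`.
#' @param gmt_path output GMT path (audit goes to `<path>.audit.json`).
#' @return `gmt_path`, invisibly.
#' @export
write_module <- function(m, gmt_path) {
  stopifnot(inherits(m, "module_definition"))
  write_gene_sets(list(gene_set(m$name, m$genes, "module definition")),
                  gmt_path)
  write_manifest(list(name = m$name, audit = m$audit,
                      provenance = m$provenance),
                 paste0(gmt_path, ".audit.json"))
  invisible(gmt_path)
}
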