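# QC boundaries, normalization closed forms, clustering determinism and
# truth recovery, annotation, EC selection and doublet flagging.

make_qc_fixture <- function() {
  # 4 cells: high-mito, low-genes, exactly-at-boundary, healthy
  genes <- c("MT-CO1", sprintf("G%03d", 1:299))
  n_detect <- function(total, k) {
    v <- integer(300)
    v[seq_len(k) + 1] <- 1L
    v[2] <- v[2] + (total - k)
    v
  }
  m <- cbind(
    himito = c(30L, rep(1L, 200), rep(0L, 99)),     # mito 30/230 > 0.10
    lowgen = n_detect(500, 149),                    # 149 detected genes
    bound = c(30L, n_detect(300 - 30, 199)[-1]),    # 0.10 mito, 200 genes
    healthy = c(2L, rep(1L, 250), rep(0L, 49)))
  bcs <- colnames(m)
  count_matrix(m, genes, bcs,
               data.frame(barcode = bcs, patient = "P1", region = "core"))
}

test_that("qc_filter applies strict boundaries with per-cell reasons", {
  cm <- make_qc_fixture()
  mito_frac <- Matrix::colSums(cm$values[cm$mito_flag, , drop = FALSE]) /
    Matrix::colSums(cm$values)
  detected <- Matrix::colSums(cm$values > 0)
  expect_gt(unname(mito_frac["himito"]), 0.10)
  expect_equal(unname(mito_frac["bound"]), 0.10)
  expect_equal(unname(detected[c("lowgen", "bound")]), c(149, 200))
  res <- qc_filter(cm)
  expect_setequal(res$report$barcode, c("himito", "lowgen"))
  expect_equal(res$report$reason[res$report$barcode == "himito"], "mito")
  expect_equal(res$report$reason[res$report$barcode == "lowgen"], "min_genes")
  # exactly 10% mito with exactly 200 genes is retained (strict inequalities)
  expect_true(all(c("bound", "healthy") %in% res$counts$barcodes))
  expect_identical(res$counts$gene_symbols, cm$gene_symbols)
})

test_that("qc_filter is idempotent and errors rather than empty out", {
  res <- qc_filter(small_atlas()$sim$counts)
  again <- qc_filter(res$counts)
  expect_equal(nrow(again$report), 0)
  expect_identical(again$counts$barcodes, res$counts$barcodes)
  tiny <- count_matrix(matrix(c(5L, 5L), 2, 1), c("MT-CO1", "G1"), "B1",
                       data.frame(barcode = "B1", patient = "P1",
                                  region = "core"))
  expect_error(qc_filter(tiny), "every cell")
})

test_that("qc removes exactly the planted failures on synthetic data", {
  s <- small_atlas()
  flagged <- names(s$sim$truth$qc_fail_flag)[s$sim$truth$qc_fail_flag]
  expect_setequal(s$qc$report$barcode, flagged)
})

test_that("normalization matches its closed form", {
  m <- matrix(0L, 3, 1)
  m[1, 1] <- 10L; m[2, 1] <- 9990L
  cm <- count_matrix(m, c("A", "B", "C"), "B1",
                     data.frame(barcode = "B1", patient = "P1",
                                region = "core"))
  nm <- normalize_counts(cm, qc_thresholds(scale_factor = 10000))
  expect_equal(as.numeric(nm$values[1, 1]), log1p(10), tolerance = 1e-12)
  expect_equal(as.numeric(nm$values[3, 1]), 0)
  # doubling all counts of a cell leaves its normalized vector unchanged
  cm2 <- count_matrix(m * 2L, c("A", "B", "C"), "B1",
                      data.frame(barcode = "B1", patient = "P1",
                                 region = "core"))
  expect_equal(as.matrix(normalize_counts(cm2)$values),
               as.matrix(nm$values))
})

test_that("normalization commutes with cell subsetting and rejects zeros", {
  s <- small_atlas()
  cm <- s$qc$counts
  keep <- seq(1, length(cm$barcodes), by = 3)
  nm_then_subset <- ecatlas:::subset_nm(normalize_counts(cm), keep)
  subset_then_nm <- normalize_counts(ecatlas:::subset_cells(cm, keep))
  expect_equal(as.matrix(nm_then_subset$values),
               as.matrix(subset_then_nm$values))
  zero <- count_matrix(matrix(c(1L, 0L), 1, 2), "A", c("B1", "B2"),
                       data.frame(barcode = c("B1", "B2"), patient = "P1",
                                  region = "core"))
  expect_error(normalize_counts(zero), "B2")
})

test_that("clustering is deterministic and recovers well-separated classes", {
  s <- small_atlas()
  a <- cluster_cells(s$nm, n_pcs = 15, k = 9, seed = 1)
  b <- cluster_cells(s$nm, n_pcs = 15, k = 9, seed = 1)
  expect_identical(a$labels, b$labels)
  # two planted classes, k = 2: perfect recovery at high effect size
  cfg <- sim_config(seed = 3, n_cells = 200, n_genes = 200,
                    cell_class_proportions = c(EC = 0.5, macrophage = 0.5),
                    n_ec_subclusters = 2,
                    ec_subcluster_proportions = c(0.5, 0.5),
                    markers_per_cluster = 8, marker_lfc = 3, class_lfc = 3,
                    class_markers_per_class = c(EC = 15, macrophage = 10),
                    n_region_genes = 5, n_bbb_core = 2, n_bbb_dysf = 2,
                    frac_qc_fail = 0, frac_doublets = 0)
  sim <- simulate_atlas(cfg)
  nm <- normalize_counts(sim$counts)
  cl <- cluster_cells(nm, n_pcs = 10, k = 2, seed = 1)
  truth <- sim$truth$cell_class[nm$barcodes]
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  # graph-community path is deterministic too and finds >= 2 communities
  g1 <- cluster_cells(nm, n_pcs = 10, resolution = 1, seed = 2)
  g2 <- cluster_cells(nm, n_pcs = 10, resolution = 1, seed = 2)
  expect_identical(g1$labels, g2$labels)
  expect_gte(g1$n_clusters, 2)
  expect_error(cluster_cells(nm, n_pcs = 10, k = 10^6), "exceeds")
  expect_error(cluster_cells(nm, n_pcs = 10), "exactly one")
})

test_that("cluster labels are contiguous, 1-based and non-empty", {
  cl <- small_atlas()$clusters
  expect_setequal(unique(cl$labels), seq_len(cl$n_clusters))
})

test_that("annotation assigns canonical classes and breaks ties by order", {
  s <- small_atlas()
  ann <- s$annotation
  # every cluster's assigned class is the majority planted class
  truth <- s$sim$truth$cell_class[s$nm$barcodes]
  for (cl in names(ann$cluster_class)) {
    cells <- s$clusters$labels == as.integer(cl)
    major <- names(sort(table(truth[cells]), decreasing = TRUE))[1]
    if (major != "doublet")
      expect_identical(unname(ann$cluster_class[cl]), major)
  }
  # a cluster expressing only the EC panel is annotated EC; exact ties go to
  # the first panel in declared order
  genes <- c("CLDN5", "VWF", "CD34", "APOC1", "CD163", "F13A1")
  m <- cbind(ec1 = c(5L, 5L, 5L, 0L, 0L, 0L), ec2 = c(4L, 6L, 5L, 0L, 0L, 0L),
             tie = c(3L, 3L, 3L, 3L, 3L, 3L), tie2 = c(2L, 2L, 2L, 2L, 2L, 2L))
  cm <- count_matrix(m, genes, colnames(m),
                     data.frame(barcode = colnames(m), patient = "P1",
                                region = "core"))
  nm <- normalize_counts(cm)
  panels <- list(gene_set("EC", c("CLDN5", "VWF", "CD34")),
                 gene_set("macrophage", c("APOC1", "CD163", "F13A1")))
  lab <- setNames(c(1L, 1L, 2L, 2L), colnames(m))
  ann2 <- annotate_clusters(nm, lab, panels)
  expect_identical(unname(ann2$cluster_class), c("EC", "EC"))
  expect_equal(ann2$ties$cluster, 2)
  expect_error(suppressWarnings(
    annotate_clusters(nm, lab, list(gene_set("ghost", "NOPE")))), "ghost")
})

test_that("EC selection keeps pure EC cells and flags planted doublets", {
  cfg <- sim_config(seed = 42)
  s <- simulate_atlas(cfg)
  qc <- qc_filter(s$counts)
  nm <- normalize_counts(qc$counts)
  truth_cls <- s$truth$cell_class[nm$barcodes]
  # truth-derived clusters with doublets placed in the EC cluster: isolates
  # the flagging rule from clustering behaviour
  lab <- setNames(as.integer(factor(ifelse(truth_cls == "doublet", "EC",
                                           truth_cls))), nm$barcodes)
  ann <- annotate_clusters(nm, lab, s$class_panels)
  sel <- select_ecs(nm, lab, ann, s$class_panels)
  db <- names(truth_cls)[truth_cls == "doublet"]
  pure <- names(truth_cls)[truth_cls == "EC"]
  recall <- mean(db %in% sel$report$barcode)
  specificity <- 1 - mean(pure %in% sel$report$barcode)
  expect_gte(recall, 0.8)
  expect_gte(specificity, 0.99)
  # retained matrix is EC cells minus flagged
  expect_true(all(sel$nm_ec$barcodes %in% c(pure, db)))
  # a pure EC cell at the median EC score is retained
  values <- nm$values; rownames(values) <- nm$gene_symbols
  ec_panel <- s$class_panels$EC$genes
  esc <- Matrix::colSums(values[ec_panel, pure]) / length(ec_panel)
  med_cell <- names(which.min(abs(esc - median(esc))))
  expect_true(med_cell %in% sel$nm_ec$barcodes)
})

test_that("a doublet-free run yields (near) zero flags", {
  cfg <- sim_config(seed = 7, frac_doublets = 0, n_cells = 1500)
  s <- simulate_atlas(cfg)
  nm <- normalize_counts(qc_filter(s$counts)$counts)
  truth_cls <- s$truth$cell_class[nm$barcodes]
  lab <- setNames(as.integer(factor(truth_cls)), nm$barcodes)
  ann <- annotate_clusters(nm, lab, s$class_panels)
  sel <- select_ecs(nm, lab, ann, s$class_panels)
  expect_gte(1 - nrow(sel$report) / sum(truth_cls == "EC"), 0.99)
  expect_error(select_ecs(nm, lab,
                          structure(list(cluster_class = c(`1` = "mural")),
                                    class = "class_annotation"),
                          s$class_panels),
               "no cluster")
})
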