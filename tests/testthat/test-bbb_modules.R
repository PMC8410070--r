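# Core-module criteria with exact boundaries, dysfunction vote, homolog
# mapping, detection restriction and module coexpression.

test_that("core-module boundaries follow the stated inequalities exactly", {
  m <- build_core_module(boundary_panel())
  expect_true("at_cpm" %in% m$genes)     # >= 100 CPM is inclusive
  expect_true("at_vasc" %in% m$genes)    # "no less than" vasculature
  expect_true("clean" %in% m$genes)
  expect_false("at_fold" %in% m$genes)   # "more than 2-fold" is strict
  expect_false("below_cpm" %in% m$genes)
  aud <- m$audit
  expect_equal(aud$fail_reason[aud$gene == "at_fold"], "b:liver_EC")
  expect_equal(aud$fail_reason[aud$gene == "below_cpm"], "a")
})

test_that("core-module audit accounts for every input gene", {
  b <- simulate_bulk_organ_panel(brain_enriched = 8, n_genes = 120, seed = 5)
  m <- build_core_module(b$panel)
  expect_setequal(m$audit$gene, rownames(b$panel$values))
  expect_true(all(xor(m$audit$included, !is.na(m$audit$fail_reason))))
  expect_setequal(m$genes, b$truth$brain_enriched_genes)
  # a decoy failing 3-of-4 organ folds is rejected with the failing organ named
  expect_match(m$audit$fail_reason[m$audit$gene ==
                                     b$truth$decoys$sub_fold[1]], "^b:")
})

test_that("missing groups and short replication are rejected", {
  b <- simulate_bulk_organ_panel(brain_enriched = 4, n_genes = 60, seed = 6)
  v <- b$panel$values
  meta <- b$panel$sample_meta
  keep <- meta$group != "liver_EC"
  expect_error(bulk_panel(v[, keep], meta[keep, ]), "liver_EC")
  one_rep <- meta$group != "kidney_EC" | meta$replicate == 1
  panel1 <- bulk_panel(v[, one_rep], meta[one_rep, ])
  expect_error(build_core_module(panel1), "kidney_EC")
})

test_that("dysfunction vote equals brute force over all 16 patterns", {
  tbl <- disease_pattern_sweep()
  m <- build_dysfunction_module(tbl)
  # independent oracle: count set bits of each pattern code
  expected <- vapply(unique(tbl$gene), function(g) {
    sum(tbl$direction[tbl$gene == g] == "up") >= 3
  }, logical(1))
  expect_setequal(m$genes, names(expected)[expected])
  expect_equal(length(m$genes), 5)       # C(4,3) + C(4,4)
  # threshold variants
  expect_equal(length(build_dysfunction_module(tbl, min_models = 4)$genes), 1)
  expect_equal(length(build_dysfunction_module(tbl, min_models = 2)$genes),
               11)
  up2 <- simulate_disease_models(c(gA = 2), seed = 2)
  expect_length(build_dysfunction_module(up2$table)$genes, 0)
})

test_that("homolog mapping renames, drops and audits deterministically", {
  m <- build_dysfunction_module(disease_pattern_sweep())
  idmap <- data.frame(source = m$genes, target = m$genes)
  expect_identical(map_homologs(m, idmap)$genes, m$genes)
  # absent gene -> dropped list, size decremented
  partial <- idmap[-1, ]
  mm <- map_homologs(m, partial)
  expect_equal(length(mm$genes), length(m$genes) - 1)
  last <- mm$provenance[[length(mm$provenance)]]
  expect_identical(last$dropped, m$genes[1])
  # one-to-many resolves to the lexicographically smallest target
  multi <- rbind(idmap, data.frame(source = m$genes[2], target = "AAA"))
  mm2 <- map_homologs(m, multi)
  expect_true("AAA" %in% mm2$genes)
  expect_false(m$genes[2] %in% mm2$genes)
  # collisions on targets are errors
  coll <- idmap
  coll$target <- "SAME"
  expect_error(map_homologs(m, coll), "collides")
  # the 162 -> 155 fixture ratio
  genes162 <- sprintf("Gene%03d", 1:162)
  mod <- structure(list(name = "m", genes = genes162,
                        audit = data.frame(gene = genes162),
                        provenance = list(list(stage = "raw",
                                               genes = genes162))),
                   class = "module_definition")
  hm <- simulate_homolog_map(genes162, 7 / 162, seed = 1)
  expect_equal(length(map_homologs(mod, hm$map)$genes), 155)
})

test_that("detection restriction applies the min-cells boundary", {
  genes <- c("IN10", "IN1", "IN0", "FILL")
  m <- matrix(0L, 4, 12)
  m[1, 1:10] <- 1L      # nonzero in 10 cells
  m[2, 1] <- 1L         # nonzero in exactly 1 cell
  m[4, ] <- 1L          # keeps every cell's total positive
  cm <- count_matrix(m, genes, sprintf("B%02d", 1:12),
                     data.frame(barcode = sprintf("B%02d", 1:12),
                                patient = "P1", region = "core"))
  nm <- normalize_counts(cm)
  mod <- structure(list(name = "m", genes = genes[1:3],
                        audit = data.frame(gene = genes[1:3]),
                        provenance = list(list(stage = "raw",
                                               genes = genes[1:3]))),
                   class = "module_definition")
  r1 <- restrict_to_detected(mod, nm, min_cells = 1)
  expect_setequal(r1$genes, c("IN10", "IN1"))       # 1-cell boundary kept
  r10 <- restrict_to_detected(mod, nm, min_cells = 10)
  expect_setequal(r10$genes, "IN10")
  r11 <- restrict_to_detected(mod, nm, min_cells = 11)
  expect_length(r11$genes, 0)                        # 10 cells < 11
  # provenance chain lengths are monotone
  sizes <- vapply(r1$provenance, function(s) length(s$genes), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("module coexpression recovers planted block correlation", {
  sim <- simulate_coexpression_profiles(n_cells = 500, r = 0.5, seed = 41)
  cx <- module_coexpression(sim$values, sim$core_genes, sim$dysf_genes)
  expect_gt(cx$mean_within_core, 0.2)
  expect_gt(cx$mean_within_dysf, 0.2)
  expect_lt(cx$mean_cross, -0.2)
  # shuffling cells within each gene destroys all structure
  set.seed(42)
  shuf <- t(apply(sim$values, 1, sample))
  rownames(shuf) <- rownames(sim$values)
  colnames(shuf) <- colnames(sim$values)
  cx0 <- module_coexpression(shuf, sim$core_genes, sim$dysf_genes)
  expect_lt(abs(cx0$mean_within_core), 0.1)
  expect_lt(abs(cx0$mean_within_dysf), 0.1)
  expect_lt(abs(cx0$mean_cross), 0.1)
  # one module against itself: cross mean equals within mean
  cxs <- module_coexpression(sim$values, sim$core_genes, sim$core_genes)
  expect_equal(cxs$mean_cross, cxs$mean_within_core)
  # fully zero-variance module errors with its name
  flat <- sim$values
  flat[sim$dysf_genes, ] <- 1
  expect_error(module_coexpression(flat, sim$core_genes, sim$dysf_genes),
               "dysfunction")
})

test_that("modules serialize with their audit sidecar", {
  dir <- withr::local_tempdir()
  m <- build_dysfunction_module(disease_pattern_sweep())
  path <- file.path(dir, "dysf.gmt")
  write_module(m, path)
  back <- read_gene_sets(path)
  expect_identical(back[[1]]$genes, m$genes)
  audit <- read_manifest(paste0(path, ".audit.json"))
  expect_equal(length(audit$provenance), length(m$provenance))
})
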