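# Readers/writers: Matrix Market triple, GMT, manifest JSON, typed TSVs.

test_that("read_counts parses a hand-written Cell-Ranger-style triple", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 4", "3 2 1"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("MT-CO1", "CLDN5", "VWF"), file.path(dir, "features.tsv"))
  writeLines(c("BC1", "BC2"), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(barcode = c("BC1", "BC2"),
                         patient = c("P1", "P1"),
                         region = c("core", "periphery")),
              file.path(dir, "cell_meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cm <- read_counts(file.path(dir, "matrix.mtx"),
                    file.path(dir, "features.tsv"),
                    file.path(dir, "barcodes.tsv"),
                    file.path(dir, "cell_meta.tsv"))
  m <- as.matrix(cm$values)
  expect_equal(sum(m != 0), 2)
  expect_equal(unname(m[1, 1]), 4)
  expect_equal(unname(m[3, 2]), 1)
  expect_identical(cm$mito_flag, c(TRUE, FALSE, FALSE))  # MT- prefix rule
  expect_identical(cm$cell_meta$region, c("core", "periphery"))
})

test_that("count matrix validation reports duplicates and mismatches", {
  meta <- data.frame(barcode = c("B1", "B2"), patient = "P1",
                     region = "core")
  expect_error(count_matrix(matrix(0, 2, 2), c("A", "A"), c("B1", "B2"), meta),
               "duplicate gene symbols: A")
  expect_error(count_matrix(matrix(0, 2, 2), c("A", "B"), c("B1", "B1"), meta),
               "duplicate barcodes: B1")
  expect_error(count_matrix(matrix(0, 3, 2), c("A", "B"), c("B1", "B2"), meta),
               "3 rows but 2 gene symbols")
  expect_error(count_matrix(matrix(-1, 1, 1), "A", "B1",
                            meta[1, , drop = FALSE]),
               "nonnegative integers")
  expect_error(count_matrix(matrix(0, 1, 2), "A", c("B1", "B3"), meta),
               "does not cover barcodes: B3")
})

test_that("dimension mismatch on disk names the offending file", {
  dir <- withr::local_tempdir()
  cm <- random_count_matrix(1)
  paths <- write_counts(cm, dir)
  writeLines(c(cm$gene_symbols, "EXTRA"), paths[["features"]])
  expect_error(read_counts(paths[["matrix"]], paths[["features"]],
                           paths[["barcodes"]], paths[["meta"]]),
               "features")
})

test_that("count matrix round-trips losslessly on randomized fixtures", {
  dir <- withr::local_tempdir()
  for (seed in 1:30) {
    cm <- random_count_matrix(seed)
    paths <- write_counts(cm, file.path(dir, paste0("rt", seed)))
    back <- read_counts(paths[["matrix"]], paths[["features"]],
                        paths[["barcodes"]], paths[["meta"]])
    expect_same_count_matrix(cm, back)
  }
  # 1x1 with value 7 writes a single coordinate entry
  one <- count_matrix(matrix(7L, 1, 1), "A", "B1",
                      data.frame(barcode = "B1", patient = "P1",
                                 region = "core"))
  p <- write_counts(one, file.path(dir, "one"))
  lines <- readLines(p[["matrix"]])
  body <- lines[!startsWith(lines, "%")]
  expect_equal(length(body), 2)             # size line + single entry
  expect_match(body[2], "^1 1 7$")
  back <- read_counts(p[["matrix"]], p[["features"]], p[["barcodes"]],
                      p[["meta"]])
  expect_equal(as.numeric(back$values[1, 1]), 7)
})

test_that("GMT parsing handles canonical sets, duplicates and bad lines", {
  path <- withr::local_tempfile()
  writeLines(c("EC\tmarkers\tCLDN5\tVWF\tCD34",
               "dup\td\tKDR\tKDR"), path)
  expect_warning(sets <- read_gene_sets(path), "duplicate")
  expect_equal(length(sets), 2)
  expect_identical(sets[["EC"]]$genes, c("CLDN5", "VWF", "CD34"))
  expect_identical(sets[["dup"]]$genes, "KDR")

  writeLines(character(), path)
  expect_identical(read_gene_sets(path), setNames(list(), character()))

  writeLines(c("ok\tdesc\tA", "bad\tonlydesc"), path)
  expect_error(read_gene_sets(path), "line 2")
})

test_that("gene set collections round-trip through GMT", {
  path <- withr::local_tempfile()
  for (seed in 1:20) {
    set.seed(seed)
    sets <- lapply(seq_len(sample(1:6, 1)), function(i)
      gene_set(paste0("S", seed, "_", i),
               sample(sprintf("G%03d", 1:50), sample(1:12, 1)),
               description = paste("set", i)))
    names(sets) <- vapply(sets, `[[`, character(1), "name")
    write_gene_sets(sets, path)
    back <- read_gene_sets(path)
    expect_equal(length(back), length(sets))
    for (nm in names(sets)) {
      expect_identical(back[[nm]]$genes, sets[[nm]]$genes)
      expect_identical(back[[nm]]$description, sets[[nm]]$description)
    }
  }
})

test_that("manifests round-trip through JSON", {
  path <- withr::local_tempfile()
  for (seed in 1:25) {
    set.seed(seed)
    m <- list(schema_version = "1.0", seed = seed,
              entries = list(genes = sprintf("G%02d", sample(99, 5)),
                             values = round(rnorm(4), 6),
                             flag = sample(c(TRUE, FALSE), 3, TRUE),
                             nested = list(a = "x", b = 2.5)))
    write_manifest(m, path)
    expect_equal(read_manifest(path), m, tolerance = 1e-12)
  }
})

test_that("typed panels and tables round-trip through TSV", {
  dir <- withr::local_tempdir()
  b <- simulate_bulk_organ_panel(brain_enriched = 5, n_genes = 40,
                                 replicates = 3, seed = 3)
  p1 <- file.path(dir, "bulk.tsv")
  write_bulk_panel(b$panel, p1)
  back <- read_bulk_panel(p1)
  expect_equal(back$values, b$panel$values, tolerance = 1e-8)
  expect_identical(back$sample_meta$group, b$panel$sample_meta$group)

  tbl <- disease_pattern_sweep()
  p2 <- file.path(dir, "disease.tsv")
  write_disease_table(tbl, p2)
  expect_identical(read_disease_table(p2), tbl)

  hm <- simulate_homolog_map(sprintf("Gene%02d", 1:20), 0.1, seed = 4)
  p3 <- file.path(dir, "homolog.tsv")
  write_homolog_map(hm$map, p3)
  expect_identical(read_homolog_map(p3), hm$map)
})
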