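# Shared fixtures and independent oracles. Expensive objects are computed
# once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Reduced-scale atlas config for fast module tests (planted structure is the
# same as the default, only smaller).
small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_cells = 600, n_genes = 400,
             markers_per_cluster = 10,
             class_markers_per_class = c(EC = 20, macrophage = 8,
                                         microglia = 8, T_cell = 8,
                                         mural = 8),
             n_region_genes = 5, n_bbb_core = 5, n_bbb_dysf = 5, ...)
}

# Small atlas taken through QC, normalization, clustering, annotation and
# EC selection once.
small_atlas <- function() {
  cached("small_atlas", {
    sim <- simulate_atlas(small_sim_config(seed = 1))
    qc <- qc_filter(sim$counts)
    nm <- normalize_counts(qc$counts)
    cl <- cluster_cells(nm, n_pcs = 15, k = 9, seed = 1)
    ann <- annotate_clusters(nm, cl, sim$class_panels)
    sel <- select_ecs(nm, cl, ann, sim$class_panels)
    cl_ec <- cluster_cells(sel$nm_ec, n_pcs = 10, k = 5, seed = 1)
    list(sim = sim, qc = qc, nm = nm, clusters = cl, annotation = ann,
         selection = sel, clusters_ec = cl_ec)
  })
}

# Full default-scale pipeline run (the study conditions), computed once and
# shared by the acceptance tests.
default_run <- function() {
  cached("default_run", {
    run_full(default_run_config(
      seed = 1, out_dir = file.path(tempdir(), "ecatlas_default_run")))
  })
}

# --- independent brute-force oracles ----------------------------------------

# Two-sided rank-sum p by enumerating all splits, scoring each with the
# Mann-Whitney pairwise-comparison count (no midrank machinery shared with
# the implementation).
oracle_ranksum_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); n <- length(pool)
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- n1 * (n - n1) / 2
  obs <- abs(ustat(x, y) - mu)
  devs <- apply(combn(n, n1), 2, function(idx)
    abs(ustat(pool[idx], pool[-idx]) - mu))
  mean(devs >= obs - 1e-9)
}

# Two-sided signed-rank p by enumerating all 2^m sign patterns.
oracle_signedrank_p <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  mu <- sum(r) / 2
  obs <- abs(sum(r[d > 0]) - mu)
  hits <- 0
  for (code in 0:(2^m - 1)) {
    signs <- as.integer(intToBits(code))[seq_len(m)]
    hits <- hits + (abs(sum(r[signs == 1]) - mu) >= obs - 1e-9)
  }
  hits / 2^m
}

# Root-mean-square misfit after optimal rotation/translation/scaling.
procrustes_rms <- function(target, guess) {
  fit <- vegan::procrustes(target, guess)
  sqrt(mean(stats::residuals(fit)^2))
}

# Random small count_matrix for round-trip property tests.
random_count_matrix <- function(seed) {
  set.seed(seed)
  g <- sample(1:25, 1); n <- sample(1:25, 1)
  m <- matrix(rpois(g * n, 0.8), g, n)
  if (n >= 2) m[, sample(n, 1)] <- 0   # keep a degenerate all-zero cell
  genes <- c("MT-CO1", sprintf("G%03d", seq_len(max(0, g - 1))))[seq_len(g)]
  bcs <- sprintf("BC%03d", seq_len(n))
  count_matrix(m, genes, bcs,
               data.frame(barcode = bcs,
                          patient = sample(paste0("P", 1:3), n, TRUE),
                          region = sample(c("core", "periphery"), n, TRUE)))
}

expect_same_count_matrix <- function(a, b) {
  expect_equal(as.matrix(a$values), as.matrix(b$values),
               ignore_attr = TRUE)
  expect_identical(a$gene_symbols, b$gene_symbols)
  expect_identical(a$barcodes, b$barcodes)
  expect_identical(a$cell_meta, b$cell_meta)
  expect_identical(a$mito_flag, b$mito_flag)
}

# Hand-built noise-free panel with genes at the exact criterion boundaries;
# a per-sample filler gene absorbs the rest of the CPM budget.
boundary_panel <- function() {
  groups <- c("brain_EC", "kidney_EC", "lung_EC", "heart_EC", "liver_EC",
              "brain_vasculature")
  reps <- 5
  base <- rbind(
    at_cpm    = c(100, 10, 10, 10, 10, 50),     # exactly at the CPM floor
    at_fold   = c(400, 100, 100, 100, 200, 50), # exactly 2-fold vs liver
    at_vasc   = c(150, 15, 15, 15, 15, 150),    # brain EC == vasculature
    clean     = c(300, 30, 30, 30, 30, 100),
    below_cpm = c(99.5, 5, 5, 5, 5, 40))
  colnames(base) <- groups
  meta <- data.frame(
    sample = paste(rep(groups, each = reps), seq_len(reps), sep = "_"),
    group = rep(groups, each = reps),
    replicate = rep(seq_len(reps), length(groups)))
  values <- base[, meta$group]
  colnames(values) <- meta$sample
  filler <- 1e6 - colSums(values)
  values <- rbind(values, filler = filler)
  bulk_panel(values, meta)
}

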