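# Synthetic-data generators. Every emitted dataset is fully determined by
# (config, seed) and ships with a truth manifest recording the planted
# structure, so downstream stages can be validated by recovery experiments.
# The count model is negative binomial with log-normal gene base means and
# log-normal library-size factors; none of this is claimed to be the
# generative model of any real dataset.

canonical_class_panels <- list(
  EC         = c("CLDN5", "VWF", "CD34", "PECAM1", "CDH5"),
  macrophage = c("APOC1", "CD163", "F13A1", "MRC1", "MSR1"),
  microglia  = c("CX3CR1", "P2RY12", "P2RY13", "TMEM119", "SALL1"),
  T_cell     = c("CD3D", "CD3E", "GZMK", "CD2", "IL7R"),
  mural      = c("RGS5", "PDGFRB", "NOTCH3", "ACTA2", "MYH11")
)

canonical_subcluster_leads <- list(
  Pe1 = c("KLF2", "TIMP3", "SLC2A1", "SLCO1A2", "ATP10A", "TSC22D1"),
  Co1 = c("COL4A1", "COL4A2", "LAMB1", "KDR", "APLN", "PGF", "HSPG2", "CD93"),
  Co2 = c("CALM1", "GNG11", "SPARC", "MYO1B"),
  Pe2 = c("CCL4", "CCL3", "HLA-DRA", "HLA-DRB1"),
  Co3 = c("IL1B", "ACKR1", "SELE", "VCAM1")
)

mito_gene_names <- function(prefix, n) {
  core <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
            "CO1", "CO2", "CO3", "ATP6", "ATP8", "CYB")
  suffix <- if (n <= length(core)) core[seq_len(n)] else
    c(core, sprintf("G%02d", seq_len(n - length(core))))
  paste0(prefix, suffix)
}

#' Configuration of the synthetic single-cell atlas
#'
#' Defaults describe the desk-scale study conditions the generator emulates:
#' a CD31-enriched mixture of endothelial cells (ECs), myeloid and lymphoid
#' cells and mural cells from paired core/periphery samples of 4 patients,
#' with 5 EC subclusters carrying 50 planted markers each, mitochondrial
#' content, planted QC failures, heterotypic doublets, region-differential
#' EC genes, and latent-factor-driven BBB core/dysfunction coexpression
#' genes.
#'
#' @param seed integer RNG seed; the whole dataset is a deterministic
#'   function of the config including this seed.
#' @param n_cells,n_genes atlas dimensions (default 3000 x 2000).
#' @param cell_class_proportions named fractions summing to 1.
#' @param n_ec_subclusters number of EC subclusters (default 5).
#' @param ec_subcluster_proportions fractions of EC cells per subcluster.
#' @param markers_per_cluster planted markers per EC subcluster (default 50).
#' @param marker_lfc natural-log up-shift of a marker in its subcluster.
#' @param class_lfc natural-log up-shift of class program genes in their class.
#' @param subcluster_ec_baseline_lfc natural-log up-shift of every
#'   subcluster marker in all EC cells: subtype markers are endothelial
#'   genes first (expressed EC-wide) with subtype-specific further
#'   up-regulation, which also makes the planted EC program the ground
#'   truth for EC-enrichment recovery.
#' @param class_markers_per_class named integer vector of planted class
#'   program sizes (the first 5 of each are the canonical annotation panel).
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param library_size_mean,library_size_sdlog log-normal library sizes.
#' @param mito_fraction_range range of the mitochondrial expression share of
#'   healthy cells.
#' @param frac_qc_fail fraction of cells planted to fail QC (half by high
#'   mitochondrial share, half by low library / detected genes).
#' @param frac_doublets fraction of cells that are EC x non-EC heterotypic
#'   doublets (50:50 mean mixtures, library size x `doublet_lib_factor`).
#' @param patients number of patients (default 4).
#' @param patient_shift_sd log-scale SD of mild per-patient gene shifts.
#' @param n_region_genes EC-program genes planted up in tumor-core EC cells
#'   and, separately, the same number planted down.
#' @param region_lfc natural-log core-vs-periphery effect on those genes.
#' @param subcluster_core_fraction per-subcluster probability that an EC cell
#'   originates from the tumor core.
#' @param n_bbb_core,n_bbb_dysf,bbb_latent_sd planted BBB coexpression genes:
#'   a per-EC-cell latent factor multiplies core genes by
#'   `exp(sd * f - sd^2/2)` and dysfunction genes by `exp(-sd * f - sd^2/2)`
#'   (mean-one, so the genes are not spuriously EC-enriched).
#' @param doublet_lib_factor library-size multiplier for doublets.
#' @param mito_prefix,n_mito_genes mitochondrial gene naming.
#' @param base_sdlog log-normal SD of gene base expression weights.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_cells = 3000, n_genes = 2000,
                       cell_class_proportions = c(EC = 0.5, macrophage = 0.2,
                                                  microglia = 0.12,
                                                  T_cell = 0.1, mural = 0.08),
                       n_ec_subclusters = 5,
                       ec_subcluster_proportions = c(0.3, 0.25, 0.2, 0.15, 0.1),
                       markers_per_cluster = 50,
                       marker_lfc = 2,
                       class_lfc = 2,
                       subcluster_ec_baseline_lfc = 1,
                       class_markers_per_class = NULL,
                       nb_dispersion = 0.1,
                       library_size_mean = 5000,
                       library_size_sdlog = 0.3,
                       mito_fraction_range = c(0.01, 0.06),
                       frac_qc_fail = 0.05,
                       frac_doublets = 0.02,
                       patients = 4,
                       patient_shift_sd = 0.05,
                       n_region_genes = 15,
                       region_lfc = 1,
                       subcluster_core_fraction = NULL,
                       n_bbb_core = 15, n_bbb_dysf = 15, bbb_latent_sd = 0.6,
                       doublet_lib_factor = 1.8,
                       mito_prefix = "MT-", n_mito_genes = 13,
                       base_sdlog = 1) {
  # YAML configs deliver mappings/sequences as lists; coerce to vectors
  cell_class_proportions <- unlist(cell_class_proportions)
  if (!is.null(class_markers_per_class))
    class_markers_per_class <- unlist(class_markers_per_class)
  ec_subcluster_proportions <- unlist(ec_subcluster_proportions)
  mito_fraction_range <- unlist(mito_fraction_range)
  if (!is.null(subcluster_core_fraction))
    subcluster_core_fraction <- unlist(subcluster_core_fraction)
  classes <- names(cell_class_proportions)
  if (is.null(classes) || !"EC" %in% classes)
    stop("cell_class_proportions must be named and include an EC class")
  if (abs(sum(cell_class_proportions) - 1) > 1e-8)
    stop("cell class proportions must sum to 1")
  if (n_ec_subclusters < 2) stop("need at least 2 EC subclusters")
  if (length(ec_subcluster_proportions) != n_ec_subclusters)
    ec_subcluster_proportions <- rep(1 / n_ec_subclusters, n_ec_subclusters)
  ec_subcluster_proportions <- ec_subcluster_proportions /
    sum(ec_subcluster_proportions)
  if (is.null(class_markers_per_class)) {
    class_markers_per_class <- setNames(rep(20L, length(classes)), classes)
    class_markers_per_class["EC"] <- max(40L, 5L + 2L * n_region_genes)
  }
  if (!all(classes %in% names(class_markers_per_class)))
    stop("class_markers_per_class must cover every class")
  if (class_markers_per_class[["EC"]] < 5 + 2 * n_region_genes)
    stop("EC class program too small for ", n_region_genes,
         " region genes per direction")
  if (frac_qc_fail < 0 || frac_qc_fail >= 1 ||
      frac_doublets < 0 || frac_doublets >= 1)
    stop("frac_qc_fail and frac_doublets must lie in [0, 1)")
  if (frac_qc_fail + frac_doublets >= 0.9)
    stop("qc-fail and doublet fractions leave too few ordinary cells")
  if (length(mito_fraction_range) != 2 || mito_fraction_range[1] < 0 ||
      mito_fraction_range[2] >= 1 ||
      mito_fraction_range[1] > mito_fraction_range[2])
    stop("mito_fraction_range must be an increasing pair within [0, 1)")
  if (is.null(subcluster_core_fraction)) {
    subcluster_core_fraction <- rep(c(0.1, 0.85), length.out = n_ec_subclusters)
    if (n_ec_subclusters == 5)
      subcluster_core_fraction <- c(0.1, 0.85, 0.85, 0.1, 0.85)
  }
  demand <- n_mito_genes + sum(class_markers_per_class) +
    n_ec_subclusters * markers_per_cluster + n_bbb_core + n_bbb_dysf
  if (demand > n_genes)
    stop("planted gene demand (", demand, ") exceeds n_genes (", n_genes, ")")
  cfg <- list(seed = as.integer(seed), n_cells = as.integer(n_cells),
              n_genes = as.integer(n_genes),
              cell_class_proportions = cell_class_proportions,
              n_ec_subclusters = as.integer(n_ec_subclusters),
              ec_subcluster_proportions = ec_subcluster_proportions,
              markers_per_cluster = as.integer(markers_per_cluster),
              marker_lfc = marker_lfc, class_lfc = class_lfc,
              subcluster_ec_baseline_lfc = subcluster_ec_baseline_lfc,
              class_markers_per_class = class_markers_per_class,
              nb_dispersion = nb_dispersion,
              library_size_mean = library_size_mean,
              library_size_sdlog = library_size_sdlog,
              mito_fraction_range = mito_fraction_range,
              frac_qc_fail = frac_qc_fail, frac_doublets = frac_doublets,
              patients = as.integer(patients),
              patient_shift_sd = patient_shift_sd,
              n_region_genes = as.integer(n_region_genes),
              region_lfc = region_lfc,
              subcluster_core_fraction = subcluster_core_fraction,
              n_bbb_core = as.integer(n_bbb_core),
              n_bbb_dysf = as.integer(n_bbb_dysf),
              bbb_latent_sd = bbb_latent_sd,
              doublet_lib_factor = doublet_lib_factor,
              mito_prefix = mito_prefix,
              n_mito_genes = as.integer(n_mito_genes),
              base_sdlog = base_sdlog)
  class(cfg) <- "sim_config"
  cfg
}

# Build the named gene universe and the planted gene groups.
#' @noRd
build_gene_universe <- function(cfg) {
  classes <- names(cfg$cell_class_proportions)
  mito <- mito_gene_names(cfg$mito_prefix, cfg$n_mito_genes)
  class_markers <- list()
  for (cl in classes) {
    k <- cfg$class_markers_per_class[[cl]]
    lead <- canonical_class_panels[[cl]] %||% character()
    lead <- lead[seq_len(min(length(lead), k))]
    fill <- if (k > length(lead))
      sprintf("%s-PRG%02d", toupper(gsub("_", "", cl)), seq_len(k - length(lead)))
    else character()
    class_markers[[cl]] <- c(lead, fill)
  }
  sub_names <- if (cfg$n_ec_subclusters == 5) names(canonical_subcluster_leads)
               else paste0("EC", seq_len(cfg$n_ec_subclusters))
  sub_markers <- list()
  for (i in seq_len(cfg$n_ec_subclusters)) {
    nm <- sub_names[i]
    k <- cfg$markers_per_cluster
    lead <- canonical_subcluster_leads[[nm]] %||% character()
    lead <- lead[seq_len(min(length(lead), k))]
    fill <- if (k > length(lead))
      sprintf("%s-M%02d", toupper(nm), seq_len(k - length(lead)))
    else character()
    sub_markers[[nm]] <- c(lead, fill)
  }
  bbb_core <- sprintf("BBBC%02d", seq_len(cfg$n_bbb_core))
  bbb_dysf <- sprintf("BBBD%02d", seq_len(cfg$n_bbb_dysf))
  planted <- c(mito, unlist(class_markers, use.names = FALSE),
               unlist(sub_markers, use.names = FALSE), bbb_core, bbb_dysf)
  stopifnot(!anyDuplicated(planted))
  background <- sprintf("G%05d", seq_len(cfg$n_genes - length(planted)))
  symbols <- c(planted, background)
  ecm <- class_markers[["EC"]]
  list(symbols = symbols, mito = mito, class_markers = class_markers,
       sub_markers = sub_markers, sub_names = sub_names,
       bbb_core = bbb_core, bbb_dysf = bbb_dysf,
       panels = lapply(classes, function(cl)
         class_markers[[cl]][seq_len(min(5, length(class_markers[[cl]])))]),
       core_up = ecm[5 + seq_len(cfg$n_region_genes)],
       core_down = ecm[5 + cfg$n_region_genes + seq_len(cfg$n_region_genes)])
}

#' Simulate a CD31-enriched single-cell atlas with planted structure
#'
#' Draws negative-binomial counts for a mixture of cell classes with planted
#' class programs, EC subcluster markers, core-vs-periphery differential EC
#' genes, BBB coexpression genes, mitochondrial content, QC failures and
#' heterotypic doublets, and records every planted property in a truth
#' manifest. Deterministic for a fixed config.
#'
#' @param cfg a [sim_config()].
#' @return List with elements `counts` (a [count_matrix()]), `truth` (the
#'   planted-structure manifest) and `class_panels` (canonical annotation
#'   panels as [gene_set()] objects).
#' @export
simulate_atlas <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  uni <- build_gene_universe(cfg)
  G <- cfg$n_genes; N <- cfg$n_cells
  classes <- names(cfg$cell_class_proportions)
  symbols <- uni$symbols
  gidx <- setNames(seq_len(G), symbols)
  is_mito <- symbols %in% uni$mito

  w <- rlnorm(G, meanlog = 0, sdlog = cfg$base_sdlog)

  # class-level expected profiles (multiplicative programs on base weights)
  class_mult <- matrix(1, G, length(classes), dimnames = list(symbols, classes))
  for (cl in classes)
    class_mult[gidx[uni$class_markers[[cl]]], cl] <- exp(cfg$class_lfc)
  # subtype markers are EC genes first: elevated EC-wide, further up-shifted
  # in their own subcluster below
  all_sub <- unlist(uni$sub_markers, use.names = FALSE)
  class_mult[gidx[all_sub], "EC"] <-
    class_mult[gidx[all_sub], "EC"] * exp(cfg$subcluster_ec_baseline_lfc)

  sub_mult <- matrix(1, G, cfg$n_ec_subclusters,
                     dimnames = list(symbols, uni$sub_names))
  for (nm in uni$sub_names)
    sub_mult[gidx[uni$sub_markers[[nm]]], nm] <- exp(cfg$marker_lfc)

  patient_ids <- paste0("P", seq_len(cfg$patients))
  patient_mult <- matrix(exp(rnorm(G * cfg$patients, 0, cfg$patient_shift_sd)),
                         G, cfg$patients, dimnames = list(symbols, patient_ids))

  # --- cell-level assignments (all exact-count planting) --------------------
  n_class <- exact_counts(cfg$cell_class_proportions * N)
  cell_class <- sample(rep(classes, n_class))
  n_qc <- round(cfg$frac_qc_fail * N)
  n_db <- round(cfg$frac_doublets * N)
  special <- sample(N, n_qc + n_db)
  qc_idx <- special[seq_len(n_qc)]
  db_idx <- setdiff(special, qc_idx)
  qc_reason <- rep(NA_character_, N)
  if (n_qc > 0)
    qc_reason[qc_idx] <- rep(c("mito", "low_genes"), length.out = n_qc)
  doublet_flag <- seq_len(N) %in% db_idx
  non_ec <- setdiff(classes, "EC")
  doublet_partner <- rep(NA_character_, N)
  doublet_partner[db_idx] <- sample(non_ec, n_db, replace = TRUE)

  ec_subcluster <- rep(NA_character_, N)
  ec_cells <- which(cell_class == "EC" & !doublet_flag)
  n_sub <- exact_counts(cfg$ec_subcluster_proportions * length(ec_cells))
  ec_subcluster[ec_cells] <- sample(rep(uni$sub_names, n_sub))

  region <- ifelse(runif(N) < 0.5, "core", "periphery")
  for (i in seq_len(cfg$n_ec_subclusters)) {
    cells_i <- which(ec_subcluster == uni$sub_names[i])
    region[cells_i] <- ifelse(runif(length(cells_i)) <
                                cfg$subcluster_core_fraction[i],
                              "core", "periphery")
  }
  patient <- sample(patient_ids, N, replace = TRUE)

  mito_share <- runif(N, cfg$mito_fraction_range[1], cfg$mito_fraction_range[2])
  mito_share[qc_reason == "mito" & !is.na(qc_reason)] <-
    runif(sum(qc_reason == "mito", na.rm = TRUE), 0.20, 0.35)

  lib <- rlnorm(N, meanlog = log(cfg$library_size_mean) -
                  cfg$library_size_sdlog^2 / 2,
                sdlog = cfg$library_size_sdlog)
  lib[doublet_flag] <- lib[doublet_flag] * cfg$doublet_lib_factor
  low <- qc_reason == "low_genes" & !is.na(qc_reason)
  lib[low] <- runif(sum(low), 80, 150)

  bbb_f <- rnorm(N)   # latent BBB axis; only applied to EC-class cells
  core_up_i <- gidx[uni$core_up]; core_down_i <- gidx[uni$core_down]
  bbb_c_i <- gidx[uni$bbb_core]; bbb_d_i <- gidx[uni$bbb_dysf]
  tau <- cfg$bbb_latent_sd

  counts <- matrix(0L, G, N)
  size <- 1 / cfg$nb_dispersion
  for (c_i in seq_len(N)) {
    cl <- cell_class[c_i]
    base <- w * class_mult[, cl] * patient_mult[, patient[c_i]]
    if (doublet_flag[c_i]) {
      other <- w * class_mult[, doublet_partner[c_i]] *
        patient_mult[, patient[c_i]]
      base <- (base + other) / 2
    }
    if (cl == "EC") {
      if (!is.na(ec_subcluster[c_i]))
        base <- base * sub_mult[, ec_subcluster[c_i]]
      if (region[c_i] == "core") {
        base[core_up_i] <- base[core_up_i] * exp(cfg$region_lfc)
        base[core_down_i] <- base[core_down_i] * exp(-cfg$region_lfc)
      }
      f <- bbb_f[c_i]
      base[bbb_c_i] <- base[bbb_c_i] * exp(tau * f - tau^2 / 2)
      base[bbb_d_i] <- base[bbb_d_i] * exp(-tau * f - tau^2 / 2)
    }
    s <- mito_share[c_i]
    p <- numeric(G)
    p[!is_mito] <- base[!is_mito] / sum(base[!is_mito]) * (1 - s)
    p[is_mito] <- w[is_mito] / sum(w[is_mito]) * s
    counts[, c_i] <- rnbinom(G, mu = lib[c_i] * p, size = size)
  }

  barcodes <- sprintf("CELL%05d", seq_len(N))
  cm <- count_matrix(counts, symbols, barcodes,
                     data.frame(barcode = barcodes, patient = patient,
                                region = region, stringsAsFactors = FALSE),
                     mito_prefix = cfg$mito_prefix)
  truth <- list(
    schema_version = "1.0",
    seed = cfg$seed,
    cell_class = setNames(ifelse(doublet_flag, "doublet", cell_class), barcodes),
    ec_subcluster = setNames(ec_subcluster, barcodes),
    doublet_flag = setNames(doublet_flag, barcodes),
    doublet_partner = setNames(doublet_partner, barcodes),
    qc_fail_flag = setNames(!is.na(qc_reason), barcodes),
    qc_fail_reason = setNames(qc_reason, barcodes),
    planted_markers = uni$sub_markers,
    class_markers = uni$class_markers,
    ec_program_genes = unique(c(uni$class_markers[["EC"]],
                                unlist(uni$sub_markers, use.names = FALSE))),
    core_up_genes = uni$core_up,
    core_down_genes = uni$core_down,
    bbb_core_genes = uni$bbb_core,
    bbb_dysf_genes = uni$bbb_dysf,
    subcluster_core_fraction = setNames(cfg$subcluster_core_fraction,
                                        uni$sub_names)
  )
  panels <- lapply(seq_along(classes), function(i)
    gene_set(classes[i], uni$panels[[i]], "canonical class panel"))
  names(panels) <- classes
  list(counts = cm, truth = truth, class_panels = panels)
}

#' Simulate a multi-organ bulk EC panel with planted brain-enriched genes
#'
#' Emits CPM-closed replicate profiles for brain, kidney, lung, heart and
#' liver ECs plus whole brain vasculature. Planted brain-enriched genes pass
#' all three core-module criteria by construction; each decoy class violates
#' exactly one criterion (below the CPM floor, sub-2-fold versus one organ,
#' or vasculature exceeding brain ECs).
#'
#' @param brain_enriched character vector of planted gene names, or an
#'   integer count (names are generated).
#' @param decoys_per_type decoy genes per violation class.
#' @param replicates replicate samples per group (default 5; two-sided exact
#'   rank-sum significance at alpha 0.05 requires at least 4 per group).
#' @param n_genes total genes including planted ones and background.
#' @param brain_cpm,organ_cpm planted mean CPM in brain ECs and in the four
#'   peripheral organs.
#' @param noise_sdlog replicate log-normal noise.
#' @param seed RNG seed.
#' @return List with elements `panel` (a [bulk_panel()]) and `truth`.
#' @export
simulate_bulk_organ_panel <- function(brain_enriched = 30, decoys_per_type = 4,
                                      replicates = 5, n_genes = 1000,
                                      brain_cpm = 400, organ_cpm = 50,
                                      noise_sdlog = 0.1, seed = 1) {
  if (replicates < 2) stop("need at least 2 replicates per group")
  set.seed(seed)
  if (is.numeric(brain_enriched) && length(brain_enriched) == 1)
    brain_enriched <- sprintf("Brainec%03d", seq_len(brain_enriched))
  groups <- c("brain_EC", "kidney_EC", "lung_EC", "heart_EC", "liver_EC",
              "brain_vasculature")
  organs <- groups[2:5]
  dec_a <- sprintf("Decoycpm%02d", seq_len(decoys_per_type))
  dec_b <- sprintf("Decoyfold%02d", seq_len(decoys_per_type))
  dec_c <- sprintf("Decoyvasc%02d", seq_len(decoys_per_type))
  planted <- c(brain_enriched, dec_a, dec_b, dec_c)
  if (anyDuplicated(planted)) stop("planted bulk gene names collide")
  if (n_genes <= length(planted))
    stop("n_genes must exceed the number of planted genes")
  background <- sprintf("Bulkg%04d", seq_len(n_genes - length(planted)))
  genes <- c(planted, background)

  base <- matrix(0, length(genes), length(groups),
                 dimnames = list(genes, groups))
  bg <- rlnorm(length(background), log(300), 0.7)
  base[brain_enriched, "brain_EC"] <- brain_cpm
  base[brain_enriched, organs] <- organ_cpm
  base[brain_enriched, "brain_vasculature"] <- brain_cpm * 0.5
  base[dec_a, "brain_EC"] <- 40
  base[dec_a, organs] <- 4
  base[dec_a, "brain_vasculature"] <- 20
  base[dec_b, "brain_EC"] <- brain_cpm
  base[dec_b, organs] <- organ_cpm
  base[dec_b, "kidney_EC"] <- brain_cpm / 1.5   # only kidney fold fails
  base[dec_b, "brain_vasculature"] <- brain_cpm * 0.5
  base[dec_c, "brain_EC"] <- brain_cpm
  base[dec_c, organs] <- organ_cpm
  base[dec_c, "brain_vasculature"] <- brain_cpm * 2.2
  # background absorbs the rest of each group's CPM budget so that closure
  # after replicate noise barely moves the planted absolute values
  for (g in groups)
    base[background, g] <- bg / sum(bg) * (1e6 - sum(base[planted, g]))

  sample_meta <- data.frame(
    sample = paste(rep(groups, each = replicates), seq_len(replicates),
                   sep = "_"),
    group = rep(groups, each = replicates),
    replicate = rep(seq_len(replicates), times = length(groups)),
    stringsAsFactors = FALSE)
  values <- matrix(0, length(genes), nrow(sample_meta),
                   dimnames = list(genes, sample_meta$sample))
  for (j in seq_len(nrow(sample_meta))) {
    v <- base[, sample_meta$group[j]] * exp(rnorm(length(genes), 0, noise_sdlog))
    values[, j] <- v / sum(v) * 1e6
  }
  truth <- list(
    seed = seed,
    brain_enriched_genes = brain_enriched,
    decoys = list(below_cpm = dec_a, sub_fold = dec_b,
                  vasculature_exceeds = dec_c),
    decoy_expected_failure = c(setNames(rep("a", length(dec_a)), dec_a),
                               setNames(rep("b:kidney_EC", length(dec_b)), dec_b),
                               setNames(rep("c", length(dec_c)), dec_c)))
  list(panel = bulk_panel(values, sample_meta), truth = truth)
}

#' Simulate per-model differential calls for the four brain-disease models
#'
#' @param planted named integer vector: for each gene, the number of models
#'   (0-4) in which it is planted "up"; non-up models are called "down" or
#'   "ns" at random.
#' @param background_genes additional genes receiving 0-2 up calls at random.
#' @param seed RNG seed.
#' @return List with elements `table` (long data.frame gene/model/direction)
#'   and `truth` (genes up in at least 3 models).
#' @export
simulate_disease_models <- function(planted, background_genes = character(),
                                    seed = 1) {
  set.seed(seed)
  if (is.null(names(planted))) stop("planted must be a named vector of up-counts")
  if (any(planted < 0 | planted > 4)) stop("up-counts must be in 0..4")
  if (length(background_genes)) {
    bg <- setNames(sample(0:2, length(background_genes), replace = TRUE),
                   background_genes)
    planted <- c(planted, bg)
  }
  models <- disease_models()
  rows <- lapply(names(planted), function(g) {
    k <- planted[[g]]
    up_models <- if (k > 0) sample(models, k) else character()
    dir <- ifelse(models %in% up_models, "up",
                  sample(c("down", "ns"), 4, replace = TRUE))
    data.frame(gene = g, model = models, direction = dir,
               stringsAsFactors = FALSE)
  })
  tbl <- do.call(rbind, rows)
  list(table = validate_disease_table(tbl),
       truth = list(seed = seed,
                    dysfunction_genes = names(planted)[planted >= 3],
                    up_counts = planted))
}

#' Exhaustive 16-pattern disease-call fixture
#'
#' One gene per up/down pattern across the four models (no "ns" calls);
#' useful for brute-force validation of the dysfunction-module vote.
#'
#' @return Long data.frame with 16 genes x 4 models.
#' @export
disease_pattern_sweep <- function() {
  models <- disease_models()
  rows <- lapply(0:15, function(code) {
    bits <- as.integer(intToBits(code))[1:4]
    data.frame(gene = sprintf("PATTERN%s", paste(bits, collapse = "")),
               model = models,
               direction = ifelse(bits == 1, "up", "down"),
               stringsAsFactors = FALSE)
  })
  validate_disease_table(do.call(rbind, rows))
}

#' Simulate anatomic-region bulk profiles with planted vascular abundance
#'
#' Each sample's expression is a region-weighted mixture of marker-set
#' signatures plus background, scaled by a per-sample vascular-abundance
#' factor. Marker sets attain their highest mixture weight in their "home"
#' region, but the microvascular-proliferation region carries a 3x vascular
#' factor by default, confounding raw comparisons until the profiles are
#' normalized by the microvascular score.
#'
#' @param marker_sets list of [gene_set()] objects (e.g. planted subcluster
#'   markers).
#' @param home_regions named character vector mapping set name to its home
#'   region; defaults to a deterministic assignment over the five regions.
#' @param vascular_genes vascular-enriched panel genes (names or a count).
#' @param n_background background genes.
#' @param samples_per_region samples per region (>= 2).
#' @param region_vascular_factor named per-region base vascular factor.
#' @param factor_jitter_sdlog log-normal jitter of per-sample factors.
#' @param noise_sdlog measurement noise on each value.
#' @param home_weight,off_weight mixture weights in / out of the home region.
#' @param seed RNG seed.
#' @return List with elements `panel` (a [region_panel()]), `vascular_panel`
#'   (a [gene_set()]) and `truth` (per-sample factors, home regions).
#' @export
simulate_anatomic_regions <- function(marker_sets,
                                      home_regions = NULL,
                                      vascular_genes = 30,
                                      n_background = 200,
                                      samples_per_region = 3,
                                      region_vascular_factor = NULL,
                                      factor_jitter_sdlog = 0.05,
                                      noise_sdlog = 0.05,
                                      home_weight = 2, off_weight = 1,
                                      seed = 1) {
  set.seed(seed)
  if (samples_per_region < 2) stop("need at least 2 samples per region")
  regions <- anatomic_regions()
  set_names <- vapply(marker_sets, function(s) s$name, character(1))
  if (is.null(home_regions))
    home_regions <- setNames(rep(regions, length.out = length(marker_sets)),
                             set_names)
  if (is.null(region_vascular_factor))
    region_vascular_factor <- setNames(c(1, 1, 1, 3, 1), regions)
  if (is.numeric(vascular_genes) && length(vascular_genes) == 1)
    vascular_genes <- sprintf("VASC%02d", seq_len(vascular_genes))
  marker_genes <- unlist(lapply(marker_sets, `[[`, "genes"), use.names = FALSE)
  background <- sprintf("RBG%04d", seq_len(n_background))
  genes <- unique(c(marker_genes, vascular_genes, background))

  sample_meta <- data.frame(
    sample = paste(rep(regions, each = samples_per_region),
                   seq_len(samples_per_region), sep = "_"),
    region = rep(regions, each = samples_per_region),
    stringsAsFactors = FALSE)
  base <- setNames(rlnorm(length(genes), log(100), 0.3), genes)
  weight <- matrix(off_weight, length(genes), length(regions),
                   dimnames = list(genes, regions))
  weight[vascular_genes, ] <- 1
  weight[background, ] <- 1
  for (s in marker_sets)
    weight[s$genes, home_regions[[s$name]]] <- home_weight
  factors <- region_vascular_factor[sample_meta$region] *
    exp(rnorm(nrow(sample_meta), 0, factor_jitter_sdlog))
  names(factors) <- sample_meta$sample
  values <- matrix(0, length(genes), nrow(sample_meta),
                   dimnames = list(genes, sample_meta$sample))
  for (j in seq_len(nrow(sample_meta)))
    values[, j] <- base * weight[, sample_meta$region[j]] * factors[j] *
      exp(rnorm(length(genes), 0, noise_sdlog))
  list(panel = region_panel(values, sample_meta),
       vascular_panel = gene_set("vascular_enriched", vascular_genes,
                                 "planted vascular-abundance panel"),
       truth = list(seed = seed, vascular_factor = factors,
                    home_regions = home_regions,
                    vascular_genes = vascular_genes))
}

#' Simulate a two-column homolog map with a planted drop fraction
#'
#' @param genes source-species gene symbols to map.
#' @param drop_fraction fraction of genes without a homolog (default 7/162,
#'   mirroring a 162-gene module of which 155 map).
#' @param seed RNG seed.
#' @param target_fun symbol transformation for mapped targets (default
#'   `toupper`, the mouse-to-human convention).
#' @return List with elements `map` (data.frame source/target) and `dropped`.
#' @export
simulate_homolog_map <- function(genes, drop_fraction = 7 / 162, seed = 1,
                                 target_fun = toupper) {
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must lie in [0, 1)")
  set.seed(seed)
  n_drop <- round(drop_fraction * length(genes))
  dropped <- if (n_drop > 0) sort(sample(genes, n_drop)) else character()
  kept <- setdiff(genes, dropped)
  list(map = data.frame(source = kept, target = target_fun(kept),
                        stringsAsFactors = FALSE),
       dropped = dropped)
}

#' Simulate coexpression profiles with a planted block correlation
#'
#' A single latent factor per cell gives every within-module gene pair
#' correlation `r` and every cross-module pair correlation `-r` exactly (in
#' expectation): `x = sqrt(r) * s * f + sqrt(1-r) * noise` with `s = +1` for
#' core genes and `-1` for dysfunction genes.
#'
#' @param n_cells number of cells (columns).
#' @param n_core,n_dysf module sizes.
#' @param r target within-module correlation (cross-module is `-r`).
#' @param seed RNG seed.
#' @return List with `values` (genes x cells matrix), `core_genes`,
#'   `dysf_genes`.
#' @export
simulate_coexpression_profiles <- function(n_cells = 500, n_core = 10,
                                           n_dysf = 10, r = 0.5, seed = 1) {
  if (r < 0 || r >= 1) stop("r must lie in [0, 1)")
  set.seed(seed)
  core <- sprintf("CORE%02d", seq_len(n_core))
  dysf <- sprintf("DYSF%02d", seq_len(n_dysf))
  s <- c(rep(1, n_core), rep(-1, n_dysf))
  f <- rnorm(n_cells)
  noise <- matrix(rnorm((n_core + n_dysf) * n_cells), n_core + n_dysf, n_cells)
  values <- sqrt(r) * outer(s, f) + sqrt(1 - r) * noise
  rownames(values) <- c(core, dysf)
  colnames(values) <- sprintf("CELL%04d", seq_len(n_cells))
  list(values = values, core_genes = core, dysf_genes = dysf)
}
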