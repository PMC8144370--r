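#' Simulate a full synthetic tissue experiment
#'
#' Generates the spatial reference with ground truth, a tissue-proportion
#' single-cell survey, a secretory-enriched single-cell sort (the analog of
#' sorting rare secretory cells before sequencing, needed because a tissue
#' draw yields too few of them for reconstruction) and a clump dataset,
#' under one seed.
#'
#' @param config a [clumpseq_config()]
#' @param seed integer seed; cells and clumps use offset sub-seeds
#' @param n_cells,n_clumps survey and clump dataset sizes
#' @param n_secretory_cells size of the secretory-enriched sort (0 skips it)
#' @param secretory_mix cell-type proportions of the enriched sort
#' @return list: `reference`, `truth`, `cells` (survey + sort combined),
#'   `cell_truth`, `clumps`, `clump_truth`
#' @export
simulate_clumpseq <- function(config = clumpseq_config(), seed = 1L,
                              n_cells = 600L, n_clumps = 1500L,
                              n_secretory_cells = 500L,
                              secretory_mix = c(enterocyte = 0.05,
                                                goblet = 0.60,
                                                enteroendocrine = 0.15,
                                                tuft = 0.15,
                                                paneth = 0.05)) {
  ref <- generate_reference(config, seed = seed)
  cells <- generate_cells(ref$truth, n_cells, config, seed = seed + 1L)
  counts <- cells$counts
  cell_truth <- cells$cell_truth
  if (n_secretory_cells > 0L) {
    sort_cells <- generate_cells(ref$truth, n_secretory_cells, config,
                                 seed = seed + 3L,
                                 proportions = secretory_mix,
                                 label = "sort")
    counts <- count_matrix(
      cbind(counts$counts, sort_cells$counts$counts),
      rbind(counts$well_meta, sort_cells$counts$well_meta))
    cell_truth <- rbind(cell_truth, sort_cells$cell_truth)
  }
  clumps <- generate_clumps(ref$truth, n_clumps, config, seed = seed + 2L)
  list(reference = ref$reference, truth = ref$truth,
       cells = counts, cell_truth = cell_truth,
       clumps = clumps$counts, clump_truth = clumps$clump_truth)
}

#' Preprocess a raw count matrix
#'
#' Background subtraction from empty wells, QC filtering, total
#' normalization — in that order.
#'
#' @param cm a [count_matrix()]
#' @param mode `"clump"` or `"single_cell"`
#' @param config a [clumpseq_config()]
#' @param mito_genes mitochondrial gene symbols
#' @return list: `norm` (a [norm_matrix()]), `report` (QC report),
#'   `subtracted` (the background-subtracted counts)
#' @export
preprocess_counts <- function(cm, mode, config, mito_genes) {
  sub <- subtract_background(cm)
  qc <- qc_filter(sub, mode, config, mito_genes)
  list(norm = normalize_total(qc$counts), report = qc$report,
       subtracted = qc$counts)
}

#' Prepare the shared upstream products of a synthetic pipeline run
#'
#' Preprocesses cells and clumps, types the single cells by marker scores,
#' builds the specificity table (enterocyte zones from ground truth, the
#' synthetic stand-in for the published zone annotations) and selects the
#' enterocyte-specific gene set.
#'
#' @param sim a [simulate_clumpseq()] result
#' @param config a [clumpseq_config()]
#' @return list of upstream products consumed by [make_goblet_runner()]
#'   and [run_clump_classification()]
#' @export
prepare_pipeline <- function(sim, config) {
  cells <- preprocess_counts(sim$cells, "single_cell", config,
                             sim$truth$mito_genes)
  clumps <- preprocess_counts(sim$clumps, "clump", config,
                              sim$truth$mito_genes)
  labels <- classify_cells_by_markers(cells$norm, sim$truth$markers)
  ent_zones <- stats::setNames(sim$cell_truth$zone, sim$cell_truth$well_id)
  spec_table <- build_specificity_table(cells$norm, labels, ent_zones)
  list(sim = sim, config = config, cells = cells, clumps = clumps,
       labels = labels, spec_table = spec_table)
}

#' Assign all clumps to zones using enterocyte landmarks
#'
#' @param prep a [prepare_pipeline()] result
#' @param config a [clumpseq_config()] (defaults to the one in `prep`)
#' @param reference optional [spatial_reference()] override (e.g. a
#'   coarse-grained one)
#' @return list: `assignment` (data.frame), `landmarks`, `ent_specific`
#' @export
run_clump_zonation <- function(prep, config = prep$config,
                               reference = prep$sim$reference) {
  sp <- config$specificity
  ent_specific <- select_type_specific_genes(
    prep$spec_table, "enterocyte", sp$enterocyte_fold,
    sp$enterocyte_min_frac)
  landmarks <- select_enterocyte_landmarks(reference, prep$spec_table,
                                           config)
  clumps_internal <- suppressWarnings(
    internal_normalize(prep$clumps$norm, ent_specific))
  assignment <- assign_clump_zones(clumps_internal, reference, landmarks,
                                   config)
  list(assignment = assignment, landmarks = landmarks,
       ent_specific = ent_specific)
}

#' Classify the secretory content of all clumps
#'
#' Selects per-type classification markers from the specificity table and
#' runs the stratified ray classifier.
#'
#' @param prep a [prepare_pipeline()] result
#' @param zones named integer zone per clump (from [run_clump_zonation()])
#' @param config a [clumpseq_config()]
#' @return data.frame of per-clump calls (see [classify_clump_types()])
#' @export
run_clump_classification <- function(prep, zones, config = prep$config) {
  sec_types <- c("goblet", "enteroendocrine", "tuft", "paneth")
  marker_sets <- lapply(stats::setNames(sec_types, sec_types), function(ty)
    select_classification_markers(prep$spec_table, ty, config))
  classify_clumps(prep$clumps$norm, marker_sets, zones, config)
}

#' Build a goblet reconstruction runner for a fixed prepared dataset
#'
#' Returns a function(config) that executes the goblet single-cell
#' reconstruction end to end — enterocyte landmarks, clump zone assignment,
#' goblet clump zonation table, secretory landmark extraction, eta
#' coordinates, eta-limit grid optimization against the coarse-grained
#' clump table, and genome-wide reconstruction — so parameter-perturbation
#' sweeps rerun every stage a parameter can influence.
#'
#' @param prep a [prepare_pipeline()] result
#' @param goblet_clump_ids ids of clumps to treat as goblet-containing
#'   (from [run_clump_classification()] calls, or ground truth when
#'   benchmarking reconstruction in isolation)
#' @param details if TRUE the runner returns intermediate products as well
#' @return function(config) returning a [zonation_table()] (or a list when
#'   `details`)
#' @export
make_goblet_runner <- function(prep, goblet_clump_ids, details = FALSE) {
  force(prep); force(goblet_clump_ids); force(details)
  cell_ids <- names(prep$labels)[prep$labels == "goblet"]
  function(config) {
    sp <- config$specificity
    zonation <- run_clump_zonation(prep, config)
    zones <- stats::setNames(zonation$assignment$zone,
                             zonation$assignment$clump_id)

    sec_genes <- select_type_specific_genes(
      prep$spec_table, "goblet", sp$secretory_fold, sp$secretory_min_frac)
    gob_ids <- intersect(goblet_clump_ids,
                         zonation$assignment$clump_id[
                           !zonation$assignment$discarded])
    gob_vals <- prep$clumps$norm$values[, gob_ids, drop = FALSE]
    gob_internal <- suppressWarnings(
      internal_normalize(gob_vals, sec_genes))
    gob_zones <- zones[colnames(gob_internal$values)]

    n_zones <- config$reconstruction$n_zones$goblet
    d_eta <- config$reconstruction$d_eta$goblet
    cutoffs <- config$clump$com_cutoffs$goblet
    gob_table7 <- compute_zonation_table(
      gob_internal, gob_zones, test_floor = config$clump$zonation_test_floor,
      n_zones = prep$sim$reference$n_zones)
    sec_landmarks <- select_secretory_landmarks(
      gob_table7, sec_genes, cutoffs[["crypt"]], cutoffs[["tip"]], config,
      cell_type = "goblet")

    clump_eta <- compute_eta(gob_internal, sec_landmarks)
    crypt_etas <- clump_eta$eta[
      gob_zones[clump_eta$sample_id] == 1L]
    cells_gob <- norm_matrix(
      prep$cells$norm$values[, cell_ids, drop = FALSE], "total")
    cell_eta_df <- compute_eta(cells_gob, sec_landmarks)
    cell_etas <- stats::setNames(cell_eta_df$eta, cell_eta_df$sample_id)

    # clump reference profiles at the reconstruction's zone count: the
    # spatial reference is linearly interpolated and zone assignment redone
    ref_coarse <- coarse_grain_reference(prep$sim$reference, n_zones)
    zonation_c <- run_clump_zonation(prep, config, reference = ref_coarse)
    zones_c <- stats::setNames(zonation_c$assignment$zone,
                               zonation_c$assignment$clump_id)
    gob_zones_c <- zones_c[colnames(gob_internal$values)]
    keep <- !is.na(gob_zones_c)
    gob_table_c <- compute_zonation_table(
      gob_internal$values[, keep, drop = FALSE], gob_zones_c[keep],
      test_floor = Inf, n_zones = n_zones)

    grid <- enumerate_eta_limits(
      crypt_etas, cell_etas, n_zones, d_eta,
      min_cells = config$reconstruction$min_cells_per_zone)
    cmp_genes <- rownames(gob_table_c$mean)[
      apply(gob_table_c$mean, 1L, max) >
        config$reconstruction$expression_threshold]
    # profile comparison is like-to-like: cells internally normalized over
    # the secretory-specific genes, as the clump table is
    cells_internal <- suppressWarnings(
      internal_normalize(cells_gob$values, sec_genes))
    cell_etas_i <- cell_etas[intersect(names(cell_etas),
                                       colnames(cells_internal$values))]
    opt <- optimize_eta_limits(grid$boundaries, cells_internal,
                               cell_etas_i, gob_table_c$mean, cmp_genes)
    table <- reconstruct_zonation(cells_gob, cell_etas, opt$boundaries,
                                  config)
    if (!details) return(table)
    list(table = table, boundaries = opt$boundaries, med_euc = opt$med_euc,
         grid = grid, sec_landmarks = sec_landmarks,
         sec_genes = sec_genes, clump_table_coarse = gob_table_c,
         clump_table_full = gob_table7, cell_etas = cell_etas,
         clump_eta = clump_eta, zonation = zonation,
         ent_landmarks = zonation$landmarks, cells_gob = cells_gob)
  }
}

#' Run the full synthetic demonstration pipeline and write its outputs
#'
#' Simulates a tissue, preprocesses, assigns clump zones, classifies clump
#' content, reconstructs goblet zonation from single cells, validates it
#' against the coarse-grained clump table, scores ligand-receptor
#' interactions between crypt/tip populations, and writes every product as
#' TSV under `out_dir`. A fixed seed makes the run byte-reproducible.
#'
#' @param seed integer seed
#' @param out_dir output directory
#' @param config a [clumpseq_config()]
#' @param n_cells,n_clumps dataset sizes
#' @return (invisibly) a list of the main in-memory products
#' @export
run_clumpseq_demo <- function(seed, out_dir, config = clumpseq_config(),
                              n_cells = 600L, n_clumps = 6000L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_clumpseq(config, seed, n_cells, n_clumps)
  prep <- prepare_pipeline(sim, config)
  utils::write.table(prep$clumps$report,
                     file.path(out_dir, "clump_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(prep$cells$report, file.path(out_dir, "cell_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  zonation <- run_clump_zonation(prep)
  utils::write.table(zonation$assignment,
                     file.path(out_dir, "clump_zones.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_landmark_set(zonation$landmarks,
                     file.path(out_dir, "enterocyte_landmarks.tsv"))
  zones <- stats::setNames(zonation$assignment$zone,
                           zonation$assignment$clump_id)

  calls <- run_clump_classification(prep, zones)
  utils::write.table(calls, file.path(out_dir, "clump_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  gob_ids <- calls$clump_id[calls$call == "goblet"]
  runner <- make_goblet_runner(prep, gob_ids, details = TRUE)
  recon <- runner(config)
  write_zonation_table(recon$table,
                       file.path(out_dir, "goblet_sc_zonation.tsv"))
  write_zonation_table(recon$clump_table_full,
                       file.path(out_dir, "goblet_clump_zonation.tsv"))
  write_landmark_set(recon$sec_landmarks,
                     file.path(out_dir, "goblet_landmarks.tsv"))
  utils::write.table(
    data.frame(boundary = recon$boundaries),
    file.path(out_dir, "goblet_eta_limits.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  val_genes <- tryCatch(
    select_validation_genes(recon$table, recon$clump_table_coarse,
                            recon$sec_landmarks, recon$sec_genes,
                            config$validation$sem_cutoffs$goblet, config),
    error = function(e) character())
  validation <- if (length(val_genes) >= 3L)
    validate_reconstruction(recon$table, recon$clump_table_coarse,
                            val_genes) else NULL
  if (!is.null(validation))
    utils::write.table(
      data.frame(R = validation$R, p = validation$p,
                 n_genes = validation$n_genes),
      file.path(out_dir, "validation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)

  # LR scoring between crypt and tip goblet/enterocyte populations,
  # using per-cell normalized expression split by true zone halves
  labels <- prep$labels
  cz <- stats::setNames(prep$sim$cell_truth$zone,
                        prep$sim$cell_truth$well_id)
  vals <- prep$cells$norm$values
  pop <- paste0(labels[colnames(vals)],
                ifelse(cz[colnames(vals)] <= 2, "_crypt",
                       ifelse(cz[colnames(vals)] >=
                                prep$sim$truth$n_zones - 1, "_tip",
                              "_mid")))
  big <- names(table(pop))[table(pop) >= 10]
  summ <- build_type_summary(vals[, pop %in% big, drop = FALSE],
                             pop[pop %in% big])
  lr_pairs <- synthetic_lr_pairs(prep$sim$truth)
  z <- compute_type_zscores(summ, config)
  scores <- compute_interaction_scores(z, lr_pairs, config)
  edges <- filter_interactions(scores, summ, "analysis", config)
  write_edge_table(edges, file.path(out_dir, "lr_edges.tsv"))

  invisible(list(sim = sim, prep = prep, zonation = zonation,
                 calls = calls, recon = recon, validation = validation,
                 lr_edges = edges))
}

#' Ligand-receptor pair list for the synthetic gene panel
#'
#' Pairs crypt-shaped with tip-shaped genes of the panel so the LR stage
#' has structured input with known zonation; a stand-in for a curated
#' catalogue.
#'
#' @param truth ground truth from [generate_reference()]
#' @param n_pairs number of pairs
#' @return data.frame with columns ligand, receptor
#' @export
synthetic_lr_pairs <- function(truth, n_pairs = 30L) {
  crypt <- names(truth$shape_of)[truth$shape_of == "crypt"]
  tip <- names(truth$shape_of)[truth$shape_of == "tip"]
  k <- min(n_pairs, length(crypt), length(tip))
  data.frame(ligand = crypt[seq_len(k)], receptor = tip[seq_len(k)])
}
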